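#' Scheffe simultaneous pairwise comparisons of focus counts
#'
#' One-way ANOVA followed by Scheffe's criterion for all pairwise contrasts:
#' the pairwise statistic `F_ij = (m_i - m_j)^2 / (MSE (1/n_i + 1/n_j))` is
#' referred to `(k - 1) F(k - 1, N - k)`, i.e.
#' `p_ij = P(F(k-1, N-k) > F_ij / (k-1))`. Simultaneous over all contrasts,
#' hence conservative relative to unadjusted pairwise F tests. Used for
#' per-nucleus focus counts, whose distributions are neither normal nor
#' homoscedastic enough for unprotected pairwise testing.
#'
#' @param groups named list of numeric vectors (per-nucleus counts per
#'   group), each with at least 2 observations.
#' @return Data frame with columns `group1`, `group2`, `diff`, `F`,
#'   `p_value`, `flag` (`"**"` p < 0.01, `"*"` p < 0.05, `""` otherwise).
#' @export
scheffe_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups")
  n <- lengths(groups)
  if (any(n < 2L)) stop("every group needs at least 2 observations")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  k <- length(groups)
  N <- sum(n)
  m <- vapply(groups, mean, numeric(1))
  sse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (sse == 0) stop("zero within-group variance; Scheffe criterion undefined")
  mse <- sse / (N - k)
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    Fij <- (m[i] - m[j])^2 / (mse * (1 / n[i] + 1 / n[j]))
    p <- stats::pf(Fij / (k - 1), k - 1, N - k, lower.tail = FALSE)
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               diff = m[i] - m[j], F = Fij, p_value = p,
               flag = if (p < 0.01) "**" else if (p < 0.05) "*" else "")
  })
  do.call(rbind, out)
}

#' Paired t test for surviving fractions
#'
#' Two-sided paired t test, as used to compare clonogenic survival between
#' dose-rate regimens (replicates paired across regimens).
#'
#' @param x,y paired numeric vectors (>= 2 pairs).
#' @return The `htest` object from [stats::t.test()].
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 2L) stop("need at least 2 pairs")
  if (stats::sd(x - y) == 0)
    stop("differences have zero variance; the paired t statistic is undefined")
  stats::t.test(x, y, paired = TRUE)
}
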