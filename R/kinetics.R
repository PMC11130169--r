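#' @title IMK lesion kinetics
#' @description
#' Potentially lethal lesions (PLLs) are produced in proportion to the dose
#' rate and removed at the total rate `a + c` (conversion plus repair). The
#' expected nucleus-level PLL count under a piecewise-constant dose-rate
#' history `Ddot(s)` is the convolution
#' `X(t) = k_N * integral_0^t Ddot(s) exp(-(a+c)(t-s)) ds`,
#' which has a closed form per segment. Lethal lesions (LLs) accrue as
#' `dW/dt = a X + b X^2 + gamma b k_N^2 G`, where
#' `G(s) = integral_0^s Ddot(u) exp(-2(a+c)(s-u)) du`
#' is the survival kernel of intra-track (same-event) PLL pairs: a pair made
#' by one deposition event at time `u` loses members at rate `a + c` each, so
#' the pair survives with `exp(-2(a+c)(s-u))`. At infinite time the three
#' terms integrate to `alpha0 D`, `F beta0 D^2` and `gamma beta0 D`
#' respectively, recovering the closed-form survival expression.
#' @name kinetics
NULL

# closed-form convolution sum_j R_j/rate * (exp(-rate*(t - min(t, hi_j))) -
# exp(-rate*(t - lo_j))) over active segments; vectorized over t
.segment_convolution <- function(t, segments, rate) {
  out <- numeric(length(t))
  for (j in seq_len(nrow(segments))) {
    lo <- segments$t_start[j]; hi <- segments$t_end[j]
    R <- segments$dose_rate[j]
    if (R == 0) next
    act <- t > lo
    if (!any(act)) next
    ta <- t[act]
    te <- pmin(ta, hi)
    # expm1 form: stable for exposure times far below 1/rate
    out[act] <- out[act] +
      R / rate * exp(-rate * (ta - te)) * (-expm1(-rate * (te - lo)))
  }
  pmax(out, 0)
}

#' Expected PLL count per nucleus
#'
#' @param t time(s) in hours since the start of irradiation (vectorized).
#' @param s a [dose_schedule()].
#' @param p a [cell_params()] object.
#' @return Expected PLL count per nucleus at each `t`.
#' @export
pll_expected <- function(t, s, p) {
  stopifnot(inherits(s, "dose_schedule"), inherits(p, "cell_params"))
  if (any(t < 0)) stop("time must be non-negative")
  p$k_N * .segment_convolution(t, s$segments, p$a_plus_c)
}

# intra-track pair kernel G(t); same shape as the PLL convolution but with
# decay rate 2(a+c) and without the k_N factor
.pair_kernel <- function(t, s, p) {
  .segment_convolution(t, s$segments, 2 * p$a_plus_c)
}

#' Expected PLL count for a train of instantaneous fractions
#'
#' The finite-fraction form: each fraction deposits `k_N * dose` PLLs at its
#' delivery time, which then decay exponentially at rate `a + c`. As the
#' number of fractions grows at fixed total dose and span, this converges to
#' the constant-rate closed form of [pll_expected()].
#'
#' @param t time(s) in hours (vectorized).
#' @param times fraction delivery times, hours, non-decreasing.
#' @param doses fraction doses, Gy (same length as `times`).
#' @param p a [cell_params()] object.
#' @export
pll_discrete <- function(t, times, doses, p) {
  stopifnot(inherits(p, "cell_params"), length(times) == length(doses))
  if (is.unsorted(times)) stop("fraction times must be non-decreasing")
  if (any(t < 0)) stop("time must be non-negative")
  vapply(t, function(tt) {
    k <- times <= tt
    p$k_N * sum(doses[k] * exp(-p$a_plus_c * (tt - times[k])))
  }, numeric(1))
}

# integrate f over [0, t] splitting at segment boundaries (the integrand is
# only piecewise-smooth); absolute tolerance in lesion counts
.piecewise_integral <- function(f, t, segments, abs_tol = 1e-10) {
  if (t <= 0) return(0)
  brk <- sort(unique(c(0, segments$t_start, segments$t_end, t)))
  brk <- brk[brk >= 0 & brk <= t]
  if (brk[length(brk)] < t) brk <- c(brk, t)
  total <- 0
  for (i in seq_len(length(brk) - 1L)) {
    piece <- stats::integrate(f, brk[i], brk[i + 1L],
                              rel.tol = 1e-9, abs.tol = abs_tol,
                              stop.on.error = FALSE)
    if (!piece$message %in% "OK")
      stop("lesion-accrual quadrature did not converge: ", piece$message)
    total <- total + piece$value
  }
  total
}

# LL accrual rate at times s (vectorized)
.ll_rate <- function(ss, s, p) {
  X <- pll_expected(ss, s, p)
  G <- .pair_kernel(ss, s, p)
  p$a * X + p$b * X^2 + p$gamma * p$b * p$k_N^2 * G
}

#' Expected lethal-lesion count per nucleus
#'
#' Numerically integrates the LL accrual rate from 0 to `t` (adaptive
#' quadrature split at every segment boundary).
#'
#' @inheritParams pll_expected
#' @export
ll_expected <- function(t, s, p) {
  stopifnot(inherits(s, "dose_schedule"), inherits(p, "cell_params"))
  if (any(t < 0)) stop("time must be non-negative")
  vapply(t, function(tt) .piecewise_integral(function(ss) .ll_rate(ss, s, p),
                                             tt, s$segments),
         numeric(1))
}

#' Lethal-lesion plateau (t -> infinity)
#'
#' After the last segment both `X` and `G` decay exponentially, so the tail
#' of the accrual integral is analytic:
#' `a X(T)/(a+c) + b X(T)^2/(2(a+c)) + gamma b k_N^2 G(T)/(2(a+c))`.
#' For a constant-rate schedule the plateau equals the closed-form
#' `-ln S` of [neg_log_survival()].
#'
#' @param s a [dose_schedule()].
#' @param p a [cell_params()] object.
#' @export
ll_plateau <- function(s, p) {
  Tend <- max(s$segments$t_end)
  XT <- pll_expected(Tend, s, p)
  GT <- .pair_kernel(Tend, s, p)
  ac <- p$a_plus_c
  ll_expected(Tend, s, p) +
    p$a * XT / ac + p$b * XT^2 / (2 * ac) +
    p$gamma * p$b * p$k_N^2 * GT / (2 * ac)
}

#' Expected gamma-H2AX focus count per nucleus
#'
#' The observable tracked by the focus-formation assay: the sum of reparable
#' (PLL) and lethal (LL) lesions per nucleus.
#'
#' @inheritParams pll_expected
#' @export
foci_expected <- function(t, s, p) {
  pll_expected(t, s, p) + ll_expected(t, s, p)
}

#' Lesion kinetics over a time grid
#'
#' @param s a [dose_schedule()].
#' @param p a [cell_params()] object.
#' @param times time grid in hours.
#' @return Data frame with columns `time_h`, `pll`, `ll`, `foci`.
#' @export
lesion_curve <- function(s, p, times) {
  pll <- pll_expected(times, s, p)
  ll <- ll_expected(times, s, p)
  data.frame(time_h = times, pll = pll, ll = ll, foci = pll + ll)
}
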