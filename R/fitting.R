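#' Exponential repair-rate fit to acute focus kinetics
#'
#' Fits `A * exp(-c t)` (optionally plus a constant offset for background and
#' residual-lesion counts) to mean focus counts per nucleus after an acute
#' exposure, by nonlinear least squares. The fitted decay rate `c` estimates
#' the PLL repair rate and is used downstream as prior information for the
#' total removal rate `a + c`; the amplitude scaled by the dose gives the
#' initial DSB yield `k_N`.
#'
#' @param foci data frame with columns `time_h` and `foci_count` (per-nucleus
#'   counts; several rows per timepoint are averaged) or `time_h` and
#'   `mean_foci`.
#' @param dose acute dose in Gy used to scale the amplitude to `k_N`.
#' @param background known background focus rate per nucleus, subtracted from
#'   the means before fitting (default 0).
#' @param offset if `TRUE`, fit `A exp(-c t) + B` instead of a pure
#'   exponential; useful when a residual plateau is present.
#' @return Object of class `repair_fit` with elements `k_N`, `c`, `sd`
#'   (named vector), `fit` (the `nls` object), `means` (the fitted means),
#'   and `r_squared`.
#' @export
fit_repair_rate <- function(foci, dose = 1, background = 0, offset = FALSE) {
  if (!is.data.frame(foci)) stop("foci must be a data frame")
  if ("mean_foci" %in% names(foci)) {
    means <- data.frame(time_h = foci$time_h, y = foci$mean_foci - background)
  } else {
    if (!all(c("time_h", "foci_count") %in% names(foci)))
      stop("foci must have columns time_h and foci_count (or mean_foci)")
    agg <- stats::aggregate(foci_count ~ time_h, data = foci, FUN = mean)
    means <- data.frame(time_h = agg$time_h, y = agg$foci_count - background)
  }
  means <- means[order(means$time_h), ]
  if (nrow(means) < 3L) stop("need at least 3 distinct timepoints")
  if (all(means$y <= 0)) stop("all focus counts are zero after background subtraction")
  pos <- means$y > 0
  slope <- stats::coef(stats::lm(log(means$y[pos]) ~ means$time_h[pos]))[2]
  start <- list(A = max(means$y), cc = max(-slope, 1e-3))
  fit <- if (offset) {
    minpack.lm::nlsLM(y ~ A * exp(-cc * time_h) + B, data = means,
                      start = c(start, list(B = max(min(means$y), 1e-3))),
                      lower = c(1e-12, 1e-12, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(y ~ A * exp(-cc * time_h), data = means,
                      start = start, lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- stats::coef(fit)
  if (cf[["A"]] <= 0 || cf[["cc"]] <= 0)
    stop("degenerate repair fit: non-positive amplitude or rate")
  se <- sqrt(diag(stats::vcov(fit)))
  fitted_y <- stats::fitted(fit)
  r2 <- r_squared(means$y, as.numeric(fitted_y))
  structure(
    list(k_N = cf[["A"]] / dose, c = cf[["cc"]],
         sd = c(k_N = se[["A"]] / dose, c = se[["cc"]]),
         offset = if (offset) cf[["B"]] else 0,
         dose = dose, fit = fit, means = means, r_squared = r2),
    class = "repair_fit"
  )
}

#' @export
print.repair_fit <- function(x, ...) {
  cat("Exponential DSB repair fit\n")
  cat(sprintf("  k_N = %.4g +/- %.3g per Gy (dose %g Gy)\n", x$k_N, x$sd[["k_N"]], x$dose))
  cat(sprintf("  c   = %.4g +/- %.3g per h\n", x$c, x$sd[["c"]]))
  if (x$offset > 0) cat(sprintf("  offset = %.3g foci\n", x$offset))
  cat(sprintf("  R^2 = %.4f on %d timepoints\n", x$r_squared, nrow(x$means)))
  invisible(x)
}

#' Likelihood-width policy for the survival fit
#'
#' The Gaussian likelihood on `-ln S` needs a width `sigma` per point:
#' \describe{
#'   \item{`"counting"`}{Poisson error propagation from raw colony counts:
#'     `sigma_i^2 = 1/colonies_i + 1/colonies_0 + value^2`, where
#'     `colonies_0` is the matching unirradiated control and `value` an extra
#'     biological coefficient of variation added in quadrature (default 0.1).
#'     The standard model for clonogenic data; needs `colonies` and
#'     (per-replicate) control rows in the table.}
#'   \item{`"se"`}{the per-point experimental standard error of `-ln S`
#'     (`se(SF)/SF` when the data carry `se` on the survival scale).}
#'   \item{`"fixed"`}{a single constant (default 0.1).}
#'   \item{`"fitted"`}{a global `sigma` sampled as a nuisance parameter with
#'     a Jeffreys-type `1/sigma` prior.}
#' }
#' The default `"auto"` uses `"counting"` when colony counts are present,
#' else `"se"` when standard errors are present, else `"fixed"`.
#'
#' @param mode one of `"auto"`, `"counting"`, `"se"`, `"fixed"`, `"fitted"`.
#' @param value constant width for `"fixed"`; extra biological cv for
#'   `"counting"` (default 0.1).
#' @export
sigma_policy <- function(mode = c("auto", "counting", "se", "fixed", "fitted"),
                         value = 0.1) {
  mode <- match.arg(mode)
  if (value < 0) stop("sigma value must be non-negative")
  if (mode == "fixed" && value <= 0) stop("fixed sigma must be positive")
  structure(list(mode = mode, value = value), class = "sigma_policy")
}

# resolve per-point sigmas on the full table (controls included), returning
# widths for the positive-dose rows; sigma = NULL means sigma is sampled
.resolve_sigma <- function(policy, survival) {
  pos <- survival$dose_Gy > 0
  has_col <- all(c("colonies", "n_plated") %in% names(survival)) &&
    any(survival$dose_Gy == 0)
  has_se <- "se" %in% names(survival) &&
    all(is.finite(survival$se[pos])) && all(survival$se[pos] > 0)
  mode <- policy$mode
  if (mode == "auto") mode <- if (has_col) "counting" else if (has_se) "se" else "fixed"
  switch(mode,
    counting = {
      if (!has_col)
        stop("sigma policy 'counting' needs colonies, n_plated and 0 Gy control rows")
      ctrl <- survival[survival$dose_Gy == 0, , drop = FALSE]
      col0_of <- function(row) {
        if ("replicate" %in% names(survival)) {
          m <- ctrl$colonies[ctrl$replicate == row$replicate]
          if (length(m) == 1L) return(m)
        }
        mean(ctrl$colonies)
      }
      n0_of <- function(row) {
        if ("replicate" %in% names(survival)) {
          m <- ctrl$n_plated[ctrl$replicate == row$replicate]
          if (length(m) == 1L) return(m)
        }
        mean(ctrl$n_plated)
      }
      sub <- survival[pos, , drop = FALSE]
      # variance from dose-level pooled counts: weighting each flask by its
      # own observed count correlates the weights with the response and
      # biases the fit; the pooled mean count per dose does not
      mean_col <- stats::ave(sub$colonies, sub$dose_Gy, FUN = mean)
      sig <- y <- numeric(nrow(sub))
      for (i in seq_len(nrow(sub))) {
        col0 <- col0_of(sub[i, ]); n0 <- n0_of(sub[i, ])
        # +0.5 keeps zero-colony flasks finite (Anscombe-style correction)
        sig[i] <- sqrt(1 / (mean_col[i] + 0.5) + 1 / (mean(ctrl$colonies) + 0.5) +
                         policy$value^2)
        y[i] <- -log(((sub$colonies[i] + 0.5) / sub$n_plated[i]) /
                       ((col0 + 0.5) / n0))
      }
      list(mode = "counting", sigma = sig, y = y)
    },
    se = {
      if (!has_se) stop("sigma policy 'se' needs positive per-point standard errors")
      list(mode = "se", sigma = survival$se[pos] / survival$sf[pos])  # sd of -ln S
    },
    fixed = list(mode = "fixed", sigma = rep(policy$value, sum(pos))),
    fitted = list(mode = "fitted", sigma = NULL)
  )
}

#' Gaussian log-likelihood of survival data under the IMK model
#'
#' `log P(d | theta) = sum_i log Normal(-ln S_exp_i; w_i(theta), sigma_i)`
#' with `w_i = (alpha0 + gamma beta0) D_i + F_i beta0 D_i^2` and `F_i` the
#' protraction factor for the delivery time of dose `D_i`.
#'
#' @param theta numeric vector `(alpha0, beta0, a_plus_c)`.
#' @param survival data frame with columns `dose_Gy`, `sf` and optionally
#'   `se`; rows with zero dose carry no information and are dropped.
#' @param gamma single-event dose factor, Gy.
#' @param sigma a [sigma_policy()] or a numeric vector of per-point widths.
#' @param dose_rate delivery dose rate in Gy/min (acute reference exposure).
#' @export
log_likelihood <- function(theta, survival, gamma, sigma = sigma_policy(),
                           dose_rate = 1.82) {
  if (inherits(sigma, "sigma_policy")) {
    res <- .resolve_sigma(sigma, survival)
    if (res$mode == "fitted")
      stop("for the 'fitted' sigma policy, sigma is part of theta; use mcmc_fit_survival")
    sig <- res$sigma
  }
  has_y <- inherits(sigma, "sigma_policy") && !is.null(res$y)
  survival <- survival[survival$dose_Gy > 0, , drop = FALSE]
  if (!inherits(sigma, "sigma_policy")) sig <- rep_len(sigma, nrow(survival))
  if (has_y) y <- res$y
  else {
    if (any(survival$sf <= 0)) stop("measured surviving fractions must be positive")
    y <- -log(survival$sf)
  }
  w <- .w_model(theta, survival$dose_Gy, gamma, dose_rate)
  sum(stats::dnorm(y, mean = w, sd = sig, log = TRUE))
}

# model -ln S at doses D delivered at dose_rate Gy/min
.w_model <- function(theta, D, gamma, dose_rate) {
  a0 <- theta[1]; b0 <- theta[2]; ac <- theta[3]
  T <- D / (dose_rate * 60)
  Fv <- lea_catcheside_F(ac, T)
  (a0 + gamma * b0) * D + Fv * b0 * D^2
}

#' MCMC configuration
#'
#' @param burn_in iterations discarded (step sizes adapt only here).
#' @param n_samples retained posterior draws.
#' @param alpha0_range,beta0_range support of the uniform priors.
#' @param target_acceptance acceptance-rate window targeted during burn-in.
#' @export
mcmc_control <- function(burn_in = 1000L, n_samples = 10000L,
                         alpha0_range = c(0, 5), beta0_range = c(0, 1),
                         target_acceptance = c(0.2, 0.45)) {
  stopifnot(burn_in >= 0, n_samples > 0)
  list(burn_in = as.integer(burn_in), n_samples = as.integer(n_samples),
       alpha0_range = alpha0_range, beta0_range = beta0_range,
       target_acceptance = target_acceptance)
}

#' Metropolis MCMC fit of the survival dose-response
#'
#' Samples `theta = (alpha0, beta0, a_plus_c)` by random-walk Metropolis.
#' Priors: uniform on `alpha0` and `beta0` within the configured ranges, and
#' a Gaussian on `a_plus_c` centred on the repair-fit rate `c` with its fit
#' standard deviation, truncated to positive values -- the repair fit is
#' prior information but the removal rate is updated by the survival data.
#' Proposal step sizes adapt during burn-in to a 20-45% acceptance window and
#' are then frozen. Fully deterministic under `seed`.
#'
#' @param survival data frame with columns `dose_Gy`, `sf`, optional `se`.
#' @param gamma single-event dose factor, Gy.
#' @param prior_c a [fit_repair_rate()] result, or `list(mean =, sd =)` for
#'   the `a_plus_c` prior.
#' @param sigma a [sigma_policy()].
#' @param control a [mcmc_control()] list.
#' @param dose_rate delivery dose rate of the survival experiment, Gy/min.
#' @param seed integer seed for the chain.
#' @return Object of class `imk_posterior`: `samples` (matrix with columns
#'   `alpha0`, `beta0`, `a_plus_c`, and `sigma` under the fitted-sigma
#'   policy), `summaries`, `acceptance_rate`, `config`, `seed`.
#' @export
mcmc_fit_survival <- function(survival, gamma, prior_c,
                              sigma = sigma_policy(), control = mcmc_control(),
                              dose_rate = 1.82, seed = 20240528L) {
  if (inherits(prior_c, "repair_fit"))
    prior_c <- list(mean = prior_c$c, sd = prior_c$sd[["c"]])
  if (prior_c$mean <= 0 || prior_c$sd < 0)
    stop("prior_c must have positive mean and non-negative sd")
  # an exact repair fit reports sd 0; keep the prior proper with a 1% floor
  prior_c$sd <- max(prior_c$sd, 0.01 * prior_c$mean)
  res <- .resolve_sigma(if (inherits(sigma, "sigma_policy")) sigma
                        else sigma_policy("fixed", sigma), survival)
  dat <- survival[survival$dose_Gy > 0, , drop = FALSE]
  if (nrow(dat) < 3L) stop("need at least 3 positive-dose survival points")
  fitted_sigma <- res$mode == "fitted"
  sig <- res$sigma
  if (!is.null(res$y)) y <- res$y
  else {
    if (any(dat$sf <= 0)) stop("measured surviving fractions must be positive")
    y <- -log(dat$sf)
  }
  D <- dat$dose_Gy
  a0r <- control$alpha0_range; b0r <- control$beta0_range

  logpost <- function(th) {
    if (th[1] <= a0r[1] || th[1] >= a0r[2]) return(-Inf)
    if (th[2] <= b0r[1] || th[2] >= b0r[2]) return(-Inf)
    if (th[3] <= 0) return(-Inf)
    s_i <- if (fitted_sigma) {
      if (th[4] <= 1e-4 || th[4] >= 10) return(-Inf)
      rep(th[4], length(y))
    } else sig
    w <- .w_model(th, D, gamma, dose_rate)
    ll <- sum(stats::dnorm(y, w, s_i, log = TRUE))
    lp <- stats::dnorm(th[3], prior_c$mean, prior_c$sd, log = TRUE)
    if (fitted_sigma) lp <- lp - log(th[4])  # Jeffreys-type 1/sigma
    ll + lp
  }

  # crude LQ initialisation: regress -ln(S)/D on D
  init_fit <- stats::lm(I(y / D) ~ D)
  a0_init <- min(max(stats::coef(init_fit)[1] - gamma * 0.01, 0.05), a0r[2] * 0.9)
  b0_init <- min(max(stats::coef(init_fit)[2], 1e-4), b0r[2] * 0.9)
  th <- c(a0_init, b0_init, prior_c$mean)
  step <- c(0.1 * max(a0_init, 0.1), 0.1 * max(b0_init, 0.01), 0.5 * prior_c$sd)
  if (fitted_sigma) { th <- c(th, 0.1); step <- c(step, 0.02) }
  npar <- length(th)

  set.seed(as.integer(seed))
  lp_cur <- logpost(th)
  if (!is.finite(lp_cur)) stop("initial state has zero posterior density")
  n_tot <- control$burn_in + control$n_samples
  samples <- matrix(NA_real_, control$n_samples, npar)
  log_post <- numeric(control$n_samples)
  acc_window <- 0L; acc_sampling <- 0L
  win <- 100L
  for (i in seq_len(n_tot)) {
    cand <- th + stats::rnorm(npar, 0, step)
    lp_cand <- logpost(cand)
    if (is.finite(lp_cand) && log(stats::runif(1)) < lp_cand - lp_cur) {
      th <- cand; lp_cur <- lp_cand
      if (i <= control$burn_in) acc_window <- acc_window + 1L
      else acc_sampling <- acc_sampling + 1L
    }
    if (i <= control$burn_in && i %% win == 0L) {
      rate <- acc_window / win
      if (rate < control$target_acceptance[1]) step <- step * 0.7
      else if (rate > control$target_acceptance[2]) step <- step * 1.3
      acc_window <- 0L
    }
    if (i > control$burn_in) {
      samples[i - control$burn_in, ] <- th
      log_post[i - control$burn_in] <- lp_cur
    }
  }
  acc_rate <- acc_sampling / control$n_samples
  if (acc_rate <= 0)
    stop("Metropolis chain never accepted a proposal during sampling")
  colnames(samples) <- c("alpha0", "beta0", "a_plus_c",
                         if (fitted_sigma) "sigma")
  summaries <- data.frame(
    parameter = colnames(samples),
    mean = colMeans(samples),
    sd = apply(samples, 2, stats::sd),
    row.names = NULL
  )
  structure(
    list(samples = samples, log_post = log_post, summaries = summaries,
         acceptance_rate = acc_rate, burn_in = control$burn_in,
         n_samples = control$n_samples, sigma_mode = res$mode,
         step = step, data = dat, y = y, sigma = sig,
         gamma = gamma, dose_rate = dose_rate,
         prior_c = prior_c, seed = as.integer(seed)),
    class = "imk_posterior"
  )
}

#' @export
print.imk_posterior <- function(x, ...) {
  cat(sprintf("IMK survival posterior (%d samples after %d burn-in, acceptance %.2f)\n",
              x$n_samples, x$burn_in, x$acceptance_rate))
  print(x$summaries, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.imk_posterior <- function(object, ...) {
  stats::setNames(object$summaries$mean, object$summaries$parameter)
}

#' Microscopic rates from a survival posterior
#'
#' Applies [micro_from_alpha0_beta0()] to the posterior means, propagating
#' the posterior standard deviations and the repair-fit `k_N` uncertainty by
#' the delta method.
#'
#' @param fit an `imk_posterior`.
#' @param k_N a `repair_fit` or `list(mean =, sd =)` for the DSB yield.
#' @return As [micro_from_alpha0_beta0()].
#' @export
derive_micro_params <- function(fit, k_N) {
  stopifnot(inherits(fit, "imk_posterior"))
  if (inherits(k_N, "repair_fit"))
    k_N <- list(mean = k_N$k_N, sd = k_N$sd[["k_N"]])
  sm <- fit$summaries
  g <- function(p, col) sm[[col]][sm$parameter == p]
  micro_from_alpha0_beta0(
    k_N = k_N$mean, alpha0 = g("alpha0", "mean"), beta0 = g("beta0", "mean"),
    a_plus_c = g("a_plus_c", "mean"),
    sd = list(k_N = k_N$sd, alpha0 = g("alpha0", "sd"),
              beta0 = g("beta0", "sd"), a_plus_c = g("a_plus_c", "sd"))
  )
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((obs - cal)^2) / sum((obs - mean(obs))^2)`.
#'
#' @param observed,calculated numeric vectors of equal length (>= 2).
#' @export
r_squared <- function(observed, calculated) {
  if (length(observed) != length(calculated)) stop("lengths differ")
  if (length(observed) < 2L) stop("need at least 2 points")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed values have zero variance")
  1 - sum((observed - calculated)^2) / ss_tot
}

#' Posterior-predictive band for a model output
#'
#' Evaluates `fun(theta)` at every posterior draw and returns the central
#' interval of the resulting distribution (default 68.3%, the 1-sigma
#' equivalent).
#'
#' @param fit an `imk_posterior`.
#' @param fun function taking a named numeric vector
#'   (`alpha0`, `beta0`, `a_plus_c`) and returning a numeric vector of model
#'   outputs (same length across draws).
#' @param prob central coverage probability.
#' @return Data frame with columns `mean`, `lo`, `hi` (one row per output).
#' @export
prediction_band <- function(fit, fun, prob = 0.683) {
  stopifnot(inherits(fit, "imk_posterior"))
  if (nrow(fit$samples) == 0L) stop("empty posterior")
  vals <- apply(fit$samples, 1, function(row) fun(row))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  qs <- apply(vals, 1, stats::quantile, probs = c((1 - prob) / 2, 1 - (1 - prob) / 2),
              names = FALSE)
  data.frame(mean = rowMeans(vals), lo = qs[1, ], hi = qs[2, ])
}
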