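#' Fit the IMK model to acute focus-kinetics and survival data
#'
#' The staged estimation procedure for one cell line:
#' \enumerate{
#'   \item fit `A exp(-c t)` to the mean focus counts after an acute exposure
#'     ([fit_repair_rate()]): yields the DSB yield `k_N = A / dose` and the
#'     repair rate `c`, the prior for the total removal rate `a + c`;
#'   \item fit the survival dose-response by Metropolis MCMC
#'     ([mcmc_fit_survival()]): posterior for `(alpha0, beta0, a_plus_c)`;
#'   \item invert to the microscopic conversion rates
#'     `a = alpha0 (a+c) / k_N`, `b = 2 beta0 (a+c) / k_N^2` with
#'     delta-method standard deviations ([derive_micro_params()]).
#' }
#' The single-event dose factor `gamma` is a beam-quality input, not fitted.
#'
#' @param foci data frame of acute per-nucleus focus counts
#'   (`time_h`, `foci_count`) or means (`time_h`, `mean_foci`).
#' @param survival data frame (`dose_Gy`, `sf`, optional `se`).
#' @param dose acute dose of the focus experiment, Gy.
#' @param gamma single-event dose factor, Gy (default 0.954, 150 kVp X-rays).
#' @param dose_rate delivery dose rate of both acute experiments, Gy/min.
#' @param background known background focus rate subtracted before the repair
#'   fit.
#' @param offset fit a constant offset in the repair fit (see
#'   [fit_repair_rate()]).
#' @param sigma a [sigma_policy()].
#' @param control a [mcmc_control()].
#' @param seed integer seed for the MCMC chain.
#' @param cell_line label stored on the fitted parameter set.
#' @return Object of class `imk_fit`: elements `params` (a [cell_params()]
#'   with fitted values and SDs), `repair`, `posterior`, `micro`,
#'   `r_squared` (named: `foci`, `survival`), `data`, `call`.
#' @examples
#' \donttest{
#' p <- imk_cell_lines("HLEC")
#' sc <- acute_schedule(1, 1.82)
#' foci <- gen_foci(p, sc, lapply(c(0.5, 1, 2.5, 6, 24, 48), timepoint),
#'                  n_cells = 100, lambda0 = 0, seed = 1)
#' surv <- gen_survival(p, dose_rate = 1.82, doses = c(0, 2, 4, 6, 10), seed = 1)
#' fit <- imk_fit(foci, summarize_survival(surv), seed = 1)
#' coef(fit)
#' }
#' @export
imk_fit <- function(foci, survival, dose = 1, gamma = 0.954, dose_rate = 1.82,
                    background = 0, offset = FALSE,
                    sigma = sigma_policy(), control = mcmc_control(),
                    seed = 20240528L, cell_line = "fitted") {
  if (missing(foci) || is.null(foci)) stop("missing input: foci (acute focus-count table)")
  if (missing(survival) || is.null(survival)) stop("missing input: survival (dose-response table)")
  repair <- fit_repair_rate(foci, dose = dose, background = background,
                            offset = offset)
  post <- mcmc_fit_survival(survival, gamma = gamma, prior_c = repair,
                            sigma = sigma, control = control,
                            dose_rate = dose_rate, seed = seed)
  micro <- derive_micro_params(post, repair)
  cf <- coef(post)
  params <- cell_params(
    k_N = repair$k_N, a_plus_c = cf[["a_plus_c"]],
    alpha0 = cf[["alpha0"]], beta0 = cf[["beta0"]], gamma = gamma,
    a = micro$a, b = micro$b,
    sd = list(k_N = repair$sd[["k_N"]], a = micro$sd[["a"]], b = micro$sd[["b"]],
              a_plus_c = post$summaries$sd[post$summaries$parameter == "a_plus_c"],
              alpha0 = post$summaries$sd[post$summaries$parameter == "alpha0"],
              beta0 = post$summaries$sd[post$summaries$parameter == "beta0"]),
    cell_line = cell_line
  )
  w_cal <- .w_model(c(cf[["alpha0"]], cf[["beta0"]], cf[["a_plus_c"]]),
                    post$data$dose_Gy, gamma, dose_rate)
  r2 <- c(foci = repair$r_squared,
          survival = r_squared(post$y, w_cal))
  structure(
    list(params = params, repair = repair, posterior = post, micro = micro,
         r_squared = r2, gamma = gamma, dose = dose, dose_rate = dose_rate,
         data = list(foci = foci, survival = survival),
         call = match.call()),
    class = "imk_fit"
  )
}

#' @export
print.imk_fit <- function(x, ...) {
  cat("IMK model fit (", x$params$cell_line, ")\n", sep = "")
  cat(sprintf("  repair fit:   k_N = %.4g per Gy, c = %.4g per h (R^2 = %.4f)\n",
              x$repair$k_N, x$repair$c, x$r_squared[["foci"]]))
  cf <- coef(x$posterior)
  cat(sprintf("  survival fit: alpha0 = %.4g per Gy, beta0 = %.4g per Gy^2, a+c = %.4g per h (R^2 = %.4f)\n",
              cf[["alpha0"]], cf[["beta0"]], cf[["a_plus_c"]],
              x$r_squared[["survival"]]))
  cat(sprintf("  derived:      a = %.4g per h, b = %.4g per h\n",
              x$micro$a, x$micro$b))
  invisible(x)
}

#' @export
summary.imk_fit <- function(object, ...) {
  p <- object$params
  flds <- c("k_N", "a", "b", "a_plus_c", "alpha0", "beta0")
  out <- data.frame(
    parameter = c(flds, "gamma"),
    estimate = c(vapply(flds, function(f) p[[f]], numeric(1)), p$gamma),
    sd = c(vapply(flds, function(f) p$sd[[f]] %||% NA_real_, numeric(1)), NA_real_),
    units = c("Gy^-1", "h^-1", "h^-1", "h^-1", "Gy^-1", "Gy^-2", "Gy")
  )
  rownames(out) <- NULL
  structure(list(table = out, r_squared = object$r_squared,
                 acceptance_rate = object$posterior$acceptance_rate,
                 cell_line = p$cell_line),
            class = "summary.imk_fit")
}

#' @export
print.summary.imk_fit <- function(x, ...) {
  cat("IMK model parameter estimates (", x$cell_line, ")\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("R^2: foci %.4f, survival %.4f; MCMC acceptance %.2f\n",
              x$r_squared[["foci"]], x$r_squared[["survival"]],
              x$acceptance_rate))
  invisible(x)
}

#' @export
coef.imk_fit <- function(object, ...) {
  p <- object$params
  c(k_N = p$k_N, a = p$a, b = p$b, a_plus_c = p$a_plus_c,
    alpha0 = p$alpha0, beta0 = p$beta0, gamma = p$gamma)
}

#' Predict focus kinetics or survival from a fitted IMK model
#'
#' @param object an `imk_fit`.
#' @param schedule a [dose_schedule()]; defaults to the acute calibration
#'   schedule.
#' @param times time grid in hours (for `type = "foci"`).
#' @param doses doses in Gy (for `type = "survival"`; each delivered at the
#'   schedule's average dose rate).
#' @param type `"foci"` or `"survival"`.
#' @param band if `TRUE`, attach a posterior-predictive 68.3% interval
#'   (survival only; focus bands come from [predict_doserate_foci()]).
#' @param ... unused.
#' @return Data frame of predictions.
#' @export
predict.imk_fit <- function(object, schedule = NULL, times = NULL, doses = NULL,
                            type = c("foci", "survival"), band = FALSE, ...) {
  type <- match.arg(type)
  p <- object$params
  if (is.null(schedule))
    schedule <- acute_schedule(object$dose, object$dose_rate)
  if (type == "foci") {
    if (is.null(times)) times <- sort(unique(c(seq(0.1, 6, by = 0.25), 12, 24, 48)))
    return(lesion_curve(schedule, p, times))
  }
  if (is.null(doses)) doses <- sort(unique(object$data$survival$dose_Gy))
  rate <- average_dose_rate(schedule, units = "Gy/min")
  out <- data.frame(dose_Gy = doses)
  th <- coef(object$posterior)
  out$neg_log_s <- .w_model(th[c("alpha0", "beta0", "a_plus_c")], doses,
                            p$gamma, rate)
  out$sf <- exp(-out$neg_log_s)
  if (band) {
    bb <- prediction_band(object$posterior, function(row)
      exp(-.w_model(row[c("alpha0", "beta0", "a_plus_c")], doses, p$gamma, rate)))
    out$sf_lo <- bb$lo; out$sf_hi <- bb$hi
  }
  out
}

#' @export
residuals.imk_fit <- function(object, type = c("foci", "survival"), ...) {
  type <- match.arg(type)
  if (type == "foci") {
    m <- object$repair$means
    return(m$y - as.numeric(stats::fitted(object$repair$fit)))
  }
  post <- object$posterior
  th <- coef(post)
  post$y - .w_model(th[c("alpha0", "beta0", "a_plus_c")],
                    post$data$dose_Gy, object$params$gamma, object$dose_rate)
}

#' Simulate datasets from a fitted IMK model
#'
#' Draws new synthetic focus-count or survival datasets at the fitted
#' parameter values (parametric bootstrap of the assays).
#'
#' @param object an `imk_fit`.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param what `"foci"` or `"survival"`.
#' @param ... passed to [gen_foci()] or [gen_survival()].
#' @return A list of `nsim` datasets.
#' @export
simulate.imk_fit <- function(object, nsim = 1, seed = NULL,
                             what = c("foci", "survival"), ...) {
  what <- match.arg(what)
  if (is.null(seed)) seed <- object$posterior$seed
  lapply(seq_len(nsim), function(i) {
    if (what == "foci") {
      gen_foci(object$params, acute_schedule(object$dose, object$dose_rate),
               timepoints = lapply(c(0.5, 1, 2.5, 6, 24, 48), timepoint),
               seed = seed + i - 1L, ...)
    } else {
      gen_survival(object$params, dose_rate = object$dose_rate,
                   seed = seed + i - 1L, ...)
    }
  })
}

#' Diagnostic plot of a fitted IMK model
#'
#' Left: mean focus counts with the fitted exponential repair curve (log
#' scale). Right: measured surviving fractions with the fitted
#' linear-quadratic curve (log scale).
#'
#' @param x an `imk_fit`.
#' @param ... unused.
#' @export
plot.imk_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  m <- x$repair$means
  tt <- seq(min(m$time_h), max(m$time_h), length.out = 200)
  graphics::plot(m$time_h, pmax(m$y, 1e-3), log = "y",
                 xlab = "time after exposure (h)", ylab = "foci per nucleus",
                 main = "DSB repair kinetics", pch = 16)
  graphics::lines(tt, x$repair$k_N * x$dose * exp(-x$repair$c * tt) + x$repair$offset)
  sdat <- x$data$survival
  sdat <- sdat[sdat$sf > 0, ]  # zero-colony flasks cannot sit on a log axis
  pr <- predict(x, type = "survival",
                doses = seq(0.01, max(sdat$dose_Gy), length.out = 100))
  graphics::plot(sdat$dose_Gy, sdat$sf, log = "y", xlab = "dose (Gy)",
                 ylab = "surviving fraction", main = "Clonogenic survival",
                 pch = 16)
  graphics::lines(pr$dose_Gy, pr$sf)
  invisible(x)
}
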