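#' Analysis configuration
#'
#' Bundles the knobs of an end-to-end run with their defaults.
#'
#' @param gamma single-event dose factor, Gy.
#' @param dose acute calibration dose, Gy.
#' @param dose_rate acute delivery dose rate, Gy/min.
#' @param lambda0 background foci per nucleus assumed for predictions.
#' @param background background subtracted before the repair fit.
#' @param offset include a constant offset in the repair fit.
#' @param sigma a [sigma_policy()].
#' @param mcmc a [mcmc_control()].
#' @param seed integer seed.
#' @export
analysis_config <- function(gamma = 0.954, dose = 1, dose_rate = 1.82,
                            lambda0 = 0.5, background = 0, offset = FALSE,
                            sigma = sigma_policy(), mcmc = mcmc_control(),
                            seed = 20240528L) {
  if (gamma <= 0) stop("gamma must be positive")
  list(gamma = gamma, dose = dose, dose_rate = dose_rate, lambda0 = lambda0,
       background = background, offset = offset, sigma = sigma, mcmc = mcmc,
       seed = as.integer(seed))
}

#' Calibrate the IMK model on acute-exposure data
#'
#' Runs the staged estimation (repair fit, MCMC survival fit, inversion to
#' microscopic rates) on acute-regimen focus and survival tables. Thin
#' wrapper over [imk_fit()] taking an [analysis_config()].
#'
#' @param foci acute focus-count table (see [imk_fit()]).
#' @param survival survival table (`dose_Gy`, `sf`, optional `se`).
#' @param config an [analysis_config()].
#' @param cell_line label for the fitted parameter set.
#' @return An `imk_fit` object.
#' @export
run_acute_calibration <- function(foci, survival, config = analysis_config(),
                                  cell_line = "fitted") {
  imk_fit(foci, survival, dose = config$dose, gamma = config$gamma,
          dose_rate = config$dose_rate, background = config$background,
          offset = config$offset, sigma = config$sigma, control = config$mcmc,
          seed = config$seed, cell_line = cell_line)
}

#' Predicted focus counts across dose-rate regimens
#'
#' Expected gamma-H2AX foci per nucleus at each (regimen, timepoint), with an
#' optional posterior-predictive 1-sigma band when a survival posterior and a
#' DSB-yield estimate are supplied (per posterior draw, the microscopic rates
#' are re-derived from that draw's `(alpha0, beta0, a_plus_c)` and a matching
#' Gaussian draw of `k_N`).
#'
#' @param params a [cell_params()] object.
#' @param scenarios as returned by [doserate_scenarios()].
#' @param lambda0 background foci added to the predictions.
#' @param posterior optional `imk_posterior` for bands.
#' @param k_N optional `list(mean =, sd =)` (or `repair_fit`) for the band's
#'   `k_N` uncertainty; required with `posterior`.
#' @param band_draws posterior draws used for the band (thinned for speed).
#' @return Data frame: `regimen`, `dose_rate_Gy_min`, `offset_h`,
#'   `reference`, `time_h`, `predicted` (+ `lo`, `hi` with a posterior).
#' @export
predict_doserate_foci <- function(params, scenarios = doserate_scenarios(),
                                  lambda0 = 0, posterior = NULL, k_N = NULL,
                                  band_draws = 200L) {
  rows <- list()
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    for (tp in sc$timepoints) {
      t_abs <- absolute_time(sc$schedule, tp)
      rows[[length(rows) + 1L]] <- data.frame(
        regimen = nm,
        dose_rate_Gy_min = average_dose_rate(sc$schedule, units = "Gy/min"),
        offset_h = tp$offset_h, reference = tp$reference, time_h = t_abs,
        predicted = lambda0 + foci_expected(t_abs, sc$schedule, params))
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(posterior)) {
    if (is.null(k_N)) stop("supply k_N (mean, sd) to compute focus bands")
    if (inherits(k_N, "repair_fit")) k_N <- list(mean = k_N$k_N, sd = k_N$sd[["k_N"]])
    idx <- unique(round(seq(1, nrow(posterior$samples),
                            length.out = min(band_draws, nrow(posterior$samples)))))
    set.seed(posterior$seed)
    kdraws <- pmax(stats::rnorm(length(idx), k_N$mean, k_N$sd), 1e-3)
    vals <- matrix(NA_real_, nrow(out), length(idx))
    for (j in seq_along(idx)) {
      th <- posterior$samples[idx[j], ]
      # a < a_plus_c requires alpha0 < k_N; binding only for pathological draws
      pj <- cell_params(k_N = kdraws[j], a_plus_c = th[["a_plus_c"]],
                        alpha0 = min(th[["alpha0"]], 0.999 * kdraws[j]),
                        beta0 = th[["beta0"]], gamma = params$gamma,
                        cell_line = params$cell_line)
      for (i in seq_len(nrow(out))) {
        sc <- scenarios[[out$regimen[i]]]
        vals[i, j] <- lambda0 + foci_expected(out$time_h[i], sc$schedule, pj)
      }
    }
    qs <- apply(vals, 1, stats::quantile, probs = c(0.1585, 0.8415), names = FALSE)
    out$lo <- qs[1, ]; out$hi <- qs[2, ]
  }
  out
}

#' Predicted survival across dose rates
#'
#' Surviving fraction at fixed doses as a function of the average dose rate
#' (each exposure modelled as constant-rate with duration `dose / rate`).
#'
#' @param params a [cell_params()] object.
#' @param dose_rates average dose rates, Gy/min.
#' @param doses doses, Gy (default 2 and 4).
#' @return Data frame `dose_rate_Gy_min`, `dose_Gy`, `F`, `neg_log_s`, `sf`.
#' @export
predict_doserate_survival <- function(params, dose_rates, doses = c(2, 4)) {
  grid <- expand.grid(dose_rate_Gy_min = dose_rates, dose_Gy = doses)
  T <- grid$dose_Gy / (grid$dose_rate_Gy_min * 60)
  Fv <- lea_catcheside_F(params$a_plus_c, T)
  w <- (params$alpha0 + params$gamma * params$beta0) * grid$dose_Gy +
    Fv * params$beta0 * grid$dose_Gy^2
  data.frame(grid, F = Fv, neg_log_s = w, sf = exp(-w))
}

#' Compare observed focus counts with model predictions
#'
#' Per (regimen, timepoint): observed mean and standard error of the
#' per-nucleus counts, the model prediction (including the background rate),
#' and the observed/predicted ratio with its standard error. A ratio
#' compatible with 1 across regimens means the data carry no dose-rate effect
#' beyond the model's.
#'
#' @param foci a focus-count table as produced by [gen_foci()] over several
#'   regimens (rows carry `schedule_label`, `time_h`, `foci_count`).
#' @param params a [cell_params()] object.
#' @param scenarios as [doserate_scenarios()]; labels must match
#'   `schedule_label`.
#' @param lambda0 background rate included in the prediction.
#' @return Data frame with observed, predicted, `ratio` and `ratio_se`.
#' @export
compare_foci <- function(foci, params, scenarios = doserate_scenarios(),
                         lambda0 = 0.5) {
  sched_by_label <- stats::setNames(
    lapply(scenarios, `[[`, "schedule"),
    vapply(scenarios, function(s) s$schedule$label, character(1)))
  keys <- unique(foci[, c("schedule_label", "offset_h", "reference", "time_h")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- foci[foci$schedule_label == k$schedule_label &
                  foci$time_h == k$time_h, ]
    s <- sched_by_label[[k$schedule_label]]
    if (is.null(s)) stop("no scenario schedule labelled '", k$schedule_label, "'")
    pred <- lambda0 + foci_expected(k$time_h, s, params)
    obs <- mean(sub$foci_count)
    se <- stats::sd(sub$foci_count) / sqrt(nrow(sub))
    data.frame(k, n = nrow(sub), observed = obs, observed_se = se,
               predicted = pred, ratio = obs / pred, ratio_se = se / pred)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the report tables of a calibrated run
#'
#' Emits UTF-8, '.'-decimal CSV tables (fitted parameter table, focus
#' kinetics curve, survival-versus-dose-rate table) and a JSON manifest
#' recording configuration and seed. Re-running with identical inputs yields
#' byte-identical files.
#'
#' @param fit an `imk_fit`.
#' @param dir output directory (created if needed).
#' @param dose_rates dose rates for the survival table, Gy/min.
#' @return Invisibly, the paths written.
#' @export
report_run <- function(fit, dir,
                       dose_rates = c(1.82, 0.435, 0.1, 0.033, 0.00461, 0.00081)) {
  stopifnot(inherits(fit, "imk_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, mode = 2) != 0) stop("output directory is not writable: ", dir)
  paths <- c(
    params = file.path(dir, "fitted_parameters.csv"),
    foci = file.path(dir, "foci_kinetics.csv"),
    survival = file.path(dir, "survival_by_doserate.csv"),
    manifest = file.path(dir, "run_manifest.json")
  )
  utils::write.csv(summary(fit)$table, paths["params"], row.names = FALSE)
  utils::write.csv(predict(fit, type = "foci"), paths["foci"], row.names = FALSE)
  utils::write.csv(predict_doserate_survival(fit$params, dose_rates),
                   paths["survival"], row.names = FALSE)
  manifest <- list(
    package = "imkfit",
    version = as.character(utils::packageVersion("imkfit")),
    cell_line = fit$params$cell_line,
    seed = fit$posterior$seed,
    gamma_Gy = fit$gamma,
    dose_Gy = fit$dose,
    dose_rate_Gy_min = fit$dose_rate,
    mcmc = list(burn_in = fit$posterior$burn_in,
                n_samples = fit$posterior$n_samples,
                acceptance_rate = fit$posterior$acceptance_rate,
                sigma_mode = fit$posterior$sigma_mode),
    r_squared = as.list(fit$r_squared)
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             paths["manifest"])
  invisible(paths)
}
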