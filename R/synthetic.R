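#' Synthetic gamma-H2AX focus-count datasets
#'
#' Emulates the focus-formation assay: for each timepoint, per-nucleus counts
#' are drawn as Poisson around `lambda0 + delta_N(t)`, where `delta_N` is the
#' expected PLL + LL count from the kinetics engine and `lambda0` a constant
#' background focus rate. An optional negative-binomial size parameter adds
#' overdispersion (real per-nucleus counts are typically wider than Poisson).
#'
#' @param params a [cell_params()] object.
#' @param schedule a [dose_schedule()] (carries the total dose).
#' @param timepoints list of [timepoint()] objects.
#' @param n_cells nuclei scored per timepoint (default 100, the usual scale
#'   of a focus-counting experiment).
#' @param lambda0 background foci per nucleus (default 0.5).
#' @param seed integer seed; identical seeds give identical datasets.
#' @param size negative-binomial size (dispersion) parameter; `NULL` (the
#'   default) draws pure Poisson counts.
#' @return Data frame with columns `cell_line`, `schedule_label`, `dose_Gy`,
#'   `offset_h`, `reference`, `time_h`, `nucleus_id`, `foci_count`, and
#'   attributes `seed`, `lambda0`, `n_cells`.
#' @export
gen_foci <- function(params, schedule, timepoints, n_cells = 100,
                     lambda0 = 0.5, seed = NULL, size = NULL) {
  stopifnot(inherits(params, "cell_params"), inherits(schedule, "dose_schedule"))
  if (n_cells < 1) stop("n_cells must be positive")
  if (lambda0 < 0) stop("lambda0 must be non-negative")
  if (inherits(timepoints, "imk_timepoint")) timepoints <- list(timepoints)
  if (!is.null(seed)) set.seed(as.integer(seed))
  rows <- lapply(timepoints, function(tp) {
    t_abs <- absolute_time(schedule, tp)
    mu <- lambda0 + foci_expected(t_abs, schedule, params)
    counts <- if (is.null(size)) stats::rpois(n_cells, mu)
              else stats::rnbinom(n_cells, size = size, mu = mu)
    data.frame(cell_line = params$cell_line, schedule_label = schedule$label,
               dose_Gy = total_dose(schedule), offset_h = tp$offset_h,
               reference = tp$reference, time_h = t_abs,
               nucleus_id = seq_len(n_cells), foci_count = counts)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "lambda0") <- lambda0
  attr(out, "n_cells") <- n_cells
  out
}

# plating design of the clonogenic assay: cells seeded per flask by dose
.default_plating <- function(dose) {
  if (dose == 0) 1e3
  else if (dose %in% c(2, 4)) 3e3
  else if (dose == 6) 5e3
  else if (dose == 10) 1e4
  else stop("no plating rule for dose ", dose,
            " Gy; supply n_plated explicitly")
}

#' Synthetic clonogenic-survival datasets
#'
#' Emulates the colony-formation assay: per replicate, colony counts are
#' binomial with success probability `pe0 * S_model(dose)`, and the surviving
#' fraction is the ratio of plating efficiencies against the same replicate's
#' unirradiated control -- exactly as the assay is scored, so the plating
#' efficiency `pe0` cancels in expectation. Cells plated per flask follow the
#' dose-tiered design (1e3 at 0 Gy, 3e3 at 2 and 4 Gy, 5e3 at 6 Gy, 1e4 at
#' 10 Gy) unless overridden.
#'
#' @param params a [cell_params()] object.
#' @param dose_rate average delivery dose rate, Gy/min (each dose is modelled
#'   as a constant-rate exposure of duration `dose / dose_rate`).
#' @param doses doses in Gy; must include 0 (the control).
#' @param pe0 plating efficiency of unirradiated cells.
#' @param replicates independent replicates.
#' @param n_plated optional named vector mapping `as.character(dose)` to
#'   cells plated, overriding the tiered design.
#' @param cv coefficient of variation of a mean-one lognormal factor applied
#'   to each irradiated flask's expected survival before counting
#'   (inter-flask biological variability; default 0 = counting noise only).
#' @param seed integer seed.
#' @param schedule_label label recorded on the rows.
#' @return Data frame with columns `cell_line`, `schedule_label`, `dose_Gy`,
#'   `replicate`, `n_plated`, `colonies`, `sf`.
#' @export
gen_survival <- function(params, dose_rate = 1.82, doses = c(0, 2, 4, 6, 10),
                         pe0 = 0.3, replicates = 3, n_plated = NULL, cv = 0,
                         seed = NULL,
                         schedule_label = sprintf("%.3g Gy/min", dose_rate)) {
  stopifnot(inherits(params, "cell_params"))
  if (pe0 <= 0 || pe0 > 1) stop("pe0 must be in (0, 1]")
  if (cv < 0) stop("cv must be non-negative")
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  if (!0 %in% doses) doses <- c(0, doses)
  doses <- sort(unique(doses))
  n_of <- function(d) {
    if (!is.null(n_plated) && !is.na(n_plated[as.character(d)]))
      return(unname(n_plated[as.character(d)]))
    .default_plating(d)
  }
  s_model <- vapply(doses, function(d) {
    if (d == 0) return(1)
    T <- d / (dose_rate * 60)
    exp(-((params$alpha0 + params$gamma * params$beta0) * d +
            lea_catcheside_F(params$a_plus_c, T) * params$beta0 * d^2))
  }, numeric(1))
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- list()
  for (r in seq_len(replicates)) {
    n0 <- n_of(0)
    col0 <- stats::rbinom(1, n0, pe0)
    if (col0 == 0) stop("control flask produced no colonies; increase pe0 or n_plated")
    pe_control <- col0 / n0
    for (i in seq_along(doses)) {
      d <- doses[i]; n <- n_of(d)
      s_eff <- if (d > 0 && cv > 0)
        s_model[i] * stats::rlnorm(1, -sdlog^2 / 2, sdlog) else s_model[i]
      col <- if (d == 0) col0 else stats::rbinom(1, n, min(pe0 * s_eff, 1))
      out[[length(out) + 1L]] <- data.frame(
        cell_line = params$cell_line, schedule_label = schedule_label,
        dose_Gy = d, replicate = r, n_plated = n, colonies = col,
        sf = (col / n) / pe_control)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "seed") <- seed
  attr(res, "pe0") <- pe0
  res
}

#' Collapse replicate survival rows to per-dose means with standard errors
#'
#' @param survival a [gen_survival()] data frame (or any frame with
#'   `dose_Gy`, `sf`).
#' @return Data frame `dose_Gy`, `sf` (mean over replicates), `se`.
#' @export
summarize_survival <- function(survival) {
  agg <- stats::aggregate(sf ~ dose_Gy, data = survival,
                          FUN = function(v) c(mean = mean(v),
                                              se = stats::sd(v) / sqrt(length(v))))
  data.frame(dose_Gy = agg$dose_Gy, sf = agg$sf[, "mean"], se = agg$sf[, "se"])
}

#' The five dose-rate regimens of the study design
#'
#' Acute 1.82 Gy/min X-rays; 0.2 Gy fractions every 120 s (0.1 Gy/min
#' average); 0.05 Gy fractions every 90 s (0.033 Gy/min average); continuous
#' gamma-ray exposures at 0.00461 and 0.00081 Gy/min. Each regimen is paired
#' with the standard observation timepoints: 0.5 and 1 h after the end of
#' irradiation, 24 and 48 h after its start. At the lowest dose rate the 24 h
#' point falls during delivery of a 1 Gy dose; the kinetics engine handles
#' in-exposure observation times.
#'
#' @param total_dose total dose per regimen, Gy (default 1; must be a
#'   multiple of 0.2 so the fraction trains close exactly).
#' @return Named list of `list(schedule =, timepoints =)` entries.
#' @export
doserate_scenarios <- function(total_dose = 1) {
  if (total_dose <= 0) stop("total_dose must be positive")
  n1 <- total_dose / 0.2
  n2 <- total_dose / 0.05
  if (abs(n1 - round(n1)) > 1e-9 || abs(n2 - round(n2)) > 1e-9)
    stop("total_dose must be a multiple of 0.2 Gy to close both fraction trains")
  tps <- list(timepoint(0.5, "after_end"), timepoint(1, "after_end"),
              timepoint(24, "after_start"), timepoint(48, "after_start"))
  sc <- list(
    `1.82 Gy/min` = acute_schedule(total_dose, 1.82, label = "acute 1.82 Gy/min"),
    `0.1 Gy/min` = fractionated_schedule(0.2, round(n1), 120, 1.82,
                                         label = "0.2 Gy/Fr @ 120 s"),
    `0.033 Gy/min` = fractionated_schedule(0.05, round(n2), 90, 1.82,
                                           label = "0.05 Gy/Fr @ 90 s"),
    `0.00461 Gy/min` = continuous_schedule(total_dose, 0.00461,
                                           label = "continuous 0.00461 Gy/min"),
    `0.00081 Gy/min` = continuous_schedule(total_dose, 0.00081,
                                           label = "continuous 0.00081 Gy/min")
  )
  lapply(sc, function(s) list(schedule = s, timepoints = tps))
}
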