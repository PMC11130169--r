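#' @title Piecewise-constant irradiation schedules
#' @description Internal representation: a data frame of exposure segments in
#'   hours and Gy/hour on an absolute clock starting at the beginning of
#'   irradiation. Constructors accept dose rates in Gy/min, the unit in which
#'   X-ray and gamma-ray source outputs are usually quoted.
#' @name schedule
NULL

# unit conversions; rates are stored in Gy/h, constructor arguments are Gy/min
.gy_min_to_gy_h <- function(x) x * 60
.gy_h_to_gy_min <- function(x) x / 60

#' Construct a dose schedule from exposure segments
#'
#' @param segments data frame with columns `t_start`, `t_end` (hours) and
#'   `dose_rate` (Gy/hour); segments must be time-ordered and non-overlapping.
#' @param label free-text label for the regimen.
#' @param meta optional list of construction metadata (e.g. fraction layout).
#' @return An object of class `dose_schedule`.
#' @export
dose_schedule <- function(segments, label = "schedule", meta = list()) {
  stopifnot(is.data.frame(segments))
  req <- c("t_start", "t_end", "dose_rate")
  if (!all(req %in% names(segments)))
    stop("segments must have columns t_start, t_end, dose_rate")
  if (nrow(segments) == 0L) stop("a schedule needs at least one segment")
  segments <- segments[order(segments$t_start), req]
  if (any(segments$t_end <= segments$t_start))
    stop("every segment must have t_end > t_start")
  if (any(segments$dose_rate < 0)) stop("dose rates must be non-negative")
  if (nrow(segments) > 1L) {
    gap <- segments$t_start[-1L] - segments$t_end[-nrow(segments)]
    if (any(gap < -1e-12)) stop("segments must not overlap")
  }
  total <- sum(segments$dose_rate * (segments$t_end - segments$t_start))
  if (total <= 0) stop("schedule must deliver a positive total dose")
  structure(
    list(segments = segments, label = label, meta = meta),
    class = "dose_schedule"
  )
}

#' Single acute exposure
#'
#' @param dose total dose in Gy (> 0).
#' @param dose_rate instantaneous dose rate in Gy/min (> 0).
#' @param label regimen label.
#' @return A `dose_schedule` with one segment of duration `dose/dose_rate`.
#' @examples
#' s <- acute_schedule(1, 1.82)
#' delivery_time(s) * 3600  # seconds
#' @export
acute_schedule <- function(dose, dose_rate, label = sprintf("acute %.3g Gy/min", dose_rate)) {
  if (!is.numeric(dose) || length(dose) != 1L || dose <= 0)
    stop("dose must be a single positive number (Gy)")
  if (!is.numeric(dose_rate) || length(dose_rate) != 1L || dose_rate <= 0)
    stop("dose_rate must be a single positive number (Gy/min)")
  rate_h <- .gy_min_to_gy_h(dose_rate)
  dose_schedule(
    data.frame(t_start = 0, t_end = dose / rate_h, dose_rate = rate_h),
    label = label, meta = list(type = "acute")
  )
}

#' Continuous low-dose-rate exposure
#'
#' Identical in structure to [acute_schedule()]; kept separate because the two
#' delivery modes come from different sources (pulsed X-ray tube vs. a
#' radionuclide gamma source) and are labelled differently in reports.
#'
#' @inheritParams acute_schedule
#' @export
continuous_schedule <- function(dose, dose_rate,
                                label = sprintf("continuous %.3g Gy/min", dose_rate)) {
  s <- acute_schedule(dose, dose_rate, label = label)
  s$meta$type <- "continuous"
  s
}

#' Fractionated exposure train
#'
#' Fractions are laid out start-to-start: fraction i begins at
#' `(i-1) * interval_s`. With 0.2 Gy per fraction every 120 s this yields the
#' nominal average dose rate 0.1 Gy/min; with 0.05 Gy every 90 s, 0.033 Gy/min.
#'
#' @param dose_per_fraction dose per fraction in Gy.
#' @param n_fractions number of fractions (positive integer).
#' @param interval_s start-to-start interval in seconds.
#' @param dose_rate instantaneous (within-fraction) dose rate in Gy/min.
#' @param label regimen label.
#' @return A `dose_schedule` with `n_fractions` segments.
#' @export
fractionated_schedule <- function(dose_per_fraction, n_fractions, interval_s,
                                  dose_rate = 1.82,
                                  label = sprintf("%g Gy/Fr @ %g s", dose_per_fraction, interval_s)) {
  if (dose_per_fraction <= 0 || n_fractions < 1 || interval_s <= 0 || dose_rate <= 0)
    stop("all fractionation parameters must be positive")
  n_fractions <- as.integer(n_fractions)
  rate_h <- .gy_min_to_gy_h(dose_rate)
  delivery_h <- dose_per_fraction / rate_h
  interval_h <- interval_s / 3600
  if (delivery_h > interval_h + 1e-12)
    stop("per-fraction delivery time exceeds the start-to-start interval")
  t0 <- (seq_len(n_fractions) - 1L) * interval_h
  dose_schedule(
    data.frame(t_start = t0, t_end = t0 + delivery_h, dose_rate = rate_h),
    label = label,
    meta = list(type = "fractionated", n_fractions = n_fractions,
                interval_h = interval_h, dose_per_fraction = dose_per_fraction)
  )
}

#' Total dose of a schedule (Gy)
#' @param s a `dose_schedule`.
#' @export
total_dose <- function(s) {
  stopifnot(inherits(s, "dose_schedule"))
  with(s$segments, sum(dose_rate * (t_end - t_start)))
}

#' Delivery time of a schedule (hours)
#'
#' @param s a `dose_schedule`.
#' @param span `"actual"` (first segment start to last segment end) or
#'   `"nominal"` (`n_fractions * interval` for fraction trains, so that
#'   dose / nominal span equals the quoted average dose rate).
#' @export
delivery_time <- function(s, span = c("actual", "nominal")) {
  stopifnot(inherits(s, "dose_schedule"))
  span <- match.arg(span)
  if (span == "nominal" && identical(s$meta$type, "fractionated"))
    return(s$meta$n_fractions * s$meta$interval_h)
  max(s$segments$t_end) - min(s$segments$t_start)
}

#' Time-averaged dose rate of a schedule
#'
#' @inheritParams delivery_time
#' @param units output units, `"Gy/min"` (default) or `"Gy/h"`.
#' @export
average_dose_rate <- function(s, span = c("nominal", "actual"),
                              units = c("Gy/min", "Gy/h")) {
  span <- match.arg(span)
  units <- match.arg(units)
  rate_h <- total_dose(s) / delivery_time(s, span = span)
  if (units == "Gy/min") .gy_h_to_gy_min(rate_h) else rate_h
}

#' Observation timepoint relative to a schedule
#'
#' Early focus counts are anchored to the end of irradiation, late residual
#' counts to its start; a timepoint carries its reference explicitly so both
#' can live on one absolute clock.
#'
#' @param offset_h non-negative offset in hours.
#' @param reference `"after_start"` or `"after_end"`.
#' @export
timepoint <- function(offset_h, reference = c("after_start", "after_end")) {
  reference <- match.arg(reference)
  if (!is.numeric(offset_h) || length(offset_h) != 1L || offset_h < 0)
    stop("offset_h must be a single non-negative number")
  structure(list(offset_h = offset_h, reference = reference), class = "imk_timepoint")
}

#' Absolute time of a timepoint on a schedule's clock (hours from start)
#'
#' @param s a `dose_schedule`.
#' @param tp an [timepoint()] object.
#' @export
absolute_time <- function(s, tp) {
  stopifnot(inherits(s, "dose_schedule"), inherits(tp, "imk_timepoint"))
  if (tp$reference == "after_start") tp$offset_h
  else delivery_time(s, span = "actual") + tp$offset_h
}

#' Constant-rate surrogate of a schedule
#'
#' Replaces the schedule by a single segment with the same total dose and the
#' same (nominal) span, at the average dose rate. This is the continuous-limit
#' surrogate under which fraction trains behave like intermediate-dose-rate
#' exposures.
#'
#' @param s a `dose_schedule`.
#' @export
equivalent_continuous <- function(s) {
  stopifnot(inherits(s, "dose_schedule"))
  if (nrow(s$segments) == 1L) return(s)
  span <- delivery_time(s, span = "nominal")
  t0 <- min(s$segments$t_start)
  dose_schedule(
    data.frame(t_start = t0, t_end = t0 + span, dose_rate = total_dose(s) / span),
    label = paste(s$label, "(continuous surrogate)"),
    meta = list(type = "continuous")
  )
}

#' @export
print.dose_schedule <- function(x, ...) {
  cat(sprintf("Dose schedule: %s\n", x$label))
  cat(sprintf("  segments: %d, total dose %.4g Gy, span %.4g h, average rate %.4g Gy/min\n",
              nrow(x$segments), total_dose(x),
              delivery_time(x), average_dose_rate(x)))
  invisible(x)
}

#' Serialize a schedule to JSON
#'
#' @param s a `dose_schedule`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
schedule_to_json <- function(s, path = NULL) {
  stopifnot(inherits(s, "dose_schedule"))
  obj <- list(
    label = s$label,
    segments = data.frame(
      t_start_h = s$segments$t_start,
      t_end_h = s$segments$t_end,
      dose_rate_Gy_per_h = s$segments$dose_rate
    )
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a schedule from JSON
#'
#' Accepts either the segment form written by [schedule_to_json()] or a
#' convenience form `{"type": "acute"|"continuous"|"fractionated", ...}` with
#' the corresponding constructor arguments (doses in Gy, rates in Gy/min,
#' intervals in seconds).
#'
#' @param x a JSON string or a path to a JSON file.
#' @export
schedule_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  if (!is.null(obj$type)) {
    return(switch(obj$type,
      acute = acute_schedule(obj$dose, obj$dose_rate,
                             label = obj$label %||% "acute"),
      continuous = continuous_schedule(obj$dose, obj$dose_rate,
                                       label = obj$label %||% "continuous"),
      fractionated = fractionated_schedule(obj$dose_per_fraction, obj$n_fractions,
                                           obj$interval_s,
                                           dose_rate = obj$dose_rate %||% 1.82,
                                           label = obj$label %||% "fractionated"),
      stop("unknown schedule type: ", obj$type)
    ))
  }
  seg <- obj$segments
  dose_schedule(
    data.frame(t_start = seg$t_start_h, t_end = seg$t_end_h,
               dose_rate = seg$dose_rate_Gy_per_h),
    label = obj$label %||% "schedule"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
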