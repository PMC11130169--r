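# fitted parameter sets used throughout; derive_rates = TRUE re-derives a and
# b from (alpha0, beta0, a_plus_c, k_N) so kinetics and survival closed forms
# are exactly consistent (the shipped table's a, b are rounded to 3 digits)
hlec <- function(consistent = TRUE) imk_cell_lines("HLEC", derive_rates = consistent)
wi38 <- function(consistent = TRUE) imk_cell_lines("WI-38", derive_rates = consistent)

acute_1gy <- function() acute_schedule(1, 1.82)

repair_timepoints <- function() lapply(c(0.5, 1, 2.5, 6, 24, 48), timepoint)

# noise-free mean-foci table following a pure exponential decay
exp_decay_means <- function(k_N, c, dose = 1, times = c(0.5, 1, 2.5, 6, 24, 48)) {
  data.frame(time_h = times, mean_foci = k_N * dose * exp(-c * times))
}
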