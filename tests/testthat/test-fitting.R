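test_that("the exponential repair fit is exact on noise-free decay data", {
  means <- exp_decay_means(40.6, 0.309)
  rf <- fit_repair_rate(means, dose = 1)
  expect_equal(rf$k_N, 40.6, tolerance = 1e-6)
  expect_equal(rf$c, 0.309, tolerance = 1e-6)
  expect_gt(rf$r_squared, 0.999999)

  # scaling by dose: amplitude 81.2 over 2 Gy is still k_N = 40.6
  means2 <- exp_decay_means(40.6, 0.309, dose = 2)
  expect_equal(fit_repair_rate(means2, dose = 2)$k_N, 40.6, tolerance = 1e-6)

  expect_error(fit_repair_rate(means[1:2, ]), "3 distinct timepoints")
  zero <- data.frame(time_h = c(1, 2, 3), mean_foci = 0)
  expect_error(fit_repair_rate(zero), "zero")
})

test_that("the repair fit recovers the rate from Poisson focus counts", {
  p <- hlec()
  foci <- gen_foci(p, acute_1gy(), repair_timepoints(), n_cells = 100,
                   lambda0 = 0.5, seed = 7)
  rf <- fit_repair_rate(foci, dose = 1, background = 0.5)
  c_true <- p$a_plus_c - p$a  # the repair component of the removal rate
  expect_lt(abs(rf$c - c_true), 2 * rf$sd[["c"]])
  expect_lt(abs(rf$k_N - p$k_N) / p$k_N, 0.1)
  # offset variant absorbs background + residual lesions
  rf2 <- fit_repair_rate(foci, dose = 1, offset = TRUE)
  expect_gt(rf2$offset, 0)
  expect_lt(abs(rf2$c - c_true), 3 * rf2$sd[["c"]])
})

test_that("the survival log-likelihood matches a direct evaluation", {
  p <- hlec(consistent = FALSE)
  d <- data.frame(dose_Gy = c(2, 4), sf = c(0.30, 0.08))
  sig <- 0.1
  # independent one-line evaluation of the Gaussian product on -ln S
  w_cal <- vapply(c(2, 4), function(D) {
    T <- D / (1.82 * 60)
    (0.559 + 0.954 * 0.0175) * D + lea_catcheside_F(0.309, T) * 0.0175 * D^2
  }, numeric(1))
  by_hand <- sum(-log(sig * sqrt(2 * pi)) - (-log(d$sf) + log(exp(-w_cal)))^2 / (2 * sig^2))
  got <- log_likelihood(c(0.559, 0.0175, 0.309), d, gamma = 0.954,
                        sigma = sigma_policy("fixed", 0.1))
  expect_equal(got, by_hand, tolerance = 1e-12)

  # a perfect fit leaves only the normalisation term
  d2 <- data.frame(dose_Gy = c(2, 4), sf = exp(-w_cal))
  got2 <- log_likelihood(c(0.559, 0.0175, 0.309), d2, gamma = 0.954,
                         sigma = sigma_policy("fixed", 0.1))
  expect_equal(got2, 2 * (-log(sig * sqrt(2 * pi))), tolerance = 1e-12)

  # doubling the residuals costs four times the quadratic term
  d3 <- data.frame(dose_Gy = c(2, 4), sf = exp(-(w_cal + 0.1)))
  d4 <- data.frame(dose_Gy = c(2, 4), sf = exp(-(w_cal + 0.2)))
  q3 <- got2 - log_likelihood(c(0.559, 0.0175, 0.309), d3, 0.954,
                              sigma_policy("fixed", 0.1))
  q4 <- got2 - log_likelihood(c(0.559, 0.0175, 0.309), d4, 0.954,
                              sigma_policy("fixed", 0.1))
  expect_equal(q4, 4 * q3, tolerance = 1e-9)

  expect_error(log_likelihood(c(0.5, 0.02, 0.3),
                              data.frame(dose_Gy = 2, sf = -1), 0.954,
                              sigma_policy("fixed", 0.1)),
               "positive")
})

test_that("the Metropolis chain is deterministic and stays in support", {
  p <- hlec()
  sv <- gen_survival(p, cv = 0.1, seed = 5)
  rf <- list(mean = 0.305, sd = 0.02)
  a <- mcmc_fit_survival(sv, 0.954, rf, seed = 99)
  b <- mcmc_fit_survival(sv, 0.954, rf, seed = 99)
  expect_identical(a$samples, b$samples)
  d <- mcmc_fit_survival(sv, 0.954, rf, seed = 100)
  expect_false(identical(a$samples, d$samples))
  expect_true(all(a$samples[, "alpha0"] > 0 & a$samples[, "alpha0"] < 5))
  expect_true(all(a$samples[, "beta0"] > 0 & a$samples[, "beta0"] < 1))
  expect_true(all(a$samples[, "a_plus_c"] > 0))
  expect_gt(a$acceptance_rate, 0)
  expect_lt(a$acceptance_rate, 1)
  expect_equal(nrow(a$samples), 10000L)
})

test_that("the posterior concentrates on the truth for near-noise-free data", {
  p <- hlec()
  doses <- c(2, 4, 6, 10)
  sf <- vapply(doses, function(D)
    surviving_fraction(acute_schedule(D, 1.82), p), numeric(1))
  d <- data.frame(dose_Gy = doses, sf = sf)
  post <- mcmc_fit_survival(d, gamma = p$gamma,
                            prior_c = list(mean = p$a_plus_c, sd = 0.02),
                            sigma = sigma_policy("fixed", 0.01), seed = 3)
  cf <- post$summaries
  for (par in c("alpha0", "beta0", "a_plus_c")) {
    truth <- switch(par, alpha0 = p$alpha0, beta0 = p$beta0,
                    a_plus_c = p$a_plus_c)
    expect_lt(abs(cf$mean[cf$parameter == par] - truth),
              2 * cf$sd[cf$parameter == par] + 0.02 * truth)
  }
})

test_that("with a flat likelihood the chain reproduces the uniform prior", {
  # two survival points with enormous sigma: the likelihood is flat, so the
  # alpha0 marginal must converge to its uniform prior (detailed balance)
  d <- data.frame(dose_Gy = c(2, 4, 6), sf = c(0.3, 0.1, 0.02), se = 1e6)
  post <- mcmc_fit_survival(d, gamma = 0.954,
                            prior_c = list(mean = 0.3, sd = 0.05),
                            sigma = sigma_policy("se"),
                            control = mcmc_control(burn_in = 2000,
                                                   n_samples = 10000),
                            seed = 17)
  # thin heavily: a random walk on a flat target is strongly autocorrelated
  thinned <- post$samples[seq(1, 10000, by = 100), "alpha0"]
  ks <- stats::ks.test(thinned, "punif", 0, 5)
  expect_gt(ks$p.value, 0.01)
})

test_that("posterior-derived microscopic rates agree with the inversion", {
  p <- wi38()
  sv <- gen_survival(p, cv = 0.1, seed = 21)
  post <- mcmc_fit_survival(sv, p$gamma, list(mean = 0.365, sd = 0.02), seed = 21)
  out <- derive_micro_params(post, list(mean = 38.4, sd = 1.7))
  cf <- coef(post)
  direct <- micro_from_alpha0_beta0(38.4, cf[["alpha0"]], cf[["beta0"]],
                                    cf[["a_plus_c"]])
  expect_equal(out$a, direct$a)
  expect_equal(out$b, direct$b)
  expect_gt(out$sd[["a"]], 0)
  expect_gt(out$sd[["b"]], 0)
})

test_that("r_squared matches hand arithmetic and rejects degenerate input", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1.1, 1.9, 3.2)), 1 - 0.06 / 2)
  # common affine rescaling of both series preserves R^2
  obs <- c(1, 2, 3); cal <- c(1.1, 1.9, 3.2)
  expect_equal(r_squared(10 * obs + 5, 10 * cal + 5), r_squared(obs, cal))
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(r_squared(1, 1), "at least 2")
})

test_that("posterior-predictive bands behave at the edges", {
  p <- hlec()
  sv <- gen_survival(p, cv = 0.1, seed = 31)
  post <- mcmc_fit_survival(sv, p$gamma, list(mean = 0.305, sd = 0.02), seed = 31)
  # survival at zero dose is exactly 1 for every draw
  band0 <- prediction_band(post, function(th) exp(-imkfit:::.w_model(
    th[c("alpha0", "beta0", "a_plus_c")], 0, p$gamma, 1.82)))
  expect_equal(band0$lo, 1)
  expect_equal(band0$hi, 1)
  # degenerate posterior gives a zero-width band
  post0 <- post
  post0$samples <- post$samples[rep(1, 50), ]
  band <- prediction_band(post0, function(th) th[["alpha0"]])
  expect_equal(band$lo, band$hi)
  # band width grows monotonically with posterior spread
  postw <- post
  postw$samples[, "alpha0"] <- coef(post)[["alpha0"]] +
    2 * (post$samples[, "alpha0"] - coef(post)[["alpha0"]])
  b1 <- prediction_band(post, function(th) th[["alpha0"]])
  b2 <- prediction_band(postw, function(th) th[["alpha0"]])
  expect_gt(b2$hi - b2$lo, b1$hi - b1$lo)
})

test_that("sigma policies resolve as documented", {
  p <- hlec()
  sv <- gen_survival(p, cv = 0.1, seed = 41)
  # raw counts present: auto resolves to counting
  post <- mcmc_fit_survival(sv, p$gamma, list(mean = 0.3, sd = 0.02), seed = 41)
  expect_equal(post$sigma_mode, "counting")
  # aggregated data with SEs: auto resolves to per-point SE
  ss <- summarize_survival(sv)
  post2 <- mcmc_fit_survival(ss, p$gamma, list(mean = 0.3, sd = 0.02), seed = 41)
  expect_equal(post2$sigma_mode, "se")
  # no se, no counts: fixed
  ss2 <- ss[, c("dose_Gy", "sf")]
  post3 <- mcmc_fit_survival(ss2, p$gamma, list(mean = 0.3, sd = 0.02), seed = 41)
  expect_equal(post3$sigma_mode, "fixed")
  # fitted mode samples sigma as a parameter
  post4 <- mcmc_fit_survival(ss2, p$gamma, list(mean = 0.3, sd = 0.02),
                             sigma = sigma_policy("fitted"), seed = 41)
  expect_true("sigma" %in% colnames(post4$samples))
  expect_true(all(post4$samples[, "sigma"] > 0))
})
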