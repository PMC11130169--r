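test_that("gamma follows from lineal energy and domain geometry", {
  # invert gamma = y_D/(rho pi r^2): 0.954 Gy corresponds to y_D ~ 4.677 keV/um
  y_D <- 0.954 * pi * 0.25 / 0.1602176634
  expect_equal(gamma_from_microdosimetry(y_D), 0.954, tolerance = 1e-12)
  expect_equal(gamma_from_microdosimetry(4.677), 0.954, tolerance = 1e-3)
  # inverse-square dependence on the domain radius
  expect_equal(gamma_from_microdosimetry(4.677, r_d = 1),
               gamma_from_microdosimetry(4.677, r_d = 0.5) / 4)
  expect_error(gamma_from_microdosimetry(0), "positive")
})

test_that("PLL counts follow the exponential-removal closed form", {
  p <- hlec()
  s <- acute_1gy()
  Td <- delivery_time(s)
  # during-delivery and post-delivery branches against hand-evaluated forms
  rate_h <- 1.82 * 60
  t_in <- Td / 2
  expect_equal(pll_expected(t_in, s, p),
               p$k_N * rate_h / p$a_plus_c * (1 - exp(-p$a_plus_c * t_in)),
               tolerance = 1e-12)
  t_out <- 24
  expect_equal(pll_expected(t_out, s, p),
               p$k_N * rate_h / p$a_plus_c *
                 (1 - exp(-p$a_plus_c * Td)) * exp(-p$a_plus_c * (t_out - Td)),
               tolerance = 1e-12)
  # ~ k_N D exp(-(a+c) t) for an effectively instantaneous 1 Gy
  expect_equal(pll_expected(24, s, p), 40.6 * exp(-0.309 * 24), tolerance = 0.005)
  # just after delivery the full initial yield is present
  expect_equal(pll_expected(Td, s, p), p$k_N * 1, tolerance = 0.002)
  expect_error(pll_expected(-1, s, p), "non-negative")
})

test_that("discrete fraction trains converge to the constant-rate limit", {
  p <- hlec()
  # single instantaneous fraction: k_N D exp(-(a+c) t)
  expect_equal(pll_discrete(c(1, 5, 24), 0, 1, p),
               p$k_N * exp(-p$a_plus_c * c(1, 5, 24)), tolerance = 1e-12)
  # fractions delivered after t contribute nothing
  expect_equal(pll_discrete(1, c(0, 2), c(0.5, 0.5), p),
               pll_discrete(1, 0, 0.5, p))
  # N = 1000 equal fractions over T vs the constant-rate closed form
  # (midpoint delivery times: the natural discretization of the convolution)
  Tspan <- 10
  N <- 1000
  times <- (seq_len(N) - 0.5) * Tspan / N
  doses <- rep(1 / N, N)
  s <- continuous_schedule(1, 1 / Tspan / 60)
  probes <- c(0.5, 1, 2, 4, 6, 8, 9.99, 12, 24, 48)
  x_disc <- pll_discrete(probes, times, doses, p)
  x_cont <- pll_expected(probes, s, p)
  expect_lt(max(abs(x_disc - x_cont) / x_cont), 1e-3)
})

test_that("LL accrual matches the closed-form survival plateau", {
  # the quadrature plateau and the protraction-factor closed form must agree:
  # this validates the F factor and the intra-track kernel simultaneously
  for (p in list(hlec(), wi38())) {
    for (T_h in c(1 / 3600, 0.1, 3.6, 20.6)) {
      s <- continuous_schedule(1, 1 / T_h / 60)
      w_quad <- ll_plateau(s, p)
      w_closed <- neg_log_survival(s, p)
      expect_lt(abs(w_quad - w_closed) / w_closed, 1e-6)
    }
  }
})

test_that("first-order-only plateau is alpha0 * D exactly", {
  p0 <- hlec()
  # b = 0: keep alpha0 consistent, beta0 must then be ~0 (use tiny epsilon)
  p <- cell_params(k_N = p0$k_N, a_plus_c = p0$a_plus_c, alpha0 = p0$alpha0,
                   beta0 = 1e-12, gamma = p0$gamma, cell_line = "b0")
  s <- continuous_schedule(2, 0.05)
  expect_equal(ll_plateau(s, p), p$alpha0 * 2, tolerance = 1e-6)
})

test_that("foci counts start at zero, jump to k_N D, and split into PLL + LL", {
  p <- hlec()
  s <- acute_1gy()
  expect_equal(foci_expected(0, s, p), 0)
  Td <- delivery_time(s)
  expect_equal(foci_expected(Td, s, p), p$k_N * 1, tolerance = 0.01)
  # 0.5 h after the end of delivery: mostly surviving PLLs plus a small LL term
  f <- foci_expected(Td + 0.5, s, p)
  expect_equal(f, 34.8, tolerance = 0.01)
  expect_gt(f, pll_expected(Td + 0.5, s, p))
  # WI-38 at 24 h: PLLs are gone and the LL plateau remains
  pw <- wi38()
  f24 <- foci_expected(24, acute_1gy(), pw)
  expect_equal(f24, ll_plateau(acute_1gy(), pw), tolerance = 0.02)
  expect_equal(f24, 0.62, tolerance = 0.05)
})

test_that("lesion curves are non-negative with non-decreasing LLs", {
  p <- wi38()
  for (s in list(acute_1gy(), fractionated_schedule(0.2, 5, 120),
                 continuous_schedule(1, 0.00461))) {
    cur <- lesion_curve(s, p, times = c(0.1, 0.5, 1, 2, 5, 10, 24, 48))
    expect_true(all(cur$pll >= 0))
    expect_true(all(cur$ll >= 0))
    expect_true(all(diff(cur$ll) >= -1e-10))
    expect_equal(cur$foci, cur$pll + cur$ll)
  }
})

test_that("the Lea-Catcheside factor has the right limits and monotonicity", {
  expect_identical(lea_catcheside_F(0.309, 0), 1)
  # hand arithmetic at x = (a+c) T = 6.358
  x <- 0.309 * 20.576
  expect_equal(lea_catcheside_F(0.309, 20.576),
               2 / x^2 * (x + exp(-x) - 1), tolerance = 1e-12)
  expect_equal(lea_catcheside_F(0.309, 20.576), 0.2652, tolerance = 1e-3)
  Ts <- c(0.01, 0.1, 1, 5, 20, 100)
  Fv <- lea_catcheside_F(0.371, Ts)
  expect_true(all(diff(Fv) < 0))
  expect_true(all(Fv > 0 & Fv <= 1))
  # series branch continuous with the closed form at the crossover
  expect_equal(lea_catcheside_F(1, 0.99e-3), lea_catcheside_F(1, 1.01e-3),
               tolerance = 1e-5)
  expect_error(lea_catcheside_F(-1, 1), "positive")
})

test_that("survival follows the protracted linear-quadratic form", {
  p <- hlec(consistent = FALSE)  # printed table values
  s2 <- acute_schedule(2, 1.82)
  T2 <- 2 / (1.82 * 60)
  w_hand <- (0.559 + 0.954 * 0.0175) * 2 +
    lea_catcheside_F(0.309, T2) * 0.0175 * 4
  expect_equal(neg_log_survival(s2, p), w_hand, tolerance = 1e-12)
  expect_equal(exp(-w_hand), 0.295, tolerance = 0.002)
  expect_equal(surviving_fraction(s2, p), exp(-w_hand))
  # dose mismatch is an error
  expect_error(neg_log_survival(s2, p, dose = 3), "does not match")
  # protraction can only spare: at fixed dose, longer delivery, higher S
  rates <- c(1.82, 0.1, 0.033, 0.00461, 0.00081)
  sf <- vapply(rates, function(r) surviving_fraction(acute_schedule(2, r), p),
               numeric(1))
  expect_true(all(diff(sf) > 0))
})

test_that("survival coefficients and microscopic rates are mutually inverse", {
  ab <- alpha0_beta0_from_micro(k_N = 38.4, a = 5.59e-3, b = 8.17e-6,
                                a_plus_c = 0.371)
  expect_equal(ab[["alpha0"]], 0.579, tolerance = 2e-3)
  expect_equal(ab[["beta0"]], 8.17e-6 * 38.4^2 / (2 * 0.371), tolerance = 1e-12)
  expect_equal(alpha0_beta0_from_micro(38.4, 0, 1e-6, 0.371)[["alpha0"]], 0)

  inv <- micro_from_alpha0_beta0(k_N = 40.6, alpha0 = 0.559, beta0 = 0.0175,
                                 a_plus_c = 0.309)
  expect_equal(inv$a, 4.25e-3, tolerance = 2e-3)
  expect_equal(inv$b, 2 * 0.0175 * 0.309 / 40.6^2, tolerance = 1e-12)
  expect_equal(inv$sd, c(a = 0, b = 0))

  # round trip is the identity to machine precision
  back <- alpha0_beta0_from_micro(40.6, inv$a, inv$b, 0.309)
  expect_equal(back[["alpha0"]], 0.559, tolerance = 1e-14)
  expect_equal(back[["beta0"]], 0.0175, tolerance = 1e-14)

  # delta-method SDs scale linearly in the input SDs
  s1 <- micro_from_alpha0_beta0(40.6, 0.559, 0.0175, 0.309,
                                sd = list(alpha0 = 0.1))
  s2 <- micro_from_alpha0_beta0(40.6, 0.559, 0.0175, 0.309,
                                sd = list(alpha0 = 0.2))
  expect_equal(s2$sd[["a"]], 2 * s1$sd[["a"]])
})

test_that("cell_params validates and derives missing microscopic rates", {
  expect_error(cell_params(k_N = -1, a_plus_c = 0.3, alpha0 = 0.5,
                           beta0 = 0.02, gamma = 0.954), "positive")
  # inconsistent alpha0 triggers the rounding warning
  expect_warning(cell_params(k_N = 40, a_plus_c = 0.3, alpha0 = 0.5,
                             beta0 = 0.02, gamma = 0.954, a = 0.01, b = 7.5e-6),
                 "alpha0 is inconsistent")
  p <- cell_params(k_N = 40, a_plus_c = 0.3, alpha0 = 0.5, beta0 = 0.02,
                   gamma = 0.954)
  expect_equal(p$a, 0.5 * 0.3 / 40)
  expect_equal(p$b, 2 * 0.02 * 0.3 / 40^2)
  both <- imk_cell_lines()
  expect_named(both, c("WI-38", "HLEC"))
  expect_equal(both[["HLEC"]]$k_N, 40.6)
})
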