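test_that("log-normal DMR identities hold to near machine precision", {
  d <- lognormal_dmr(-25.20, 1.72)
  expect_equal(dmr_mean(d), exp(d$mu + d$sigma^2 / 2), tolerance = 1e-12)
  expect_equal(dmr_median(d), exp(d$mu), tolerance = 1e-12)
  expect_equal(dmr_mode(d), exp(d$mu - d$sigma^2), tolerance = 1e-12)
  expect_equal(dmr_cv(d), sqrt(exp(d$sigma^2) - 1), tolerance = 1e-12)
  expect_true(dmr_mode(d) < dmr_median(d))
  expect_true(dmr_median(d) < dmr_mean(d))

  d0 <- lognormal_dmr(-23, 0)
  expect_equal(dmr_mode(d0), dmr_mean(d0))

  td <- tidy(d)
  expect_equal(td$cv, dmr_cv(d))
  expect_error(lognormal_dmr(0, -1), class = "mutpie_error_invalid_input")
})

test_that("mean-parameterized construction round-trips (WS calibration)", {
  d <- dmr_from_mean_sigma(5e-11, 1.72)
  expect_equal(d$mu, -25.20, tolerance = 0.01 / 25)
  expect_equal(dmr_mean(d), 5e-11, tolerance = 1e-12)
  expect_equal(dmr_median(d), 1.14e-11, tolerance = 0.01)
  expect_equal(dmr_mode(d), 5.90e-13, tolerance = 0.01)

  d0 <- dmr_from_mean_sigma(3, 0)
  expect_equal(d0$mu, log(3))
  expect_error(dmr_from_mean_sigma(0, 1), class = "mutpie_error_invalid_input")
})

test_that("rate sampling matches the requested family's moments", {
  d <- dmr_from_mean_sigma(5e-11, 1.72)

  d0 <- lognormal_dmr(-23, 0)
  expect_equal(sample_rates(d0, 5), rep(exp(-23), 5),
               ignore_attr = TRUE)

  set.seed(301)
  r <- sample_rates(d, 1e5)
  expect_true(all(r > 0))
  # the sample CV of very heavy-tailed log-normals converges too slowly to
  # check at sigma 1.72; verify the closed-form CV where moments behave
  d1 <- dmr_from_mean_sigma(5e-11, 1)
  set.seed(311)
  r1 <- sample_rates(d1, 1e5)
  expect_equal(sd(r1) / mean(r1), dmr_cv(d1), tolerance = 0.05)

  set.seed(302)
  g <- sample_rates(d, 1e5, family = "gamma")
  expect_true(all(g >= 0))
  expect_equal(mean(g), dmr_mean(d), tolerance = 3 * sd(g) / sqrt(1e5) / dmr_mean(d))

  expect_type(attr(r, "n_implausible"), "integer")
})

test_that("sampled MPCs depend on sigma only, never on mu", {
  d0 <- lognormal_dmr(-40, 0)
  expect_equal(unevenness(sample_mpc(d0, 10)), 0)

  set.seed(303); a <- sample_mpc(lognormal_dmr(-25, 1.7), 50)
  set.seed(303); b <- sample_mpc(lognormal_dmr(-10, 1.7), 50)
  expect_equal(a$share, b$share, tolerance = 1e-12)

  set.seed(304); ua <- unevenness_distribution(lognormal_dmr(-25, 2), 20, 2000)
  set.seed(304); ub <- unevenness_distribution(lognormal_dmr(5, 2), 20, 2000)
  expect_equal(ua, ub)
})

test_that("unevenness distributions shift up with sigma and match the asymptote", {
  d0 <- lognormal_dmr(-25, 0)
  u0 <- unevenness_distribution(d0, 100, 500)
  expect_equal(u0$median, 0)
  expect_equal(u0$q97_5, 0)

  set.seed(305)
  meds <- sapply(c(0.5, 1, 2, 3), function(s) {
    unevenness_distribution(lognormal_dmr(-25, s), 30, 3000)$median
  })
  expect_true(all(diff(meds) > 0))

  # large-n asymptote: median U ~ sigma^2 / (2 ln n)
  set.seed(306)
  med <- unevenness_distribution(lognormal_dmr(-25.15, 1.69), 500, 4000)$median
  expect_equal(med, 1.69^2 / (2 * log(500)), tolerance = 0.2)
})

test_that("TMR distributions obey the closed-form moments and the CLT", {
  d <- dmr_from_mean_sigma(5e-11, 1.72)

  set.seed(307)
  t1 <- tmr_distribution(d, 500, 2e4)
  expect_equal(t1$mean, 500 * 5e-11,
               tolerance = 3 * t1$sd / sqrt(2e4) / (500 * 5e-11))
  expect_equal(mean(t1$standardized), 0, tolerance = 1e-10)
  expect_equal(sd(t1$standardized), 1, tolerance = 1e-10)

  # n = 1 skewness oracle, at a dispersion where the estimator converges
  dn <- dmr_from_mean_sigma(1e-10, 0.5)
  set.seed(308)
  tn <- tmr_distribution(dn, 1, 1e5)
  skew_oracle <- (exp(0.25) + 2) * sqrt(exp(0.25) - 1)
  expect_equal(tn$skewness, skew_oracle, tolerance = 0.15)

  # aggregation symmetrizes: skewness falls as sites accumulate,
  # and reaches the near-normal regime at moderate dispersion
  set.seed(309)
  s1 <- tmr_distribution(d, 1, 2e4)$skewness
  s100 <- tmr_distribution(d, 100, 2e4)$skewness
  expect_lt(s100, s1)
  set.seed(310)
  z <- tmr_distribution(dmr_from_mean_sigma(1e-10, 1), 1000, 2e4)
  expect_lt(abs(z$skewness), 0.5)
})

test_that("TMR asymptotics follow Table-4 scalings", {
  d <- dmr_from_mean_sigma(5e-11, 1.72)
  a1 <- tmr_asymptotics(d, 1)
  expect_equal(a1$mean, dmr_mean(d))
  expect_equal(a1$cv, dmr_cv(d))

  a500 <- tmr_asymptotics(d, 500)
  expect_equal(a500$mean, 2.5e-8)
  expect_equal(a500$median_limit, a500$mean)
  # cv halves when n quadruples
  expect_equal(tmr_asymptotics(d, 400)$cv / tmr_asymptotics(d, 100)$cv, 0.5)
})

test_that("parallel-evolution probability is exp(sigma^2)/n with a clamp", {
  expect_equal(as.numeric(prob_parallel(0, 4)), 0.25)
  expect_equal(as.numeric(suppressWarnings(prob_parallel(sqrt(log(7)), 7))),
               1, tolerance = 1e-12)
  expect_warning(p <- prob_parallel(2, 3), class = "mutpie_warning_clamped")
  expect_equal(as.numeric(p), 1)
  expect_true(attr(p, "clamped"))
  # monotone: decreasing in n, increasing in sigma
  grid_n <- sapply(c(2, 4, 8, 64), function(n) prob_parallel(0.5, n))
  expect_true(all(diff(grid_n) < 0))
  grid_s <- sapply(c(0, 0.5, 1), function(s) prob_parallel(s, 100))
  expect_true(all(diff(grid_s) > 0))
})
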