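test_that("even-case closed forms match harmonic-sum oracles", {
  expect_equal(expected_completion_even(1), 1)
  expect_equal(expected_completion_even(16), 16 * harmonic(16))
  expect_equal(expected_completion_even(16), oracle_even_mean(16))
  expect_equal(expected_completion_even(50), 224.96, tolerance = 1e-4)
  expect_equal(round(expected_completion_even(50)), 225)

  expect_equal(sd_completion_even(1), 0)
  expect_equal(sd_completion_even(2), sqrt(4 * 1.25 - 3))
  expect_equal(sd_completion_even(50), 61.95, tolerance = 1e-3)
  expect_equal(round(sd_completion_even(50)), 62)

  # approximations close in on the exact values as m grows
  for (m in c(10, 25, 50, 200)) {
    expect_lt(abs(expected_completion_even(m) -
                    expected_completion_even(m, exact = FALSE)), 0.1)
    expect_lt(abs(sd_completion_even(m) -
                    sd_completion_even(m, exact = FALSE)), 0.5)
  }
  expect_warning(sd_completion_even(1, exact = FALSE),
                 "radicand")
  expect_error(expected_completion_even(0),
               class = "mutpie_error_invalid_input")
})

test_that("expected_additional is the geometric mean wait", {
  expect_equal(expected_additional(50, 40), 5)
  expect_equal(expected_additional(2, 1), 2)
  for (m in c(3, 17)) expect_equal(expected_additional(m, 0), 1)
  expect_error(expected_additional(5, 5),
               class = "mutpie_error_invalid_input")
})

test_that("the completion integral agrees with independent closed forms", {
  # even case: harmonic sum
  expect_equal(expected_completion_general(rep(1, 16)),
               16 * harmonic(16), tolerance = 1e-4)
  # two coupons: 1/p + 1/q - 1
  expect_equal(expected_completion_general(c(0.996, 0.004)),
               1 / 0.996 + 1 / 0.004 - 1, tolerance = 1e-4)
  expect_equal(expected_completion_general(c(0.75, 0.25)),
               1 / 0.75 + 1 / 0.25 - 1, tolerance = 1e-4)
  expect_error(expected_completion_general(c(0.5, 0.5, 0)),
               class = "mutpie_error_invalid_input")
})

test_that("simulators are exact: both methods match the integral mean", {
  expect_equal(simulate_completion(1, reps = 7), rep(1L, 7))

  set.seed(101)
  draws <- simulate_completion(rep(1, 2), reps = 4e4)
  expect_true(all(draws >= 2))
  expect_equal(mean(draws), 3, tolerance = 0.02)  # 2 H_2 = 3

  # dual-route check on uneven small charts: race and direct samplers vs
  # the quadrature mean, within 4 standard errors
  set.seed(102)
  for (w in list(c(5, 1), c(1, 2, 7), c(4, 3, 2, 1, 1, 9))) {
    m <- mpc(w)
    mu <- expected_completion_general(m)
    for (meth in c("race", "direct")) {
      d <- simulate_completion(m, reps = 6000, method = meth)
      se <- sd(d) / sqrt(length(d))
      expect_lt(abs(mean(d) - mu), 4 * se)
    }
  }

  expect_error(simulate_completion(c(0.5, 0.5, 0), reps = 10),
               class = "mutpie_error_invalid_input")
})

test_that("completion summaries are ordered, reproducible and right-skewed", {
  set.seed(103)
  s <- completion_distribution(rep(1, 16), reps = 2e4, keep_draws = TRUE)
  expect_lte(s$q2_5, s$median)
  expect_lte(s$median, s$q97_5)
  expect_lte(s$q97_5, s$max_observed)
  expect_gte(s$mean, 16)
  expect_gt(s$mean, s$median)  # right skew
  expect_length(attr(s, "draws"), 2e4)

  set.seed(104); a <- completion_distribution(mpc(c(3, 1, 1)), reps = 500)
  set.seed(104); b <- completion_distribution(mpc(c(3, 1, 1)), reps = 500)
  expect_identical(a, b)

  s1 <- completion_distribution(1, reps = 50)
  expect_equal(unlist(s1[, c("mean", "median", "q2_5", "q97_5")]),
               c(mean = 1, median = 1, q2_5 = 1, q97_5 = 1))
})

test_that("the even chart minimizes expected completion (KKT optimality)", {
  set.seed(105)
  for (m in c(4, 8)) {
    even_mu <- expected_completion_general(rep(1, m))
    expect_equal(even_mu, m * harmonic(m), tolerance = 1e-4)
    mus <- replicate(50, expected_completion_general(
      random_mpc_dirichlet(m, concentration = runif(1, 0.3, 5))))
    expect_true(all(mus >= even_mu - 1e-6))
  }
})

test_that("median completion increases with unevenness", {
  set.seed(106)
  meds <- sapply(c(0.1, 0.3, 0.5), function(u) {
    median(sapply(1:30, function(i) {
      median(simulate_completion(mpc_at_unevenness(16, u), reps = 100))
    }))
  })
  expect_true(all(diff(meds) >= 0))
})

test_that("total-mutation-count ML estimator inverts the collection curve", {
  e <- estimate_total_mutations(3, 2)
  expect_equal(e$m, 2, tolerance = 1e-6)
  expect_equal(e$m_integer, 2L)

  e <- estimate_total_mutations(225, 50)
  expect_equal(e$m, 50)  # 50 H_50 = 224.96 <= 225: boundary
  # just below the boundary the root moves above k
  e2 <- estimate_total_mutations(220, 50)
  expect_gt(e2$m, 50)
  # oracle: the fitted m reproduces obs through the defining sum
  expect_equal(sum(e2$m / (e2$m - 0:49)), 220, tolerance = 1e-3)

  e <- estimate_total_mutations(5, 5)
  expect_true(e$unbounded)
  expect_identical(e$m, Inf)

  expect_error(estimate_total_mutations(4, 5),
               class = "mutpie_error_invalid_input")
})
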