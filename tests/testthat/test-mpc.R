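test_that("mpc() normalizes weights and preserves order and labels", {
  m <- mpc(c(2, 2))
  expect_equal(m$share, c(0.5, 0.5))

  m <- mpc(ws_counts, label = paste0("g", seq_along(ws_counts)))
  expect_equal(sum(m$share), 1, tolerance = 1e-9)
  expect_equal(m$share[9], 120 / 500)  # wspF
  expect_equal(m$label[9], "g9")

  # rates and counts give the same chart (scale invariance of construction)
  expect_equal(mpc(ws_counts * 2e-11)$share, mpc(ws_counts)$share)
})

test_that("mpc() rejects degenerate weight vectors", {
  expect_error(mpc(c(0, 0)), class = "mutpie_error_invalid_input")
  expect_error(mpc(c(1, -1)), class = "mutpie_error_invalid_input")
  expect_error(mpc(numeric(0)), class = "mutpie_error_invalid_input")
  expect_error(mpc(c(1, NA)), class = "mutpie_error_invalid_input")
})

test_that("unevenness matches its closed forms and the aws value", {
  expect_equal(unevenness(rep(0.25, 4)), 0)
  expect_equal(unevenness(c(0.5, 0.5, 0, 0)), 1 - log(2) / log(4))
  expect_equal(round(unevenness(mpc(aws_counts)), 3), 0.315)
  # one share takes all: U = 1
  expect_equal(unevenness(c(1, 0, 0)), 1)
})

test_that("gini matches the brute-force pairwise oracle", {
  expect_equal(gini(rep(1, 5)), 0)
  expect_equal(gini(c(1, 0, 0, 0)), 0.75)  # 1 - 1/n at the one-share limit
  expect_equal(gini(c(0.75, 0.25)), 0.25)
  for (p in list(c(0.6, 0.3, 0.1), runif(7), rexp(12))) {
    p <- p / sum(p)
    expect_equal(gini(p), oracle_gini(p))
  }
})

test_that("sls2 is the sum of the two largest shares", {
  expect_equal(sls2(rep(1, 4)), 0.5)  # the 2/n minimum
  expect_equal(sls2(c(0.3, 0.7)), 1)
  expect_equal(sls2(c(0.1, 0.6, 0.3)), 0.9)  # order-free
})

test_that("metrics demand at least two shares", {
  expect_error(unevenness(1), class = "mutpie_error_undefined_metric")
  expect_error(gini(1), class = "mutpie_error_undefined_metric")
  expect_error(sls2(1), class = "mutpie_error_undefined_metric")
})

test_that("metrics respect their ranges, minimality at evenness, and invariances", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(2:40, 1)
    p <- as.numeric(rgamma(n, shape = runif(1, 0.2, 5)))
    m <- mpc(p)
    u <- unevenness(m); g <- gini(m); s <- sls2(m)
    expect_gte(u, 0); expect_lt(u, 1)
    expect_gte(g, 0); expect_lte(g, 1 - 1 / n)
    expect_gte(s, 2 / n); expect_lte(s, 1)
    # permutation invariance
    perm <- sample(n)
    expect_equal(u, unevenness(p[perm]))
    expect_equal(g, gini(p[perm]))
    expect_equal(s, sls2(p[perm]))
    # insensitivity to absolute rates
    expect_equal(u, unevenness(p * 1e-11))
  }
  # all three are minimal exactly on the even MPC
  even <- rep(1 / 8, 8)
  expect_equal(unevenness(even), 0)
  expect_equal(gini(even), 0)
  expect_equal(sls2(even), 2 / 8)
})

test_that("aggregate_genes sums member shares and conserves probability", {
  agg <- aggregate_genes(aws_spectrum())
  expect_equal(agg$label, c("awsO", "awsR", "awsX"))
  expect_equal(agg$share, c(2, 14, 25) / 41, tolerance = 1e-12)
  expect_equal(sum(agg$share), 1, tolerance = 1e-9)

  # identity grouping leaves the chart unchanged
  m <- mpc(c(3, 1, 6), label = c("a", "b", "c"))
  id <- aggregate_genes(m, grouping = c("a", "b", "c"))
  expect_equal(id$share, m$share)

  # symmetric 3+3 grouping of the even 6-MPC
  expect_equal(aggregate_genes(rep(1, 6),
                               grouping = rep(c("x", "y"), each = 3))$share,
               c(0.5, 0.5))

  # aggregation never decreases the largest share
  set.seed(7)
  for (i in 1:10) {
    p <- rgamma(12, 1)
    grp <- sample(letters[1:4], 12, replace = TRUE)
    while (length(unique(grp)) < 2) grp <- sample(letters[1:4], 12, TRUE)
    expect_gte(max(aggregate_genes(mpc(p), grouping = grp)$share),
               max(mpc(p)$share))
  }

  expect_error(aggregate_genes(mpc(c(1, 1))),  # no gene assignment
               class = "mutpie_error_invalid_grouping")
})

test_that("as_mpc handles data frames and weight-column precedence", {
  df <- data.frame(gene = c("a", "b"), mutation = c("m1", "m2"),
                   count = c(3, 1))
  m <- as_mpc(df)
  expect_s3_class(m, "mpc")
  expect_equal(m$share, c(0.75, 0.25))
  expect_equal(m$label, c("m1", "m2"))
  expect_error(as_mpc(data.frame(x = 1:2)),
               class = "mutpie_error_invalid_input")
})
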