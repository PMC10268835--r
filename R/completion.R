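#' Simulate completion experiments
#'
#' A completion experiment draws independent mutants from an MPC until every
#' mutational element has been observed at least once (the non-equiprobable
#' coupon collector's problem) and records the number of draws required --
#' the observation span a sequencing study would need to fully characterize
#' the genotype-to-phenotype map.
#'
#' Two exact samplers are provided. `"race"` (default) uses the
#' Poissonization of the collector's problem: embedding draws in a unit-rate
#' Poisson process, the first arrival of element *i* is at
#' \eqn{X_i \sim Exp(p_i)}, independently across elements; with
#' \eqn{T = \max_i X_i} the completion count is distributed as
#' \eqn{n + \sum_i Pois(p_i (T - X_i))}. `"direct"` draws element indices
#' from the categorical distribution in geometrically growing blocks and
#' scans for the last first-occurrence. Both follow the same law; `"race"`
#' is far faster for many replicates.
#'
#' @param x An MPC (or object coercible via [as_mpc()]). All shares must be
#'   strictly positive, otherwise completion is impossible.
#' @param reps Number of replicate experiments.
#' @param method `"race"` or `"direct"` (see Details).
#' @return Numeric vector of length `reps`: the draw index at which the last
#'   unseen element first appeared (always `>= n`; stored as doubles since
#'   near-degenerate charts can need more than 2^31 draws).
#' @examples
#' set.seed(1)
#' simulate_completion(rep(1, 16), reps = 5)
#' @export
simulate_completion <- function(x, reps = 1L, method = c("race", "direct")) {
  p <- shares(x)
  reps <- check_count(reps, "reps")
  method <- match.arg(method)
  if (any(p <= 0)) {
    abort_invalid(
      "MPC has zero shares: completion would never terminate. Drop them first.")
  }
  n <- length(p)
  if (n == 1L) return(rep(1L, reps))
  if (method == "race") completion_race(p, reps) else completion_direct(p, reps)
}

completion_race <- function(p, reps) {
  n <- length(p)
  out <- numeric(reps)
  chunk <- max(1L, min(reps, floor(4e6 / n)))
  done <- 0L
  while (done < reps) {
    k <- min(chunk, reps - done)
    rate <- rep(p, each = k)
    x <- matrix(rexp(k * n, rate = rate), k, n)
    tmax <- x[cbind(seq_len(k), max.col(x))]
    lam <- pmax(tmax - x, 0) * rate
    cnt <- numeric(k * n)
    # near-degenerate shares can push a Poisson mean beyond integer range;
    # the normal limit is exact to floating precision there
    big <- lam > 2^30
    cnt[!big] <- rpois(sum(!big), lam[!big])
    if (any(big)) {
      cnt[big] <- round(rnorm(sum(big), lam[big], sqrt(lam[big])))
    }
    out[done + seq_len(k)] <- n + rowSums(matrix(cnt, k, n))
    done <- done + k
  }
  out
}

completion_direct <- function(p, reps) {
  n <- length(p)
  mu <- expected_completion_general(mpc(p))
  block <- max(2L * n, ceiling(2 * mu))
  out <- integer(reps)
  for (r in seq_len(reps)) {
    draws <- sample.int(n, block, replace = TRUE, prob = p)
    first <- match(seq_len(n), draws)
    while (anyNA(first)) {
      more <- sample.int(n, block, replace = TRUE, prob = p)
      miss <- which(is.na(first))
      first[miss] <- length(draws) + match(miss, more)
      draws <- c(draws, more)
    }
    out[r] <- max(first)
  }
  out
}

#' Replicate-summary of completion experiments
#'
#' @inheritParams simulate_completion
#' @param keep_draws Keep the raw completion counts as attribute `"draws"`
#'   (useful for plotting with [plot_completion()]).
#' @return A one-row tibble of class `"completion_summary"`: `reps`, `mean`,
#'   `median`, `q2_5`, `q97_5` (central 95% bounds) and `max_observed`.
#' @examples
#' set.seed(1)
#' completion_distribution(rep(1, 16), reps = 1000)
#' @export
completion_distribution <- function(x, reps, method = c("race", "direct"),
                                    keep_draws = FALSE) {
  draws <- simulate_completion(x, reps = reps, method = method)
  qs <- q95(draws)
  out <- tibble(reps = length(draws), mean = mean(draws),
                median = median(draws), q2_5 = qs[1], q97_5 = qs[2],
                max_observed = max(draws))
  if (keep_draws) attr(out, "draws") <- draws
  class(out) <- c("completion_summary", class(out))
  out
}

#' Expected completion count for an even MPC
#'
#' With `m` equiprobable mutations, the expected number of draws to observe
#' all of them is \eqn{m H_m} exactly, approximately
#' \eqn{m(\ln m + \gamma + 1/(2m))} with Euler-Mascheroni
#' \eqn{\gamma \approx 0.5772}.
#'
#' @param m Number of mutational elements (`>= 1`).
#' @param exact Use the harmonic sum (`TRUE`) or the approximation.
#' @return Expected number of observations.
#' @examples
#' expected_completion_even(50)  # 224.96: ~225 mutants for 50 mutations
#' @export
expected_completion_even <- function(m, exact = TRUE) {
  m <- check_count(m, "m")
  if (exact) {
    m * sum(1 / seq_len(m))
  } else {
    g <- -digamma(1)
    m * (log(m) + g + 1 / (2 * m))
  }
}

#' Standard deviation of the even-MPC completion count
#'
#' Exact form from the sum of geometric stage variances,
#' \eqn{\sqrt{m^2 H^{(2)}_m - m H_m}}; approximate form
#' \eqn{\sqrt{\pi^2 m^2/6 - (\ln m + 1 + \gamma) m - 1/(12m)}}. A negative
#' radicand (tiny `m`) falls back to the exact form with a warning.
#'
#' @inheritParams expected_completion_even
#' @return Standard deviation of the number of observations.
#' @examples
#' sd_completion_even(50)  # 61.95: SD ~62 alongside the mean of 225
#' @export
sd_completion_even <- function(m, exact = TRUE) {
  m <- check_count(m, "m")
  if (!exact) {
    g <- -digamma(1)
    rad <- pi^2 * m^2 / 6 - (log(m) + 1 + g) * m - 1 / (12 * m)
    if (rad < 0) {
      warn("approximation radicand negative; using the exact form.")
    } else {
      return(sqrt(rad))
    }
  }
  k <- seq_len(m)
  sqrt(m^2 * sum(1 / k^2) - m * sum(1 / k))
}

#' Expected extra draws before the next new mutation (even MPC)
#'
#' After `k` of `m` equiprobable mutations have been discovered, the wait
#' for the (k+1)-th is geometric with mean `m / (m - k)`.
#'
#' @param m Total number of mutations.
#' @param k Number already discovered (`0 <= k < m`).
#' @return Expected number of additional observations.
#' @examples
#' expected_additional(50, 40)  # 5
#' @export
expected_additional <- function(m, k) {
  m <- check_count(m, "m")
  k <- check_count(k, "k", min = 0L)
  if (k >= m) abort_invalid("`k` must be smaller than `m`.")
  m / (m - k)
}

#' Expected completion count for an arbitrary MPC
#'
#' Evaluates the exact integral representation of the expected waiting time
#' of the non-equiprobable coupon collector,
#' \deqn{E\{C_m\} = \int_0^\infty \Big(1 - \prod_i (1 - e^{-p_i x})\Big) dx,}
#' by adaptive quadrature. The upper limit is doubled until the integrand
#' falls below 1e-12 (it decays like \eqn{e^{-p_{min} x}}).
#'
#' @inheritParams simulate_completion
#' @return Expected number of observations (a positive number).
#' @examples
#' expected_completion_general(rep(1, 16))  # = 16 * H_16 = 54.09
#' expected_completion_general(c(0.996, 0.004))  # ~250
#' @export
expected_completion_general <- function(x) {
  p <- shares(x)
  if (any(p <= 0)) {
    abort_invalid("MPC has zero shares: the completion integral diverges.")
  }
  n <- length(p)
  if (n == 1L) return(1)
  integrand <- function(t) {
    e <- exp(-outer(t, p))
    1 - exp(rowSums(log1p(-e)))
  }
  upper <- log(n * 1e12) / min(p)
  while (integrand(upper) > 1e-12) upper <- 2 * upper
  integrate(integrand, 0, upper, rel.tol = 1e-6,
            subdivisions = 2000L)$value
}

#' Maximum-likelihood estimate of the total number of mutations
#'
#' Under the even-MPC model, given `k` distinct mutations discovered in
#' `obs` total observations, the ML estimate of the total number of
#' mutations `m` solves
#' \deqn{obs = \frac{m}{m} + \frac{m}{m-1} + \dots + \frac{m}{m-k+1},}
#' the expected number of draws to collect `k` distinct coupons out of `m`.
#' The right-hand side decreases in `m` from \eqn{k H_k} (at `m = k`) to `k`
#' (as \eqn{m \to \infty}); the real root is found by bisection.
#'
#' @param obs Total observation span (number of mutants sequenced).
#' @param k Number of distinct mutations observed (`1 <= k <= obs`).
#' @return A one-row tibble: `obs`, `k`, `m` (real root, `Inf` when
#'   unbounded), `m_integer` (nearest integer, ties to the smaller value)
#'   and `unbounded` (`TRUE` when every draw was new, which carries no upper
#'   signal on `m`).
#' @examples
#' estimate_total_mutations(3, 2)     # m = 2
#' estimate_total_mutations(225, 50)  # m ~ 50
#' estimate_total_mutations(5, 5)     # unbounded
#' @export
estimate_total_mutations <- function(obs, k) {
  obs <- check_count(obs, "obs")
  k <- check_count(k, "k")
  if (obs < k) {
    abort_invalid("`obs` must be at least `k`: cannot see k distinct in fewer draws.")
  }
  res <- function(m, m_int, unbounded) {
    tibble(obs = obs, k = k, m = m, m_integer = m_int, unbounded = unbounded)
  }
  if (obs == k) return(res(Inf, NA_integer_, TRUE))
  f <- function(m) sum(m / (m - seq_len(k) + 1)) - obs
  # f decreasing; f(k) = k*H_k - obs
  if (f(k) <= 0) return(res(as.numeric(k), k, FALSE))
  hi <- 2 * k
  while (f(hi) > 0) hi <- 2 * hi
  root <- uniroot(f, c(k, hi), tol = 1e-6 * k)$root
  res(root, as.integer(ceiling(root - 0.5)), FALSE)
}
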