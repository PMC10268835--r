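#' Log-normal distribution of mutation rates (DMR)
#'
#' Absolute per-mutation rates are modelled as i.i.d. draws from a
#' log-normal distribution: most rates are very low, a few are much higher
#' (hotspots), none are exactly zero. `mu` and `sigma` are the parameters of
#' the underlying normal, so the mean is \eqn{e^{\mu + \sigma^2/2}}, the
#' median \eqn{e^\mu}, the mode \eqn{e^{\mu - \sigma^2}} and the coefficient
#' of variation \eqn{\sqrt{e^{\sigma^2} - 1}}.
#'
#' @param mu Location of the underlying normal (log gen^-1 scale).
#' @param sigma Scale of the underlying normal (dimensionless, `>= 0`).
#' @return An object of class `"lognormal_dmr"`.
#' @seealso [dmr_from_mean_sigma()] to parameterize by the distribution
#'   mean, as done when the mean is pinned to an experimental average.
#' @examples
#' d <- lognormal_dmr(mu = -25.20, sigma = 1.72)
#' dmr_mean(d); dmr_median(d); dmr_mode(d)
#' @export
lognormal_dmr <- function(mu, sigma) {
  mu <- check_number(mu, "mu")
  sigma <- check_number(sigma, "sigma", min = 0)
  structure(list(mu = mu, sigma = sigma), class = "lognormal_dmr")
}

#' Log-normal DMR from its mean and sigma
#'
#' When the distribution mean is fixed at an experimentally measured average
#' rate, the location parameter follows as
#' \eqn{\mu = \ln(mean) - \sigma^2/2}.
#'
#' @param mean Mean mutation rate (gen^-1, `> 0`).
#' @param sigma Scale of the underlying normal (`>= 0`).
#' @return An object of class `"lognormal_dmr"`.
#' @examples
#' dmr_from_mean_sigma(5e-11, 1.72)  # mu = -25.20 as in the WS calibration
#' @export
dmr_from_mean_sigma <- function(mean, sigma) {
  mean <- check_number(mean, "mean", min = 0, strict = TRUE)
  sigma <- check_number(sigma, "sigma", min = 0)
  lognormal_dmr(log(mean) - sigma^2 / 2, sigma)
}

#' @rdname lognormal_dmr
#' @param d A `"lognormal_dmr"` object.
#' @export
dmr_mean <- function(d) exp(d$mu + d$sigma^2 / 2)

#' @rdname lognormal_dmr
#' @export
dmr_median <- function(d) exp(d$mu)

#' @rdname lognormal_dmr
#' @export
dmr_mode <- function(d) exp(d$mu - d$sigma^2)

#' @rdname lognormal_dmr
#' @export
dmr_cv <- function(d) sqrt(exp(d$sigma^2) - 1)

#' @export
print.lognormal_dmr <- function(x, ...) {
  cat(sprintf(
    "Log-normal DMR: mu = %.4g, sigma = %.4g\n  mean %.3g, median %.3g, mode %.3g gen^-1 (CV %.3g)\n",
    x$mu, x$sigma, dmr_mean(x), dmr_median(x), dmr_mode(x), dmr_cv(x)))
  invisible(x)
}

#' @export
tidy.lognormal_dmr <- function(x, ...) {
  tibble(mu = x$mu, sigma = x$sigma, mean = dmr_mean(x),
         median = dmr_median(x), mode = dmr_mode(x), cv = dmr_cv(x))
}

#' Sample absolute mutation rates from a DMR
#'
#' Draws i.i.d. per-mutation rates. The `"gamma"` family is a
#' moment-matched alternative (same mean and standard deviation as the
#' log-normal: shape \eqn{1/(e^{\sigma^2}-1)}, scale
#' \eqn{mean \cdot (e^{\sigma^2}-1)}) for shape-sensitivity comparisons.
#' Rates above 1e-2 gen^-1 are biologically implausible; their number is
#' recorded in attribute `"n_implausible"` rather than truncated.
#'
#' @param d A `"lognormal_dmr"`.
#' @param n Number of rates to draw.
#' @param family `"lognormal"` (default) or moment-matched `"gamma"`.
#' @return Numeric vector of `n` positive rates.
#' @examples
#' set.seed(1)
#' sample_rates(dmr_from_mean_sigma(5e-11, 1.72), 5)
#' @export
sample_rates <- function(d, n, family = c("lognormal", "gamma")) {
  n <- check_count(n, "n")
  family <- match.arg(family)
  if (d$sigma == 0) {
    r <- rep(exp(d$mu), n)
  } else if (family == "lognormal") {
    r <- rlnorm(n, meanlog = d$mu, sdlog = d$sigma)
  } else {
    v <- exp(d$sigma^2) - 1
    r <- rgamma(n, shape = 1 / v, scale = dmr_mean(d) * v)
  }
  attr(r, "n_implausible") <- sum(r > 1e-2)
  r
}

#' Sample a random MPC from a DMR
#'
#' Each of `n_sites` mutations draws its absolute rate independently from
#' the DMR; normalizing the rates gives the MPC. Because normalization
#' cancels any common factor, the resulting unevenness depends only on
#' `sigma`, never on `mu`.
#'
#' @inheritParams sample_rates
#' @param n_sites Number of mutational elements (`>= 2`).
#' @return An [mpc()].
#' @examples
#' set.seed(1)
#' unevenness(sample_mpc(lognormal_dmr(-25.15, 1.69), 500))
#' @export
sample_mpc <- function(d, n_sites, family = c("lognormal", "gamma")) {
  n_sites <- check_count(n_sites, "n_sites", min = 2L)
  mpc(as.numeric(sample_rates(d, n_sites, family = family)))
}

# unevenness of `reps` sampled MPCs, vectorized and chunked.
# Zero-probability shares cannot occur (log-normal draws are positive).
sample_unevenness <- function(d, n_sites, reps,
                              family = c("lognormal", "gamma")) {
  family <- match.arg(family)
  if (d$sigma == 0 && family == "lognormal") return(rep(0, reps))
  logn <- log(n_sites)
  out <- numeric(reps)
  chunk <- max(1L, min(reps, floor(5e6 / n_sites)))
  done <- 0L
  while (done < reps) {
    k <- min(chunk, reps - done)
    m <- matrix(sample_rates(d, k * n_sites, family = family), k, n_sites)
    p <- m / rowSums(m)
    out[done + seq_len(k)] <- 1 + rowSums(p * log(p)) / logn
    done <- done + k
  }
  out
}

#' Distribution of MPC unevenness under a DMR
#'
#' Samples `reps` MPCs of `n_sites` mutations from the DMR and summarizes
#' the distribution of their unevenness index.
#'
#' @inheritParams sample_mpc
#' @param reps Number of MPCs to sample.
#' @param keep_draws Keep the raw unevenness values as attribute `"draws"`.
#' @return One-row tibble: `n_sites`, `reps`, `mean`, `median`, `q2_5`,
#'   `q97_5`.
#' @examples
#' set.seed(1)
#' unevenness_distribution(lognormal_dmr(-25.15, 1.69), 500, reps = 1000)
#' @export
unevenness_distribution <- function(d, n_sites, reps,
                                    family = c("lognormal", "gamma"),
                                    keep_draws = FALSE) {
  n_sites <- check_count(n_sites, "n_sites", min = 2L)
  reps <- check_count(reps, "reps")
  u <- sample_unevenness(d, n_sites, reps, family = family)
  qs <- q95(u)
  out <- tibble(n_sites = n_sites, reps = reps, mean = mean(u),
                median = median(u), q2_5 = qs[1], q97_5 = qs[2])
  if (keep_draws) attr(out, "draws") <- u
  out
}

#' Distribution of the total mutation rate (TMR)
#'
#' The TMR to a phenotype is the sum of the rates of all its `n_sites`
#' mutations. With i.i.d. rates the central limit theorem drives the TMR
#' towards normality as `n_sites` grows; with few sites it inherits the
#' DMR's right skew. Skewness uses the adjusted Fisher-Pearson estimator.
#'
#' @inheritParams unevenness_distribution
#' @param reps Number of replicate TMR draws (`>= 2`).
#' @return Object of class `"tmr_summary"`: a list with `n_sites`, `reps`,
#'   `mean`, `sd`, `skewness` and `standardized` (the centred and scaled
#'   draws).
#' @examples
#' set.seed(1)
#' tmr_distribution(dmr_from_mean_sigma(5e-11, 1.72), 500, reps = 1000)
#' @export
tmr_distribution <- function(d, n_sites, reps,
                             family = c("lognormal", "gamma")) {
  n_sites <- check_count(n_sites, "n_sites")
  reps <- check_count(reps, "reps", min = 2L)
  family <- match.arg(family)
  s <- numeric(reps)
  chunk <- max(1L, min(reps, floor(5e6 / n_sites)))
  done <- 0L
  while (done < reps) {
    k <- min(chunk, reps - done)
    m <- matrix(sample_rates(d, k * n_sites, family = family), k, n_sites)
    s[done + seq_len(k)] <- rowSums(m)
    done <- done + k
  }
  mu <- mean(s)
  sdev <- sd(s)
  structure(
    list(n_sites = n_sites, reps = reps, mean = mu, sd = sdev,
         skewness = e1071::skewness(s, type = 2),
         standardized = (s - mu) / sdev),
    class = "tmr_summary")
}

#' @export
print.tmr_summary <- function(x, ...) {
  cat(sprintf(
    "TMR over %d sites (%d draws): mean %.3g, sd %.3g, skewness %.3g\n",
    x$n_sites, x$reps, x$mean, x$sd, x$skewness))
  invisible(x)
}

#' @export
tidy.tmr_summary <- function(x, ...) {
  tibble(n_sites = x$n_sites, reps = x$reps, mean = x$mean, sd = x$sd,
         skewness = x$skewness)
}

#' Asymptotic moments of the TMR
#'
#' Closed-form mean \eqn{n e^{\mu+\sigma^2/2}}, standard deviation
#' \eqn{\sqrt{n} e^{\mu+\sigma^2/2} \sqrt{e^{\sigma^2}-1}}, coefficient of
#' variation \eqn{\sqrt{e^{\sigma^2}-1}/\sqrt{n}}, and the large-n median
#' limit (the mean, by the central limit theorem).
#'
#' @inheritParams unevenness_distribution
#' @return One-row tibble: `n_sites`, `mean`, `sd`, `cv`, `median_limit`.
#' @examples
#' tmr_asymptotics(dmr_from_mean_sigma(5e-11, 1.72), 500)
#' @export
tmr_asymptotics <- function(d, n_sites) {
  n_sites <- check_count(n_sites, "n_sites")
  m1 <- exp(d$mu + d$sigma^2 / 2)
  cv1 <- sqrt(exp(d$sigma^2) - 1)
  tibble(n_sites = n_sites, mean = n_sites * m1,
         sd = sqrt(n_sites) * m1 * cv1, cv = cv1 / sqrt(n_sites),
         median_limit = n_sites * m1)
}

#' Probability of parallel evolution under a log-normal DMR
#'
#' For `n` evolutionary possibilities with i.i.d. log-normal rates, the
#' probability that two independent realizations use the same element
#' reduces to \eqn{Pr_{para} = e^{\sigma^2}/n}. The expression exceeds 1
#' when \eqn{e^{\sigma^2} > n}; it is then clamped to 1 with a warning and
#' attribute `"clamped"` set.
#'
#' @param sigma Scale of the underlying normal (`>= 0`).
#' @param n Number of evolutionary possibilities (`>= 1`).
#' @return A probability; attribute `"clamped"` is `TRUE` if clamping
#'   occurred.
#' @examples
#' prob_parallel(0, 4)  # 1/4, the uniform case
#' @export
prob_parallel <- function(sigma, n) {
  sigma <- check_number(sigma, "sigma", min = 0)
  n <- check_count(n, "n")
  p <- exp(sigma^2) / n
  clamped <- p > 1
  if (clamped) {
    warn("exp(sigma^2)/n exceeds 1; clamping to 1.",
         class = "mutpie_warning_clamped")
    p <- 1
  }
  structure(p, clamped = clamped)
}
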