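#' Probability that the larger mutational target has the larger rate
#'
#' Two pathways A and B have `n_large` and `n_small` sites; every site draws
#' its rate i.i.d. from a log-normal DMR with scale `sigma` (the location
#' `mu` cancels from the comparison and is fixed at 0). The returned value
#' is the Monte-Carlo estimate of \eqn{P(\sum_A rates > \sum_B rates)}: the
#' probability that target-size determinism beats DMR stochasticity.
#'
#' @param sigma Scale of the log-normal DMR (`>= 0`).
#' @param n_large,n_small Target sizes, `n_large >= n_small >= 1`.
#' @param reps Monte-Carlo replicates (`>= 1000`).
#' @return A probability in `[0, 1]`.
#' @examples
#' set.seed(1)
#' prob_larger_wins(1.72, 15, 1, reps = 10000)
#' @export
prob_larger_wins <- function(sigma, n_large, n_small, reps = 1e5) {
  sigma <- check_number(sigma, "sigma", min = 0)
  n_large <- check_count(n_large, "n_large")
  n_small <- check_count(n_small, "n_small")
  if (n_large < n_small) abort_invalid("`n_large` must be >= `n_small`.")
  reps <- check_count(reps, "reps", min = 1000L)
  if (sigma == 0) return(as.numeric(n_large > n_small))
  wins <- 0
  chunk <- max(1L, min(reps, floor(4e6 / (n_large + n_small))))
  done <- 0L
  while (done < reps) {
    k <- min(chunk, reps - done)
    a <- rowSums(matrix(rlnorm(k * n_large, 0, sigma), k, n_large))
    b <- rowSums(matrix(rlnorm(k * n_small, 0, sigma), k, n_small))
    wins <- wins + sum(a > b)
    done <- done + k
  }
  wins / reps
}

# smallest integer r >= 1 with prob_larger_wins(sigma, r * n_small, n_small)
# >= certainty, by doubling then bisection on r
r_threshold_int <- function(sigma, certainty, n_small, reps) {
  pwin <- function(r) prob_larger_wins(sigma, r * n_small, n_small, reps)
  lo <- 1L
  hi <- 1L
  p_hi <- pwin(hi)
  while (p_hi < certainty) {
    lo <- hi
    hi <- 2L * hi
    p_hi <- pwin(hi)
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pwin(mid) >= certainty) hi <- mid else lo <- mid
  }
  hi
}

#' Threshold target-size ratio for repeatable evolution
#'
#' The smallest integer ratio `r` such that a pathway `r` times larger than
#' an `n_small`-site pathway has the higher summed rate with probability at
#' least `certainty`, despite rates fluctuating under the log-normal DMR.
#' Above this ratio, target-size determinism is robust; below it, more than
#' `1 - certainty` of DMR realizations upset the size ranking.
#'
#' When `batches > 1` the replicate budget is split and the threshold
#' recomputed per batch; the mean and median across batches are reported
#' alongside the pooled estimate.
#'
#' @inheritParams prob_larger_wins
#' @param certainty Required probability, in `(0.5, 1)`; default 0.95.
#' @param n_small Size of the smaller target; the default 1 is the
#'   conservative design (the larger target gets no concentration help from
#'   a many-site small pathway).
#' @param reps Monte-Carlo replicates per candidate ratio.
#' @param batches Number of replicate batches for the mean/median variants.
#' @return One-row tibble: `sigma`, `certainty`, `n_small`, `r_thresh`
#'   (pooled), `r_thresh_mean`, `r_thresh_median`, `batches`.
#' @examples
#' set.seed(1)
#' r_threshold(1.72, reps = 10000)
#' @export
r_threshold <- function(sigma, certainty = 0.95, n_small = 1L, reps = 1e5,
                        batches = 1L) {
  certainty <- check_number(certainty, "certainty", min = 0.5, strict = TRUE)
  if (certainty >= 1) abort_invalid("`certainty` must be below 1.")
  batches <- check_count(batches, "batches")
  r_pooled <- r_threshold_int(sigma, certainty, n_small, reps)
  if (batches > 1L) {
    per <- max(1000L, floor(reps / batches))
    rb <- vapply(seq_len(batches), function(i) {
      r_threshold_int(sigma, certainty, n_small, per)
    }, integer(1))
    r_mean <- mean(rb)
    r_median <- median(rb)
  } else {
    r_mean <- r_median <- as.numeric(r_pooled)
  }
  tibble(sigma = sigma, certainty = certainty, n_small = as.integer(n_small),
         r_thresh = r_pooled, r_thresh_mean = r_mean,
         r_thresh_median = r_median, batches = batches)
}

#' Repeatability threshold curve over a sigma grid
#'
#' @inheritParams r_threshold
#' @param sigma_grid Vector of DMR scales to evaluate.
#' @return A tibble of class `"repeatability_curve"`, one [r_threshold()]
#'   row per `sigma`.
#' @examples
#' set.seed(1)
#' repeatability_curve(c(0.5, 1.5), reps = 5000)
#' @export
repeatability_curve <- function(sigma_grid, certainty = 0.95, n_small = 1L,
                                reps = 1e5, batches = 1L) {
  out <- bind_rows(lapply(sigma_grid, r_threshold, certainty = certainty,
                          n_small = n_small, reps = reps, batches = batches))
  class(out) <- c("repeatability_curve", class(out))
  out
}
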