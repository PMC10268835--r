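#' Draw a sample of mutants from a known MPC
#'
#' The "observation compartment" of an estimation experiment: `n_obs`
#' independent mutants are drawn from the true MPC and tallied per element
#' (a multinomial sample).
#'
#' @inheritParams simulate_completion
#' @param n_obs Number of mutants observed (`>= 1`).
#' @return Integer vector of per-element occurrence counts, summing to
#'   `n_obs`, named by the MPC labels.
#' @examples
#' set.seed(1)
#' observe_sample(rep(1, 4), 100)
#' @export
observe_sample <- function(x, n_obs) {
  m <- as_mpc(x)
  n_obs <- check_count(n_obs, "n_obs")
  counts <- as.integer(rmultinom(1L, n_obs, m$share))
  setNames(counts, m$label)
}

#' Plug-in MPC estimate from observed counts
#'
#' The "modelling compartment": given occurrence counts over a known number
#' of categories, the estimated MPC uses the plug-in shares `count / total`.
#' Unobserved categories are retained as zero shares (the `0 ln 0 = 0`
#' convention makes downstream unevenness well defined).
#'
#' @param counts Non-negative integer occurrence counts.
#' @param n_categories Known total number of categories; must equal
#'   `length(counts)`.
#' @return An [mpc()]; zero shares are kept.
#' @examples
#' estimate_mpc(c(5, 5, 5, 5))  # the even 4-MPC
#' @export
estimate_mpc <- function(counts, n_categories = length(counts)) {
  n_categories <- check_count(n_categories, "n_categories")
  if (length(counts) != n_categories) {
    abort_invalid("`counts` must have length `n_categories`.")
  }
  if (sum(counts) <= 0) {
    abort_invalid("total count must be positive.")
  }
  mpc(counts, label = names(counts))
}

#' Convergence of unevenness estimation with observation span
#'
#' Three-compartment experiment: for each observation span in `obs_grid`,
#' draw `reps` independent multinomial samples from the true MPC, estimate
#' the MPC by plug-in shares over the known number of categories, and record
#' the signed unevenness error \eqn{\hat U - U_{true}} (negative =
#' underestimation, positive = overestimation).
#'
#' @inheritParams simulate_completion
#' @param obs_grid Ascending vector of observation spans.
#' @param reps Replicates per grid point.
#' @return A tibble of class `"estimation_error"`, one row per grid point:
#'   `obs`, `reps`, `mean_error`, `median_error`, `band_low`, `band_high`
#'   (central 95% bounds of the signed error).
#' @examples
#' set.seed(1)
#' estimation_error_experiment(rep(1, 16), c(50, 200), reps = 200)
#' @export
estimation_error_experiment <- function(x, obs_grid, reps) {
  m <- as_mpc(x)
  reps <- check_count(reps, "reps")
  if (length(obs_grid) < 1L || any(obs_grid < 1) ||
      is.unsorted(obs_grid, strictly = TRUE)) {
    abort_invalid("`obs_grid` must be strictly ascending positive counts.")
  }
  n <- nrow(m)
  u_true <- unevenness(m)
  logn <- log(n)
  rows <- lapply(obs_grid, function(obs) {
    cnt <- rmultinom(reps, obs, m$share)  # n x reps
    p <- cnt / obs
    plp <- p * log(p)
    plp[p == 0] <- 0
    err <- (1 + colSums(plp) / logn) - u_true
    qs <- q95(err)
    tibble(obs = as.integer(obs), reps = reps, mean_error = mean(err),
           median_error = median(err), band_low = qs[1], band_high = qs[2])
  })
  out <- bind_rows(rows)
  attr(out, "u_true") <- u_true
  class(out) <- c("estimation_error", class(out))
  out
}
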