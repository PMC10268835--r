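# Independent oracles, deliberately naive: direct transcriptions of the
# defining formulas, used to cross-check the package's implementations.

oracle_gini <- function(p) {
  n <- length(p)
  sum(abs(outer(p, p, "-"))) / (2 * n^2 * (1 / n))
}

oracle_unevenness <- function(p) {
  terms <- ifelse(p > 0, p * log(p), 0)
  1 + sum(terms) / log(length(p))
}

harmonic <- function(m, r = 1) sum(1 / seq_len(m)^r)

# expected draws to collect all m even coupons, by the stage-wise geometric
# decomposition (independent of the integral and of the simulators)
oracle_even_mean <- function(m) sum(m / (m - seq_len(m) + 1))

# counts of the aws fluctuation-test spectrum, in table order
aws_counts <- c(1, 1, 9, 1, 1, 2, 1, 1, 2, 1, 20, 1)
ws_counts <- c(10, 50, 85, 50, 50, 50, 10, 50, 120, 10, 2, 2, 2, 3, 3, 3)
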