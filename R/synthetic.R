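#' In-package wrinkly spreader (WS) data fixtures
#'
#' Machine-readable copies of the two published tables for the WS system in
#' *Pseudomonas fluorescens* SBW25 that the package's worked analyses use:
#'
#' * `ws_gene_setup()` -- estimated number of mutations able to produce the
#'   WS phenotype for each of 16 genes (total 500).
#' * `ws_pathway_setup()` -- the same counts aggregated to 10 mutational
#'   pathways (operons *aws* = 145 and *wsp* = 240; other genes unchanged).
#' * `aws_spectrum()` -- the *aws* fluctuation-test spectrum: 12 distinct
#'   mutations with their occurrence counts (total 41) across *awsO*,
#'   *awsR* and *awsX*.
#'
#' @return `ws_gene_setup()` and `ws_pathway_setup()` return a tibble with
#'   columns `gene` and `n_mutations`; `aws_spectrum()` a tibble with
#'   columns `gene`, `mutation` and `count`.
#' @examples
#' sum(ws_gene_setup()$n_mutations)  # 500
#' unevenness(aws_spectrum())        # 0.315
#' @name fixtures
NULL

mutpie_extdata <- function(file) {
  system.file("extdata", file, package = "mutpie", mustWork = TRUE)
}

#' @rdname fixtures
#' @export
ws_gene_setup <- function() {
  read_gene_setup_tsv(mutpie_extdata("ws_gene_setup.tsv"))
}

#' @rdname fixtures
#' @export
ws_pathway_setup <- function() {
  g <- ws_gene_setup()
  pathway <- g$gene
  pathway[startsWith(pathway, "aws")] <- "aws"
  pathway[startsWith(pathway, "wsp")] <- "wsp"
  keys <- unique(pathway)
  tibble(gene = keys,
         n_mutations = unname(vapply(keys, function(k) {
           sum(g$n_mutations[pathway == k])
         }, integer(1))))
}

#' @rdname fixtures
#' @export
aws_spectrum <- function() {
  read_spectrum_tsv(mutpie_extdata("aws_spectrum.tsv"))
}

#' Look up a fixture by registry name
#'
#' @param name One of `"ws_gene_setup"`, `"ws_pathway_setup"`,
#'   `"aws_spectrum"`.
#' @return The corresponding fixture tibble (see [fixtures]).
#' @examples
#' fixture("aws_spectrum")
#' @export
fixture <- function(name) {
  switch(name,
         ws_gene_setup = ws_gene_setup(),
         ws_pathway_setup = ws_pathway_setup(),
         aws_spectrum = aws_spectrum(),
         abort_invalid(sprintf("unknown fixture '%s'.", name)))
}

#' Average rate per mutation implied by a gene setup
#'
#' Divides a measured total mutation rate to the phenotype by the setup's
#' total number of mutations. For the WS system, the fluctuation-test total
#' of 1e-8 gen^-1 spread over 500 mutations gives 2e-11 gen^-1 per
#' mutation.
#'
#' @param setup A gene-setup tibble (columns `gene`, `n_mutations`).
#' @param total_rate Total mutation rate to the phenotype (gen^-1).
#' @return Average per-mutation rate (gen^-1).
#' @examples
#' setup_mean_rate(ws_gene_setup(), 1e-8)  # 2e-11
#' @export
setup_mean_rate <- function(setup, total_rate = 1e-8) {
  total_rate <- check_number(total_rate, "total_rate", min = 0, strict = TRUE)
  total_rate / sum(setup$n_mutations)
}

#' Read and write spectrum and gene-setup tables
#'
#' Plain TSV interchange mirroring the shipped fixtures: spectra have
#' columns `gene`, `mutation`, `count`; gene setups have `gene`,
#' `n_mutations`. Counts must be non-negative integers; violations are
#' reported with their line number.
#'
#' @param path File path.
#' @param x For the writers: a tibble with the respective columns.
#' @return Readers return a tibble (see [fixtures]); writers return `path`
#'   invisibly.
#' @examples
#' p <- tempfile(fileext = ".tsv")
#' write_spectrum_tsv(aws_spectrum(), p)
#' identical(read_spectrum_tsv(p), aws_spectrum())
#' @export
read_spectrum_tsv <- function(path) {
  read_fixture_tsv(path, c("gene", "mutation", "count"), "count")
}

#' @rdname read_spectrum_tsv
#' @export
read_gene_setup_tsv <- function(path) {
  read_fixture_tsv(path, c("gene", "n_mutations"), "n_mutations")
}

read_fixture_tsv <- function(path, columns, count_col) {
  if (!file.exists(path)) abort_parse(sprintf("file '%s' does not exist.", path))
  raw <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE),
    error = function(e) abort_parse(sprintf("cannot parse '%s': %s", path,
                                            conditionMessage(e))))
  if (!identical(names(raw), columns)) {
    abort_parse(sprintf("expected header '%s' in '%s' (line 1).",
                        paste(columns, collapse = "\t"), path))
  }
  if (nrow(raw) == 0L) abort_parse(sprintf("'%s' has no data rows.", path))
  cnt <- suppressWarnings(as.numeric(raw[[count_col]]))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != floor(cnt))
  if (length(bad) > 0L) {
    abort_parse(sprintf(
      "'%s': column `%s` must hold non-negative integers (first offence on line %d).",
      path, count_col, bad[1L] + 1L))
  }
  out <- as_tibble(setNames(lapply(columns, function(cc) raw[[cc]]), columns))
  out[[count_col]] <- as.integer(cnt)
  out
}

#' @rdname read_spectrum_tsv
#' @export
write_spectrum_tsv <- function(x, path) {
  stopifnot(all(c("gene", "mutation", "count") %in% names(x)))
  readr::write_tsv(x[, c("gene", "mutation", "count")], path)
  invisible(path)
}

#' @rdname read_spectrum_tsv
#' @export
write_gene_setup_tsv <- function(x, path) {
  stopifnot(all(c("gene", "n_mutations") %in% names(x)))
  readr::write_tsv(x[, c("gene", "n_mutations")], path)
  invisible(path)
}

#' Random MPC from a symmetric Dirichlet distribution
#'
#' @param n Number of shares (`>= 2`).
#' @param concentration Symmetric Dirichlet concentration (`> 0`); the
#'   expected unevenness decreases as the concentration grows.
#' @return An [mpc()].
#' @examples
#' set.seed(1)
#' random_mpc_dirichlet(16, 1)
#' @export
random_mpc_dirichlet <- function(n, concentration) {
  n <- check_count(n, "n", min = 2L)
  concentration <- check_number(concentration, "concentration", min = 0,
                                strict = TRUE)
  g <- rgamma(n, shape = concentration)
  while (sum(g) == 0) g <- rgamma(n, shape = concentration)  # tiny-shape underflow
  mpc(g)
}

# expected unevenness of a symmetric Dirichlet(n, a) composition:
# E[p_i ln p_i] = (1/n) (digamma(a + 1) - digamma(n a + 1))
dirichlet_expected_u <- function(n, a) {
  1 + (digamma(a + 1) - digamma(n * a + 1)) / log(n)
}

#' Random MPC with a prescribed unevenness
#'
#' Generates an MPC whose unevenness is within `tolerance` of `target_u`.
#' The symmetric-Dirichlet concentration whose *expected* unevenness equals
#' the target is found by root-finding on the digamma closed form; draws
#' from that Dirichlet are then rejection-sampled until one lands within
#' the tolerance.
#'
#' @param n Number of shares (`>= 2`).
#' @param target_u Target unevenness in `[0, 1)`; 0 returns the even MPC
#'   exactly.
#' @param tolerance Acceptance half-width on the realized unevenness.
#' @param max_tries Rejection budget before giving up.
#' @return An [mpc()] with `|unevenness - target_u| <= tolerance`.
#' @examples
#' set.seed(1)
#' unevenness(mpc_at_unevenness(16, 0.3))
#' @export
mpc_at_unevenness <- function(n, target_u, tolerance = 0.005,
                              max_tries = 10000L) {
  n <- check_count(n, "n", min = 2L)
  target_u <- check_number(target_u, "target_u", min = 0)
  if (target_u >= 1) abort_invalid("`target_u` must be below 1.")
  tolerance <- check_number(tolerance, "tolerance", min = 0, strict = TRUE)
  if (target_u == 0) return(mpc(rep(1, n)))
  f <- function(loga) dirichlet_expected_u(n, exp(loga)) - target_u
  a <- exp(uniroot(f, c(-30, 30), tol = 1e-10)$root)
  for (i in seq_len(max_tries)) {
    m <- random_mpc_dirichlet(n, a)
    if (abs(unevenness(m) - target_u) <= tolerance) return(m)
  }
  abort(sprintf("no MPC within %.3g of U = %.3g in %d tries.",
                tolerance, target_u, max_tries),
        class = "mutpie_error_generation")
}

#' Stream of simulated mutant observations
#'
#' Independent categorical draws from an MPC -- the model of observing one
#' sequenced mutant at a time in the laboratory.
#'
#' @inheritParams simulate_completion
#' @param n_draws Number of observations to draw.
#' @return Integer vector of element indices (1-based into the MPC rows).
#' @examples
#' set.seed(1)
#' table(mutant_stream(c(0.5, 0.5), 10))
#' @export
mutant_stream <- function(x, n_draws) {
  p <- shares(x)
  n_draws <- check_count(n_draws, "n_draws")
  sample.int(length(p), n_draws, replace = TRUE, prob = p)
}
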