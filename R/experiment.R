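#' Run a named experiment and write its report files
#'
#' A uniform front end over the package's analyses, suitable for scripting:
#' it seeds the RNG, runs the requested experiment, writes the result (TSV
#' for grid/distribution summaries, JSON for structured single results) and
#' a JSON run manifest recording the seed, the effective parameters and the
#' package version -- everything needed to reproduce the run bit for bit.
#' The thin command-line wrapper installed at `exec/mutpie` maps shell flags
#' onto this function.
#'
#' @param name One of `"completion"`, `"estimate-mpc"`, `"unevenness-dist"`,
#'   `"tmr"`, `"calibrate"`, `"repeatability"`, `"metrics"`.
#' @param params Named list of experiment-specific parameters:
#'   * `completion`: `mpc` (see below), `reps`.
#'   * `estimate-mpc`: `mpc`, `obs_grid`, `reps`.
#'   * `unevenness-dist` / `tmr`: `mean` (or `mu`), `sigma`, `n_sites`,
#'     `reps`, optional `family`.
#'   * `calibrate`: `spectrum` (TSV path) or `u_obs`; `mean`, `n_sites`,
#'     `sigma_grid`, `reps`.
#'   * `repeatability`: `sigma_grid`, `n_small`, `certainty`, `reps`,
#'     `batches`.
#'   * `metrics`: `mpc`.
#'
#'   An `mpc` parameter may be a numeric weight vector, `"even:N"`, a
#'   spectrum TSV path, or `"setup:<path>"` for a gene-setup TSV.
#' @param seed Integer RNG seed; recorded in the manifest.
#' @param out_dir Directory for report files (created if missing).
#' @param basename Stem for the output file names.
#' @return Invisibly, a list with `result` (the in-memory result) and
#'   `files` (paths written).
#' @examples
#' out <- run_experiment("metrics", list(mpc = "even:4"),
#'                       seed = 1, out_dir = tempdir())
#' out$result
#' @export
run_experiment <- function(name, params = list(), seed = 1L,
                           out_dir = ".", basename = name) {
  valid <- c("completion", "estimate-mpc", "unevenness-dist", "tmr",
             "calibrate", "repeatability", "metrics")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid)) {
    abort(sprintf("unknown experiment; use one of: %s.",
                  paste(valid, collapse = ", ")),
          class = "mutpie_error_usage")
  }
  seed <- check_count(seed, "seed", min = 0L)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(seed)
  p <- params
  res <- switch(
    name,
    completion = completion_distribution(
      parse_mpc_spec(p$mpc), reps = p$reps %||% 1e5),
    `estimate-mpc` = estimation_error_experiment(
      parse_mpc_spec(p$mpc), obs_grid = p$obs_grid %||% c(50, 100, 200, 500, 1000),
      reps = p$reps %||% 1e4),
    `unevenness-dist` = unevenness_distribution(
      parse_dmr_spec(p), n_sites = p$n_sites, reps = p$reps %||% 1e5,
      family = p$family %||% "lognormal"),
    tmr = tidy(tmr_distribution(
      parse_dmr_spec(p), n_sites = p$n_sites, reps = p$reps %||% 1e5,
      family = p$family %||% "lognormal")),
    calibrate = calibrate_sigma(
      u_obs = p$u_obs %||% unevenness(read_spectrum_tsv(p$spectrum)),
      mean = p$mean %||% 5e-11,
      n_sites = p$n_sites %||%
        (if (!is.null(p$spectrum)) nrow(read_spectrum_tsv(p$spectrum)) else
           abort_invalid("`n_sites` (or `spectrum`) is required.")),
      sigma_grid = p$sigma_grid %||% seq(0.1, 4.5, by = 0.05),
      reps = p$reps %||% 2e4),
    repeatability = repeatability_curve(
      sigma_grid = p$sigma_grid %||% 1.72,
      certainty = p$certainty %||% 0.95, n_small = p$n_small %||% 1L,
      reps = p$reps %||% 1e5, batches = p$batches %||% 1L),
    metrics = mpc_metrics(parse_mpc_spec(p$mpc)))

  files <- character(0)
  if (name %in% c("calibrate", "metrics")) {
    payload <- if (name == "calibrate") {
      g <- glance(res)
      c(as.list(g), list(grid = res$grid))
    } else {
      as.list(res)
    }
    f <- file.path(out_dir, paste0(basename, ".json"))
    jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = NA)
    files <- f
  } else {
    f <- file.path(out_dir, paste0(basename, ".tsv"))
    readr::write_tsv(as_tibble(res), f)
    files <- f
  }
  manifest <- list(
    experiment = name, seed = seed,
    params = params_for_manifest(params),
    package = "mutpie",
    version = as.character(utils::packageVersion("mutpie")),
    files = basename(files))
  mf <- file.path(out_dir, paste0(basename, "_manifest.json"))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(list(result = res, files = c(files, mf)))
}

params_for_manifest <- function(p) {
  lapply(p, function(v) if (is.numeric(v) && length(v) > 20L) {
    list(length = length(v), min = min(v), max = max(v))
  } else v)
}

# mpc parameter mini-language shared with the command line
parse_mpc_spec <- function(x) {
  if (is.null(x)) abort_invalid("an `mpc` parameter is required.")
  if (is.numeric(x) || is.data.frame(x) || inherits(x, "mpc")) {
    return(as_mpc(x))
  }
  if (is.character(x) && length(x) == 1L) {
    if (startsWith(x, "even:")) {
      return(mpc(rep(1, check_count(as.numeric(sub("^even:", "", x)), "N"))))
    }
    if (startsWith(x, "setup:")) {
      return(as_mpc(read_gene_setup_tsv(sub("^setup:", "", x))))
    }
    return(as_mpc(read_spectrum_tsv(x)))
  }
  abort_invalid("cannot interpret the `mpc` parameter.")
}

parse_dmr_spec <- function(p) {
  if (!is.null(p$mu)) {
    lognormal_dmr(p$mu, p$sigma)
  } else {
    dmr_from_mean_sigma(p$mean %||% 5e-11, p$sigma)
  }
}
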