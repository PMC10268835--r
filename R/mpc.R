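#' Build a mutation pie chart (MPC)
#'
#' An MPC distributes probability 1 among a set of mutational elements
#' (mutations, genes or pathways): each share is the relative rate at which
#' the corresponding element produces the focal phenotype. `mpc()` accepts
#' raw weights -- occurrence counts, estimated numbers of mutations, or
#' absolute rates -- and normalizes them, so spectrum tables can be used
#' verbatim.
#'
#' @param weights Numeric vector of non-negative weights; at least one must
#'   be positive. They are divided by their sum, preserving order.
#' @param label Optional character vector of per-element identifiers
#'   (e.g. mutation names). Defaults to `"e1"`, `"e2"`, ...
#' @param gene Optional character vector assigning each element to a gene
#'   (or pathway); used by [aggregate_genes()].
#'
#' @return A tibble of class `"mpc"` with columns `label`, `gene` and
#'   `share`. Shares sum to 1 (within 1e-9) and are all `>= 0`.
#'
#' @examples
#' mpc(c(2, 2))
#' mpc(c(1, 1, 9, 1), gene = c("awsO", "awsO", "awsR", "awsR"))
#' @export
mpc <- function(weights, label = NULL, gene = NULL) {
  if (!is.numeric(weights) || length(weights) < 1L) {
    abort_invalid("`weights` must be a numeric vector of length >= 1.")
  }
  if (anyNA(weights) || any(!is.finite(weights))) {
    abort_invalid("`weights` must be finite and non-missing.")
  }
  if (any(weights < 0)) {
    abort_invalid("`weights` must be non-negative.")
  }
  total <- sum(weights)
  if (total <= 0) {
    abort_invalid("`weights` must contain at least one positive value.")
  }
  n <- length(weights)
  label <- label %||% paste0("e", seq_len(n))
  gene <- gene %||% rep(NA_character_, n)
  if (length(label) != n || length(gene) != n) {
    abort_invalid("`label` and `gene` must match `weights` in length.")
  }
  out <- tibble(label = as.character(label), gene = as.character(gene),
                share = as.numeric(weights) / total)
  class(out) <- c("mpc", class(out))
  out
}

#' Coerce to an MPC
#'
#' Accepts a numeric weight vector, an existing MPC, or a data frame holding
#' one of the weight columns `share`, `count`, `n_mutations` or `rate`
#' (searched in that order), with optional `mutation`/`label` and `gene`
#' columns.
#'
#' @param x Object to coerce.
#' @return An [mpc()] tibble.
#' @examples
#' as_mpc(data.frame(gene = c("a", "b"), count = c(3, 1)))
#' @export
as_mpc <- function(x) {
  if (inherits(x, "mpc")) return(x)
  if (is.numeric(x)) return(mpc(x))
  if (is.data.frame(x)) {
    wcol <- intersect(c("share", "count", "n_mutations", "rate"), names(x))
    if (length(wcol) == 0L) {
      abort_invalid(
        "data frame needs a `share`, `count`, `n_mutations` or `rate` column.")
    }
    label <- if ("mutation" %in% names(x)) x$mutation
             else if ("label" %in% names(x)) x$label
             else if ("gene" %in% names(x)) x$gene
             else NULL
    gene <- if ("gene" %in% names(x)) x$gene else NULL
    return(mpc(x[[wcol[1L]]], label = label, gene = gene))
  }
  abort_invalid("cannot coerce this object to an MPC.")
}

# shares as a bare numeric vector; the common entry point for metrics
shares <- function(x) {
  if (is.numeric(x)) {
    m <- mpc(x)
    return(m$share)
  }
  as_mpc(x)$share
}

check_metric_input <- function(p) {
  if (length(p) < 2L) {
    abort_metric("imbalance metrics need at least 2 shares (ln 1 = 0).")
  }
  p
}

#' Shannon-evenness-based unevenness index
#'
#' The unevenness index summarizes the imbalance of an MPC from Shannon's
#' diversity index \eqn{H'}: \eqn{U = 1 - H'/\ln n = 1 + (1/\ln n) \sum_i
#' p_i \ln p_i}, with the convention \eqn{0 \ln 0 = 0}. `U = 0` iff all
#' shares are equal, and `U = 1` iff a single element takes the whole chart.
#'
#' @param x An MPC, a data frame coercible via [as_mpc()], or a numeric
#'   weight vector (normalized first).
#' @return A number in `[0, 1]`.
#' @examples
#' unevenness(rep(1, 4))          # 0
#' unevenness(c(0.5, 0.5, 0, 0))  # 0.5
#' unevenness(aws_spectrum())     # 0.315, the observed aws value
#' @export
unevenness <- function(x) {
  p <- check_metric_input(shares(x))
  pos <- p[p > 0]
  1 + sum(pos * log(pos)) / log(length(p))
}

#' Gini inequality coefficient of an MPC
#'
#' Pairwise-comparison imbalance measure
#' \eqn{G = (1/(2 n^2 \bar p)) \sum_i \sum_j |p_i - p_j|} with
#' \eqn{\bar p = 1/n}. Zero iff all shares are equal; its maximum,
#' \eqn{1 - 1/n}, is reached when one element takes everything.
#'
#' @inheritParams unevenness
#' @return A number in `[0, 1 - 1/n]`.
#' @examples
#' gini(c(1, 0, 0, 0))  # 0.75
#' @export
gini <- function(x) {
  p <- check_metric_input(shares(x))
  n <- length(p)
  # sum_{i,j} |p_i - p_j| via the sorted-shares identity, O(n log n)
  s <- sort(p)
  tot <- 2 * sum((2 * seq_len(n) - n - 1) * s)
  tot / (2 * n)
}

#' Sum of the two largest shares (SLS2)
#'
#' The most experimentally intuitive imbalance measure: the combined
#' probability of the two most common elements. Minimal (`2/n`) on the even
#' MPC; 1 iff two elements exhaust the chart.
#'
#' @inheritParams unevenness
#' @return A number in `(0, 1]`.
#' @examples
#' sls2(c(0.6, 0.3, 0.1))  # 0.9
#' @export
sls2 <- function(x) {
  p <- check_metric_input(shares(x))
  sum(sort(p, decreasing = TRUE)[1:2])
}

#' All three MPC imbalance metrics at once
#'
#' @inheritParams unevenness
#' @return A one-row tibble with columns `n`, `unevenness`, `gini`, `sls2`.
#' @examples
#' mpc_metrics(aws_spectrum())
#' @export
mpc_metrics <- function(x) {
  p <- shares(x)
  tibble(n = length(p), unevenness = unevenness(p), gini = gini(p),
         sls2 = sls2(p))
}

#' Aggregate an MPC to the gene (or pathway) level
#'
#' A gene's share is the sum of the shares of its member mutations, matching
#' the convention that a pathway's rate is the sum of its mutations' rates.
#'
#' @param x An MPC (or coercible object).
#' @param grouping Optional character vector, one gene label per share;
#'   defaults to the MPC's `gene` column. Every share must be assigned.
#' @return An [mpc()] with one share per gene, in order of first appearance.
#' @examples
#' aggregate_genes(aws_spectrum())  # shares of awsO, awsR, awsX
#' @export
aggregate_genes <- function(x, grouping = NULL) {
  m <- as_mpc(x)
  grouping <- grouping %||% m$gene
  if (length(grouping) != nrow(m) || anyNA(grouping)) {
    abort_grouping("every share must be assigned to exactly one gene.")
  }
  grouping <- as.character(grouping)
  genes <- unique(grouping)
  agg <- vapply(genes, function(g) sum(m$share[grouping == g]), numeric(1))
  mpc(agg, label = genes, gene = genes)
}

#' @export
print.mpc <- function(x, ...) {
  cat(sprintf("# A mutation pie chart: %d shares\n", nrow(x)))
  NextMethod()
  invisible(x)
}
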