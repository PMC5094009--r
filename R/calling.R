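# Expression calling: thresholding raw FPKM into called values, per-gene
# max-normalisation, and per-sample expressed gene sets. The 2-FPKM floor
# removes spurious or background read counts before any downstream logic;
# every expressed/silent decision in the package flows from it.

#' Call expression by thresholding FPKM values
#'
#' Sets every value below the threshold to zero and leaves the rest
#' unchanged, so each cell is either 0 or an expression level at or above
#' the floor. The default floor of 2 FPKM treats sub-threshold signal as
#' background. The boundary is inclusive by default (`cmp = "ge"`: a value
#' exactly at the threshold counts as expressed); set `cmp = "gt"` for a
#' strict boundary.
#'
#' Calling is idempotent, and raising the threshold never adds expressed
#' calls.
#'
#' @param x Expression tibble (`gene_id` + numeric sample columns).
#' @param threshold Positive expression floor in FPKM-equivalent units.
#' @param cmp `"ge"` (expressed iff value >= threshold, default) or
#'   `"gt"` (strictly greater).
#' @return A called expression tibble of the same shape, with attributes
#'   `threshold` and `cmp`.
#' @export
#' @examples
#' m <- tibble::tibble(gene_id = "A", s1 = 1.9, s2 = 2.0)
#' call_expression(m) # s1 -> 0, s2 kept
call_expression <- function(x, threshold = 2, cmp = c("ge", "gt")) {
  cmp <- match.arg(cmp)
  if (!is.numeric(threshold) || length(threshold) != 1 || !is.finite(threshold) ||
      threshold <= 0) {
    abort("`threshold` must be a single positive number.")
  }
  m <- expr_matrix(x)
  keep <- if (cmp == "ge") m >= threshold else m > threshold
  m[!keep] <- 0
  out <- expr_tibble(m)
  attr(out, "threshold") <- threshold
  attr(out, "cmp") <- cmp
  out
}

#' Normalise each gene to its maximal expression
#'
#' Divides every row by its own maximum so each gene's profile lies in
#' \[0, 1\] with maximum exactly 1; rows that are entirely zero (genes
#' with no called expression anywhere) stay entirely zero rather than
#' erroring. Intended to run on a called matrix so sub-threshold noise
#' does not set the scale.
#'
#' @param x Called (or raw) expression tibble.
#' @return A tibble of the same shape with values in \[0, 1\].
#' @export
normalize_to_max <- function(x) {
  m <- expr_matrix(x)
  if (ncol(m) > 0 && nrow(m) > 0) {
    mx <- apply(m, 1, max)
    scale <- ifelse(mx > 0, mx, 1)
    m <- m / scale
  }
  expr_tibble(m)
}

#' Genes expressed in one sample
#'
#' The set of genes whose called value is positive in the given sample.
#' Together with [genes_per_sample()] this is the column-wise view of the
#' called matrix; [expression_breadth()] is the row-wise view.
#'
#' @param x Called expression tibble.
#' @param sample_id A single sample identifier present in `x`.
#' @return Character vector of gene ids.
#' @export
expressed_genes <- function(x, sample_id) {
  m <- expr_matrix(x)
  if (length(sample_id) != 1) abort("`sample_id` must be a single id.")
  check_samples_present(sample_id, colnames(m))
  rownames(m)[m[, sample_id] > 0]
}
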