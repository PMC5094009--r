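# Tissue-set exclusivity: genes called expressed in at least one sample
# of a designated target set (e.g. reproductive tissues plus
# preimplantation stages) and silent in every other sample, with each
# gene's peak stage recorded so peaks can be located within a
# developmental window such as 8-cell to morula.

#' Genes expressed exclusively in a target sample set
#'
#' Filters a called matrix for genes with positive expression in at least
#' one target sample and zero called expression in every non-target
#' sample. For each exclusive gene the peak (maximal) target sample and
#' value are recorded. Ties for the maximum are resolved to the earliest
#' temporal rank when `samples` is supplied (column order otherwise) and
#' flagged in `peak_tie`.
#'
#' @param x Called expression tibble.
#' @param target_samples Character vector: a non-empty proper subset of
#'   the matrix samples.
#' @param samples Optional sample annotation; when given, target columns
#'   are ordered by `temporal_rank` (ranked samples first) before peak
#'   ties are broken.
#' @return A tibble of class `hbx_exclusivity` with columns `gene_id`,
#'   `peak_sample`, `peak_value`, `peak_tie`, and attribute
#'   `target_samples`.
#' @export
#' @examples
#' m <- tibble::tibble(gene_id = c("a", "b"),
#'                     oocyte = c(5, 5), liver = c(0, 3))
#' exclusive_to(m, "oocyte") # only "a"
exclusive_to <- function(x, target_samples, samples = NULL) {
  m <- expr_matrix(x)
  all_samples <- colnames(m)
  target_samples <- unique(target_samples)
  check_samples_present(target_samples, all_samples, what = "target sample")
  if (length(target_samples) == 0) abort("`target_samples` must be non-empty.")
  if (length(target_samples) == length(all_samples)) {
    abort("`target_samples` must be a proper subset of the matrix samples.")
  }
  if (!is.null(samples)) {
    samples <- check_sample_annotation(samples)
    rk <- setNames(samples$temporal_rank, samples$sample_id)[target_samples]
    target_samples <- target_samples[order(is.na(rk), rk)]
  }
  other <- setdiff(all_samples, target_samples)
  tgt <- m[, target_samples, drop = FALSE]
  keep <- rowSums(tgt > 0) > 0 & rowSums(m[, other, drop = FALSE] > 0) == 0
  tgt <- tgt[keep, , drop = FALSE]
  if (nrow(tgt) == 0) {
    out <- tibble(gene_id = character(), peak_sample = character(),
                  peak_value = double(), peak_tie = logical())
  } else {
    peak_idx <- apply(tgt, 1, which.max)
    out <- tibble(
      gene_id = rownames(tgt),
      peak_sample = target_samples[peak_idx],
      peak_value = tgt[cbind(seq_len(nrow(tgt)), peak_idx)],
      peak_tie = apply(tgt, 1, function(r) sum(r == max(r)) > 1)
    )
  }
  attr(out, "target_samples") <- target_samples
  class(out) <- c("hbx_exclusivity", class(out))
  out
}

#' Restrict exclusive genes to a developmental peak window
#'
#' Keeps the exclusive genes whose peak sample has a temporal rank inside
#' `window` (inclusive bounds). Genes peaking in unranked samples (e.g.
#' adult reproductive tissues in a mixed target set) are never inside a
#' window; pass the full ranked range to retrieve every gene with a
#' ranked peak.
#'
#' @param result Tibble from [exclusive_to()].
#' @param samples Sample annotation with `temporal_rank`.
#' @param window Numeric length-2 vector `c(rank_lo, rank_hi)` with
#'   `rank_lo <= rank_hi`, inside the annotated rank range.
#' @return The filtered exclusivity tibble with an added `peak_rank`
#'   column.
#' @export
peak_in_window <- function(result, samples, window) {
  samples <- check_sample_annotation(samples)
  if (length(window) != 2 || window[1] > window[2]) {
    abort("`window` must be c(rank_lo, rank_hi) with rank_lo <= rank_hi.")
  }
  ranks <- samples$temporal_rank[!is.na(samples$temporal_rank)]
  if (length(ranks) == 0) abort("No sample carries a temporal_rank.")
  if (window[1] < min(ranks) || window[2] > max(ranks)) {
    abort(sprintf("`window` [%s, %s] lies outside the ranked range [%d, %d].",
                  window[1], window[2], min(ranks), max(ranks)))
  }
  rk <- setNames(samples$temporal_rank, samples$sample_id)
  out <- as_tibble(result)
  out$peak_rank <- unname(rk[out$peak_sample])
  out[!is.na(out$peak_rank) & out$peak_rank >= window[1] & out$peak_rank <= window[2], ]
}

#' Extend a target sample set with manual additions
#'
#' Unions extra samples (e.g. adding ovary to a clustering-derived
#' reproductive set that did not capture it) into a target set,
#' validating each addition against the matrix samples and reporting the
#' manual provenance.
#'
#' @param target_samples Current target set (character).
#' @param extra_samples Samples to add.
#' @param sample_ids All sample ids of the matrix, for validation.
#' @return Character vector: the union, original order first.
#' @export
augment_target_set <- function(target_samples, extra_samples, sample_ids) {
  check_samples_present(extra_samples, sample_ids)
  added <- setdiff(extra_samples, target_samples)
  if (length(added) > 0) {
    inform(sprintf("Manually added to target set: %s", toString(added)))
  }
  c(target_samples, added)
}

#' @export
print.hbx_exclusivity <- function(x, ...) {
  cat(sprintf("<hbx_exclusivity> %d exclusive gene(s) over %d target sample(s)\n",
              nrow(x), length(attr(x, "target_samples"))))
  NextMethod()
}
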