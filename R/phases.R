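# Temporal phase segmentation of a stage-ordered developmental series:
# quantify the turnover of the expressed gene set between consecutive
# stages (the "gear changes") and place phase boundaries at the largest
# turnovers. A boundary at position p separates the stage of temporal
# rank index p-1 from the stage at index p (positions count gaps,
# 1..n_stages-1 along the rank order).

#' Expressed-set turnover between consecutive stages
#'
#' For every pair of consecutive stages (ordered by `temporal_rank`)
#' computes the Jaccard distance between their expressed gene sets:
#' 0 when the same genes are on (or both sets are empty), 1 when the sets
#' are disjoint. All samples must carry a temporal rank.
#'
#' @param x Called expression tibble whose samples are developmental
#'   stages.
#' @param samples Sample annotation; every matrix sample must have a
#'   `temporal_rank`.
#' @return A tibble of class `hbx_turnover` with columns `position`
#'   (gap index 1..n_stages-1), `from_stage`, `to_stage`, `turnover`.
#' @export
stage_turnover <- function(x, samples) {
  m <- expr_matrix(x)
  samples <- check_sample_annotation(samples)
  check_samples_present(colnames(m), samples$sample_id)
  ann <- samples[match(colnames(m), samples$sample_id), ]
  if (anyNA(ann$temporal_rank)) {
    abort(sprintf("Sample(s) without temporal_rank: %s",
                  toString(ann$sample_id[is.na(ann$temporal_rank)])))
  }
  if (ncol(m) < 2) abort("Need at least 2 staged samples.")
  ord <- ann$sample_id[order(ann$temporal_rank)]
  sets <- lapply(ord, function(s) rownames(m)[m[, s] > 0])
  out <- tibble(
    position = seq_len(length(ord) - 1),
    from_stage = ord[-length(ord)],
    to_stage = ord[-1],
    turnover = purrr::map_dbl(seq_len(length(ord) - 1),
                              function(i) jaccard_distance(sets[[i]], sets[[i + 1]]))
  )
  class(out) <- c("hbx_turnover", class(out))
  out
}

#' Place phase boundaries at the largest turnovers
#'
#' Selects the `n_boundaries` gaps with the highest turnover (ties broken
#' toward the earlier position) and returns them in stage order. With
#' `n_boundaries` boundaries the series falls into `n_boundaries + 1`
#' phases.
#'
#' @param turnover Tibble from [stage_turnover()].
#' @param n_boundaries Number of boundaries, between 1 and the number of
#'   gaps (default 3, giving four phases).
#' @return A tibble of class `hbx_boundaries`: the selected rows of
#'   `turnover`, ascending by position, with attribute `n_phases`.
#' @export
detect_boundaries <- function(turnover, n_boundaries = 3) {
  n_gaps <- nrow(turnover)
  if (n_boundaries < 1 || n_boundaries > n_gaps) {
    abort(sprintf("`n_boundaries` must be in 1..%d.", n_gaps))
  }
  picked <- order(-turnover$turnover, turnover$position)[seq_len(n_boundaries)]
  out <- turnover[sort(picked), ]
  attr(out, "n_phases") <- n_boundaries + 1L
  class(out) <- c("hbx_boundaries", class(out))
  out
}

#' Phase id of every stage given boundary positions
#'
#' @param boundaries Integer vector of boundary positions (gap indices),
#'   strictly increasing within 1..n_stages-1.
#' @param n_stages Number of stages.
#' @return Integer vector of length `n_stages`: phase id (1-based) per
#'   stage in rank order.
#' @export
phase_of_stages <- function(boundaries, n_stages) {
  boundaries <- as.integer(boundaries)
  if (is.unsorted(boundaries, strictly = TRUE) ||
      any(boundaries < 1) || any(boundaries > n_stages - 1)) {
    abort("`boundaries` must be strictly increasing within 1..n_stages-1.")
  }
  as.integer(findInterval(seq_len(n_stages) - 1, boundaries) + 1)
}

#' Cluster staged profiles into temporal groups
#'
#' Delegates to [cluster_genes()]/[cut_groups()] on the stage-ordered
#' normalised matrix, then summarises each gene by its onset (first
#' expressed rank) and offset (last expressed rank). Genes never
#' expressed in the series are set aside in a reserved `"silent"` group
#' and are not clustered (their profiles carry no temporal signal).
#'
#' @param x Normalised expression tibble over staged samples.
#' @param samples Sample annotation; all matrix samples must be ranked.
#' @param k Number of temporal groups among the expressed genes.
#' @param distance,linkage Passed to [cluster_genes()].
#' @return A tibble with columns `gene_id`, `group` (character `"1"`,
#'   `"2"`, ... or `"silent"`), `onset`, `offset` (temporal ranks, NA for
#'   silent genes).
#' @export
assign_temporal_groups <- function(x, samples, k,
                                   distance = "correlation",
                                   linkage = "average") {
  m <- expr_matrix(x)
  samples <- check_sample_annotation(samples)
  check_samples_present(colnames(m), samples$sample_id)
  ann <- samples[match(colnames(m), samples$sample_id), ]
  if (anyNA(ann$temporal_rank)) {
    abort(sprintf("Sample(s) without temporal_rank: %s",
                  toString(ann$sample_id[is.na(ann$temporal_rank)])))
  }
  m <- m[, ann$sample_id[order(ann$temporal_rank)], drop = FALSE]
  ranks <- sort(ann$temporal_rank)
  silent <- rowSums(m > 0) == 0
  live <- rownames(m)[!silent]
  if (length(live) < 2) abort("Fewer than 2 expressed genes; nothing to cluster.")
  if (k < 1 || k > length(live)) abort(sprintf("`k` must be in 1..%d.", length(live)))
  dend <- cluster_genes(expr_tibble(m[live, , drop = FALSE]),
                        distance = distance, linkage = linkage)
  cl <- cut_groups(dend, k = k)
  onset <- apply(m[live, , drop = FALSE], 1, function(r) ranks[which(r > 0)[1]])
  offset <- apply(m[live, , drop = FALSE], 1, function(r) ranks[max(which(r > 0))])
  out <- tibble(
    gene_id = c(live, rownames(m)[silent]),
    group = c(as.character(cl$group), rep("silent", sum(silent))),
    onset = c(unname(onset), rep(NA_integer_, sum(silent))),
    offset = c(unname(offset), rep(NA_integer_, sum(silent)))
  )
  out[match(rownames(m), out$gene_id), ]
}
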