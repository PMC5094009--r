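# Expression breadth (in how many samples is each gene expressed?) and
# its summaries: Tukey five-number statistics per evolutionary gene class,
# widespread-gene identification, and the per-sample dual (how many genes
# does each tissue express?).

#' Expression breadth per gene
#'
#' Counts, for every gene, the samples (optionally restricted to a
#' subset, e.g. adult tissues only) in which its called value is
#' positive. Breadth 0 means the gene is never expressed; low breadth
#' means high tissue specificity. Breadth is invariant under per-gene
#' max-normalisation and under sample permutation.
#'
#' @param x Called expression tibble.
#' @param sample_subset Optional character vector of sample ids to count
#'   over; default all samples.
#' @return A tibble of class `hbx_breadth` with columns `gene_id`,
#'   `breadth`, and an `n_samples` attribute recording the size of the
#'   sample universe counted over.
#' @export
expression_breadth <- function(x, sample_subset = NULL) {
  m <- expr_matrix(x)
  if (!is.null(sample_subset)) {
    check_samples_present(sample_subset, colnames(m))
    m <- m[, sample_subset, drop = FALSE]
  }
  out <- tibble(gene_id = rownames(m), breadth = as.integer(rowSums(m > 0)))
  attr(out, "n_samples") <- ncol(m)
  class(out) <- c("hbx_breadth", class(out))
  out
}

#' Summarise breadth by homeobox class
#'
#' Tukey five-number summary of expression breadth within each gene
#' class, using the boxplot convention: box from lower to upper hinge
#' with the median inside, whiskers at the furthest observation within
#' 1.5 x IQR of the hinges, and everything beyond listed as an outlier.
#' Classes named in the annotation but absent from the breadth table are
#' omitted with a warning.
#'
#' @param b Breadth tibble from [expression_breadth()].
#' @param genes Gene annotation tibble covering every gene in `b`.
#' @return A tibble with one row per class: `hbx_class`, `n_genes`,
#'   `whisker_low`, `hinge_low`, `median`, `hinge_high`, `whisker_high`
#'   and a list column `outlier_genes`.
#' @export
class_breadth_summary <- function(b, genes) {
  genes <- check_gene_annotation(genes)
  missing <- setdiff(b$gene_id, genes$gene_id)
  if (length(missing) > 0) {
    abort(sprintf("Gene(s) missing from annotation: %s", toString(head(missing, 5))))
  }
  empty <- setdiff(unique(genes$hbx_class), genes$hbx_class[genes$gene_id %in% b$gene_id])
  if (length(empty) > 0) {
    warn(sprintf("Class(es) with zero genes omitted: %s", toString(empty)))
  }
  dplyr::inner_join(as_tibble(b), genes[, c("gene_id", "hbx_class")], by = "gene_id") |>
    dplyr::group_by(.data$hbx_class) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      .stats = list(tukey_summary(.data$breadth, .data$gene_id)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider(".stats") |>
    dplyr::mutate(outlier_genes = purrr::map(.data$outlier_genes, unlist2chr))
}

# Tukey hinges + 1.5 IQR whiskers, returning whisker limits at the most
# extreme observations still inside the fences (grDevices::boxplot.stats
# convention).
tukey_summary <- function(values, ids) {
  fn <- fivenum(values)
  iqr <- fn[4] - fn[2]
  lo_fence <- fn[2] - 1.5 * iqr
  hi_fence <- fn[4] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(
    whisker_low = min(values[inside]),
    hinge_low = fn[2],
    median = fn[3],
    hinge_high = fn[4],
    whisker_high = max(values[inside]),
    outlier_genes = list(ids[!inside])
  )
}

#' Identify widely expressed genes
#'
#' Two routes to the "widespread expression" set:
#'
#' * **cluster route** (used when `groups` is supplied and carries a
#'   `widespread` label, the route truest to reading the set off a
#'   clustered heatmap): the members of the widespread-labelled
#'   cluster(s);
#' * **threshold route** (fallback): genes whose breadth is at least
#'   `min_fraction` of the sample universe.
#'
#' @param b Breadth tibble from [expression_breadth()].
#' @param min_fraction Fraction of samples in (0, 1] for the threshold
#'   route (default 0.9).
#' @param groups Optional labelled group tibble from [label_groups()].
#' @return A tibble with columns `gene_id` and `route` (`"cluster"` or
#'   `"breadth"`).
#' @export
classify_widespread <- function(b, min_fraction = 0.9, groups = NULL) {
  if (!is.null(groups) && "label" %in% names(groups) &&
      any(groups$label == "widespread")) {
    return(tibble(
      gene_id = groups$gene_id[groups$label == "widespread"],
      route = "cluster"
    ))
  }
  if (min_fraction <= 0 || min_fraction > 1) abort("`min_fraction` must be in (0, 1].")
  n <- attr(b, "n_samples")
  if (is.null(n)) abort("`b` lacks its n_samples attribute; use expression_breadth().")
  tibble(
    gene_id = b$gene_id[b$breadth >= min_fraction * n],
    route = "breadth"
  )
}

#' Expressed genes per sample
#'
#' Counts, for every sample, the genes with positive called value: the
#' column-wise dual of [expression_breadth()]. The two satisfy the
#' double-counting identity sum(genes_per_sample) == sum(breadth).
#'
#' @param x Called expression tibble.
#' @return A tibble with columns `sample_id`, `n_genes`.
#' @export
genes_per_sample <- function(x) {
  m <- expr_matrix(x)
  tibble(sample_id = colnames(m), n_genes = as.integer(colSums(m > 0)))
}

# Flatten a possibly list-wrapped id vector to character.
unlist2chr <- function(x) {
  out <- unlist(x, use.names = FALSE)
  if (is.null(out)) character(0) else as.character(out)
}
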