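# broom-style tidiers for the package's fitted/derived objects.

#' Tidy a gene dendrogram
#'
#' One row per agglomeration step: the merge height and the size of the
#' cluster formed. Heights are non-decreasing along any root path.
#'
#' @param x A `gene_dendrogram` from [cluster_genes()].
#' @param ... Unused.
#' @return A tibble with columns `step`, `height`, `size`.
#' @method tidy gene_dendrogram
#' @export
tidy.gene_dendrogram <- function(x, ...) {
  hc <- x$hclust
  sizes <- integer(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    sizes[i] <- sum(vapply(hc$merge[i, ], function(j) {
      if (j < 0) 1L else sizes[j]
    }, integer(1)))
  }
  tibble(step = seq_len(nrow(hc$merge)), height = hc$height, size = sizes)
}

#' @rdname tidy.gene_dendrogram
#' @return For `glance()`: a one-row tibble with `n_genes`, `distance`,
#'   `linkage`, `max_height`.
#' @method glance gene_dendrogram
#' @export
glance.gene_dendrogram <- function(x, ...) {
  tibble(n_genes = x$n_genes, distance = x$distance, linkage = x$linkage,
         max_height = max(x$hclust$height))
}

#' Tidy an exclusivity result
#'
#' Returns the per-gene table as a plain tibble; `glance()` gives the
#' run-level counts.
#'
#' @param x An `hbx_exclusivity` from [exclusive_to()].
#' @param ... Unused.
#' @method tidy hbx_exclusivity
#' @export
tidy.hbx_exclusivity <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @rdname tidy.hbx_exclusivity
#' @method glance hbx_exclusivity
#' @export
glance.hbx_exclusivity <- function(x, ...) {
  tibble(
    n_exclusive = nrow(x),
    n_target_samples = length(attr(x, "target_samples")),
    n_peak_ties = sum(x$peak_tie)
  )
}

#' @rdname tidy.hbx_boundaries
#' @method glance hbx_boundaries
#' @export
glance.hbx_boundaries <- function(x, ...) {
  tibble(
    n_boundaries = nrow(x),
    n_phases = attr(x, "n_phases"),
    min_turnover = min(x$turnover),
    max_turnover = max(x$turnover)
  )
}

#' Tidy detected phase boundaries
#'
#' @param x An `hbx_boundaries` from [detect_boundaries()].
#' @param ... Unused.
#' @method tidy hbx_boundaries
#' @export
tidy.hbx_boundaries <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}
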