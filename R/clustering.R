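# Hierarchical clustering of normalised expression profiles into
# expression groups: the computational counterpart of reading macro-groups
# (widespread, neural, immune, reproductive/developmental, organ-specific,
# no-expression) off a clustered heatmap.

#' Cluster gene expression profiles
#'
#' Agglomerative hierarchical clustering of the rows of a (normally
#' max-normalised) expression matrix. The default metric is
#' Pearson-correlation distance (1 - r), the standard choice for
#' expression heatmaps because it compares profile shape rather than
#' magnitude.
#'
#' Correlation is undefined on constant rows. Rows that are constant
#' (after max-normalisation these are exactly the all-zero, never-expressed
#' genes) are placed at distance 0 from identical constant rows and at the
#' maximal correlation distance 2 from every non-constant profile, so
#' silent genes coalesce into their own cluster instead of attaching
#' arbitrarily to sparse tissue-specific profiles. A matrix in which every
#' row is constant has no usable correlation structure and errors with
#' advice to use `distance = "euclidean"`.
#'
#' @param x Normalised expression tibble (`gene_id` + numeric columns).
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage `"average"` (default), `"complete"` or `"ward"`
#'   (Ward's D2 on the chosen distance).
#' @return An object of class `gene_dendrogram` wrapping the
#'   [stats::hclust] tree with the gene ids and parameters used.
#' @export
#' @examples
#' m <- tibble::tibble(gene_id = c("a", "b", "c"),
#'                     s1 = c(1, 1, 0), s2 = c(0, 0, 1))
#' cluster_genes(m, distance = "euclidean")
cluster_genes <- function(x,
                          distance = c("correlation", "euclidean"),
                          linkage = c("average", "complete", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  m <- expr_matrix(x)
  if (nrow(m) < 2) abort("Need at least 2 genes to cluster.")
  if (distance == "euclidean") {
    d <- stats::dist(m, method = "euclidean")
  } else {
    constant <- apply(m, 1, function(r) max(r) == min(r))
    if (all(constant)) {
      abort(paste(
        "All rows are constant; correlation distance is undefined.",
        "Use distance = \"euclidean\" instead."
      ))
    }
    dm <- matrix(0, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
    live <- which(!constant)
    if (length(live) > 1) {
      cc <- suppressWarnings(cor(t(m[live, , drop = FALSE])))
      dm[live, live] <- 1 - cc
    }
    if (any(constant)) {
      dead <- which(constant)
      dm[dead, live] <- 2
      dm[live, dead] <- 2
      if (length(dead) > 1) {
        # constant rows at different levels are still distinct profiles
        lev <- m[dead, 1]
        dm[dead, dead] <- 2 * outer(lev, lev, Vectorize(function(a, b) a != b))
      }
    }
    diag(dm) <- 0
    d <- as.dist(dm)
  }
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- hclust(d, method = method)
  structure(
    list(hclust = hc, gene_ids = rownames(m), distance = distance,
         linkage = linkage, n_genes = nrow(m)),
    class = "gene_dendrogram"
  )
}

#' @export
print.gene_dendrogram <- function(x, ...) {
  cat(sprintf("<gene_dendrogram> %d genes, %s distance, %s linkage\n",
              x$n_genes, x$distance, x$linkage))
  invisible(x)
}

#' Cut a gene dendrogram into expression groups
#'
#' Cuts the tree into exactly `k` groups, or undoes every merge above
#' height `h`. Cuts at successive `k` are nested refinements. Group ids
#' are integers in order of first appearance along the gene list; use
#' [label_groups()] to attach biological labels.
#'
#' @param dend A `gene_dendrogram` from [cluster_genes()].
#' @param k Number of groups (1..n_genes), or `NULL`.
#' @param h Cut height >= 0, or `NULL`. Exactly one of `k`, `h` must be
#'   given.
#' @return A tibble with columns `gene_id`, `group` (integer).
#' @export
cut_groups <- function(dend, k = NULL, h = NULL) {
  stopifnot(inherits(dend, "gene_dendrogram"))
  if (is.null(k) == is.null(h)) abort("Supply exactly one of `k` or `h`.")
  if (!is.null(k)) {
    if (k < 1 || k > dend$n_genes) {
      abort(sprintf("`k` must be in 1..%d.", dend$n_genes))
    }
    cl <- cutree(dend$hclust, k = k)
  } else {
    if (h < 0) abort("`h` must be >= 0.")
    cl <- cutree(dend$hclust, h = h)
  }
  tibble(gene_id = dend$gene_ids, group = as.integer(unname(cl)))
}

#' Label expression groups by where their genes peak
#'
#' Attaches a biological label to each group of a partition from
#' [cut_groups()]:
#'
#' * a group whose members all have all-zero called rows is
#'   `no_expression`;
#' * a group whose members' median expression breadth covers at least
#'   `widespread_fraction` of the samples is `widespread`;
#' * otherwise the label is the dominant sample-annotation `group` among
#'   the members' sites of maximal called expression (peak-site ties go to
#'   the first sample column). A tie between dominant sample groups is
#'   broken lexicographically and flagged `ambiguous`.
#'
#' @param groups Tibble from [cut_groups()] (`gene_id`, `group`).
#' @param called Called expression tibble covering the same genes.
#' @param samples Sample annotation tibble with a `group` column.
#' @param widespread_fraction Breadth fraction above which a cluster is
#'   called widespread (default 0.9).
#' @return `groups` with added columns `label` and `ambiguous`.
#' @export
label_groups <- function(groups, called, samples, widespread_fraction = 0.9) {
  m <- expr_matrix(called)
  samples <- check_sample_annotation(samples)
  check_samples_present(colnames(m), samples$sample_id)
  if (!setequal(groups$gene_id, rownames(m))) {
    abort("`groups` must partition exactly the genes of `called`.")
  }
  m <- m[groups$gene_id, , drop = FALSE]
  sgroup <- setNames(samples$group, samples$sample_id)
  peak_idx <- apply(m, 1, which.max)
  peak_group <- unname(sgroup[colnames(m)[peak_idx]])
  breadth_n <- rowSums(m > 0)
  info <- groups |>
    dplyr::mutate(.peak = peak_group, .breadth = unname(breadth_n)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      label = {
        if (all(.data$.breadth == 0)) {
          "no_expression"
        } else if (median(.data$.breadth) >= widespread_fraction * ncol(m)) {
          "widespread"
        } else {
          tab <- sort(table(.data$.peak[.data$.breadth > 0]), decreasing = TRUE)
          top <- names(tab)[tab == max(tab)]
          sort(top)[1]
        }
      },
      ambiguous = {
        if (all(.data$.breadth == 0) ||
            median(.data$.breadth) >= widespread_fraction * ncol(m)) {
          FALSE
        } else {
          tab <- table(.data$.peak[.data$.breadth > 0])
          sum(tab == max(tab)) > 1
        }
      },
      .groups = "drop"
    )
  dplyr::left_join(groups, info, by = "group")
}

#' Export a leaf-ordered heatmap matrix (and optional figure)
#'
#' Writes the normalised matrix with rows reordered to the dendrogram's
#' leaf order — the tabular form of a clustered expression heatmap — and,
#' if `image_path` is given, renders the heatmap (red high, blue low or
#' zero) with dimensions that scale with the matrix shape. Sample order is
#' kept as supplied; only genes are clustered.
#'
#' @param x Normalised expression tibble.
#' @param dend `gene_dendrogram` over the same genes.
#' @param matrix_path Output TSV path for the leaf-ordered matrix.
#' @param image_path Optional PNG/PDF path for the rendered heatmap.
#' @return The leaf-ordered tibble, invisibly.
#' @export
export_heatmap <- function(x, dend, matrix_path, image_path = NULL) {
  stopifnot(inherits(dend, "gene_dendrogram"))
  x <- check_expression(x)
  ord <- dend$gene_ids[dend$hclust$order]
  if (!setequal(ord, x$gene_id)) abort("`dend` and `x` cover different genes.")
  out <- x[match(ord, x$gene_id), ]
  readr::write_tsv(out, matrix_path, progress = FALSE)
  if (!is.null(image_path)) {
    p <- plot_expression_heatmap(out)
    n_s <- ncol(out) - 1
    n_g <- nrow(out)
    ggplot2::ggsave(
      image_path, p,
      width = max(4, 1.5 + 0.15 * n_s),
      height = max(3, 1 + 0.035 * n_g),
      dpi = 100, limitsize = FALSE
    )
  }
  invisible(out)
}
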