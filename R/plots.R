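# ggplot2 views of the main result types. Conventions follow the field's
# figures: red = high relative expression, blue = low/zero in heatmaps;
# per-class breadth as Tukey boxplots with one dot per gene.

#' Heatmap of an expression matrix
#'
#' Tile heatmap of a (normally max-normalised, leaf-ordered) expression
#' tibble, rows in the order given. Red marks high relative expression,
#' blue low or zero.
#'
#' @param x Expression tibble (`gene_id` + numeric sample columns).
#' @param dend Optional `gene_dendrogram`; if given, rows are reordered
#'   to its leaf order first.
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(x, dend = NULL) {
  x <- check_expression(x)
  if (!is.null(dend)) {
    x <- x[match(dend$gene_ids[dend$hclust$order], x$gene_id), ]
  }
  long <- tidyr::pivot_longer(x, -"gene_id",
                              names_to = "sample_id", values_to = "value")
  long$gene_id <- factor(long$gene_id, levels = rev(x$gene_id))
  long$sample_id <- factor(long$sample_id, levels = setdiff(names(x), "gene_id"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$gene_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#2166AC", high = "#B2182B",
                                 name = "relative\nexpression") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}

#' Per-class expression-breadth boxplot
#'
#' Tukey boxplots of expression breadth by homeobox class, one dot per
#' gene, ordered by class median so the specificity gradient across
#' classes reads left to right.
#'
#' @param b Breadth tibble from [expression_breadth()].
#' @param genes Gene annotation tibble.
#' @return A ggplot object.
#' @export
plot_class_breadth <- function(b, genes) {
  genes <- check_gene_annotation(genes)
  d <- dplyr::inner_join(as_tibble(b), genes[, c("gene_id", "hbx_class")],
                         by = "gene_id")
  ord <- d |>
    dplyr::group_by(.data$hbx_class) |>
    dplyr::summarise(m = median(.data$breadth), .groups = "drop") |>
    dplyr::arrange(.data$m)
  d$hbx_class <- factor(d$hbx_class, levels = ord$hbx_class)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hbx_class, y = .data$breadth)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$hbx_class),
                         width = 0.2, height = 0, size = 1, alpha = 0.7,
                         show.legend = FALSE) +
    ggplot2::labs(x = "homeobox class",
                  y = "samples with expression (breadth)") +
    ggplot2::theme_classic()
}

#' Stage-turnover profile with detected boundaries
#'
#' Line plot of Jaccard turnover across consecutive stage gaps, with
#' detected (or planted) phase boundaries as dashed verticals.
#'
#' @param turnover Tibble from [stage_turnover()].
#' @param boundaries Optional boundary positions (integer vector or the
#'   tibble from [detect_boundaries()]).
#' @return A ggplot object.
#' @export
plot_stage_turnover <- function(turnover, boundaries = NULL) {
  p <- ggplot2::ggplot(as_tibble(turnover),
                       ggplot2::aes(x = .data$position, y = .data$turnover)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "stage gap (position)", y = "Jaccard turnover") +
    ggplot2::theme_classic()
  if (!is.null(boundaries)) {
    pos <- if (is.data.frame(boundaries)) boundaries$position else boundaries
    p <- p + ggplot2::geom_vline(xintercept = pos, linetype = "dashed",
                                 colour = "#B2182B")
  }
  p
}

#' @rdname plot_class_breadth
#' @param object,... For the `autoplot` method: an `hbx_breadth` object,
#'   with `genes` passed through `...` as the first argument.
#' @method autoplot hbx_breadth
#' @export
autoplot.hbx_breadth <- function(object, ...) {
  plot_class_breadth(object, ...)
}

#' @rdname plot_stage_turnover
#' @param object,... For the `autoplot` method: an `hbx_turnover` object
#'   and optional `boundaries`.
#' @method autoplot hbx_turnover
#' @export
autoplot.hbx_turnover <- function(object, ...) {
  plot_stage_turnover(object, ...)
}
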