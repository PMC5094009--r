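# Reading, validating and writing the three tables the pipeline consumes:
# the expression matrix (genes x samples, FPKM-like), the gene annotation
# (gene -> homeobox class) and the sample annotation (sample -> category,
# group, optional temporal rank).

delim_for <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tsv = "\t", txt = "\t", csv = ",",
    abort(sprintf("Cannot infer delimiter from extension '.%s'; pass `delim`.", ext))
  )
}

#' Read an expression matrix
#'
#' Reads a genes-by-samples table of non-negative FPKM-like values. The
#' first column holds gene identifiers (renamed to `gene_id`), the header
#' row holds sample identifiers. The delimiter is inferred from the file
#' extension (`.tsv` tab, `.csv` comma) unless `delim` is given.
#'
#' Identifiers are treated case-sensitively and never normalised: human
#' symbols (`LEUTX`) and mouse symbols (`Cphx1`) differ only by case
#' convention. Missing cells are an error, not imputed as zero — silence
#' must be a measured low value, not absent data.
#'
#' @param path Path to a TSV/CSV file.
#' @param delim Optional single-character delimiter overriding inference.
#' @return A tibble with a `gene_id` column followed by one numeric column
#'   per sample, in file order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' readr::write_tsv(tibble::tibble(gene_id = c("A", "B"), liver = c(0, 5)), tf)
#' read_expression_matrix(tf)
read_expression_matrix <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_delim(
    path,
    delim = delim_for(path, delim),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(raw) < 2) abort("Expression file needs a gene id column and at least one sample column.")
  names(raw)[1] <- "gene_id"
  for (s in setdiff(names(raw), "gene_id")) {
    v <- raw[[s]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad) > 0) {
      abort(sprintf(
        "Non-numeric value '%s' at gene '%s', sample '%s'.",
        v[bad[1]], raw$gene_id[bad[1]], s
      ))
    }
    na <- which(is.na(num))
    if (length(na) > 0) {
      abort(sprintf(
        "Missing value at gene '%s', sample '%s'; missing cells are not imputed.",
        raw$gene_id[na[1]], s
      ))
    }
    raw[[s]] <- num
  }
  check_expression(raw, arg = "path")
}

#' Write an expression matrix
#'
#' Inverse of [read_expression_matrix()]: writes the wide tibble with the
#' delimiter implied by the output extension (or `delim`). Round-tripping
#' preserves values and row/column order.
#'
#' @param x Expression tibble (`gene_id` + numeric sample columns).
#' @param path Output path (`.tsv` or `.csv`).
#' @param delim Optional delimiter override.
#' @return `x`, invisibly.
#' @export
write_expression_matrix <- function(x, path, delim = NULL) {
  x <- check_expression(x)
  readr::write_delim(x, path, delim = delim_for(path, delim), progress = FALSE)
  invisible(x)
}

#' Read a gene annotation table
#'
#' Expects columns `gene_id` and `hbx_class` (one of the 11 classes in
#' [homeobox_classes]) and an optional `subclass` column (e.g. HOXL, NKL
#' within ANTP).
#'
#' @param path TSV/CSV path.
#' @param delim Optional delimiter override.
#' @return A tibble with columns `gene_id`, `hbx_class`, `subclass`.
#' @export
read_gene_annotation <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  x <- readr::read_delim(path, delim = delim_for(path, delim),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_gene_annotation(x)
}

check_gene_annotation <- function(x) {
  need <- c("gene_id", "hbx_class")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(sprintf("Gene annotation is missing column(s): %s", toString(missing)))
  }
  x <- as_tibble(x)
  dup <- x$gene_id[duplicated(x$gene_id)]
  if (length(dup) > 0) abort(sprintf("Duplicate gene id(s) in annotation: %s", toString(unique(dup))))
  bad <- setdiff(unique(x$hbx_class), homeobox_classes)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown homeobox class label(s): %s (must be one of %s).",
      toString(bad), toString(homeobox_classes)
    ))
  }
  if (!"subclass" %in% names(x)) x$subclass <- NA_character_
  x[, c("gene_id", "hbx_class", "subclass")]
}

#' Read a sample annotation table
#'
#' Expects columns `sample_id`, `category` (one of `adult_tissue`,
#' `developmental_stage`, `cell_type`), `group` (free label such as
#' `neural`, `immune`, `reproductive_dev`) and optionally `temporal_rank`
#' (non-negative integer; ranks must be unique among samples that carry
#' one, so ranked samples form a strict temporal order).
#'
#' @param path TSV/CSV path.
#' @param delim Optional delimiter override.
#' @return A tibble with columns `sample_id`, `category`, `group`,
#'   `temporal_rank`.
#' @export
read_sample_annotation <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  x <- readr::read_delim(path, delim = delim_for(path, delim),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_sample_annotation(x)
}

sample_categories <- c("adult_tissue", "developmental_stage", "cell_type")

check_sample_annotation <- function(x) {
  need <- c("sample_id", "category", "group")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(sprintf("Sample annotation is missing column(s): %s", toString(missing)))
  }
  x <- as_tibble(x)
  dup <- x$sample_id[duplicated(x$sample_id)]
  if (length(dup) > 0) abort(sprintf("Duplicate sample id(s) in annotation: %s", toString(unique(dup))))
  bad <- setdiff(unique(x$category), sample_categories)
  if (length(bad) > 0) {
    abort(sprintf("Unknown sample category label(s): %s (must be one of %s).",
                  toString(bad), toString(sample_categories)))
  }
  if (!"temporal_rank" %in% names(x)) x$temporal_rank <- NA_integer_
  tr <- suppressWarnings(as.integer(x$temporal_rank))
  if (any(!is.na(x$temporal_rank) & x$temporal_rank != "" & is.na(tr))) {
    abort("temporal_rank must be integer or empty.")
  }
  x$temporal_rank <- tr
  ranked <- tr[!is.na(tr)]
  if (any(ranked < 0)) abort("temporal_rank must be non-negative.")
  if (anyDuplicated(ranked)) {
    abort(sprintf("temporal_rank values must be unique (strict temporal order); duplicated: %s",
                  toString(unique(ranked[duplicated(ranked)]))))
  }
  x[, c("sample_id", "category", "group", "temporal_rank")]
}

#' Read gene and sample annotations together
#'
#' Convenience wrapper reading both annotation tables with the same
#' validation as [read_gene_annotation()] and [read_sample_annotation()].
#'
#' @param gene_path,sample_path TSV/CSV paths.
#' @param delim Optional delimiter override applied to both.
#' @return A list with elements `genes` and `samples`.
#' @export
read_annotations <- function(gene_path, sample_path, delim = NULL) {
  list(
    genes = read_gene_annotation(gene_path, delim = delim),
    samples = read_sample_annotation(sample_path, delim = delim)
  )
}

#' Align an expression matrix with its annotations
#'
#' Restricts the matrix, gene annotation and sample annotation to their
#' common gene and sample identifiers, preserving matrix order, and
#' reports anything dropped. Re-aligning an aligned dataset is a no-op.
#'
#' @param x Expression tibble.
#' @param genes Gene annotation tibble (see [read_gene_annotation()]).
#' @param samples Sample annotation tibble (see [read_sample_annotation()]).
#' @return An object of class `hbx_dataset`: a list with `expression`,
#'   `genes`, `samples` and a `dropped` list recording discarded ids.
#' @export
align_expression <- function(x, genes, samples) {
  x <- check_expression(x)
  genes <- check_gene_annotation(genes)
  samples <- check_sample_annotation(samples)
  keep_g <- intersect(x$gene_id, genes$gene_id)
  keep_s <- intersect(setdiff(names(x), "gene_id"), samples$sample_id)
  if (length(keep_g) == 0) abort("No genes shared between matrix and gene annotation.")
  if (length(keep_s) == 0) abort("No samples shared between matrix and sample annotation.")
  dropped <- list(
    matrix_genes = setdiff(x$gene_id, keep_g),
    annotation_genes = setdiff(genes$gene_id, keep_g),
    matrix_samples = setdiff(setdiff(names(x), "gene_id"), keep_s),
    annotation_samples = setdiff(samples$sample_id, keep_s)
  )
  n_drop <- sum(lengths(dropped))
  if (n_drop > 0) {
    warn(sprintf(
      "align_expression() dropped %d id(s): %s",
      n_drop, toString(unlist(dropped, use.names = FALSE))
    ))
  }
  out <- list(
    expression = x[match(keep_g, x$gene_id), c("gene_id", keep_s)],
    genes = genes[match(keep_g, genes$gene_id), ],
    samples = samples[match(keep_s, samples$sample_id), ],
    dropped = dropped
  )
  structure(out, class = "hbx_dataset")
}

#' @export
print.hbx_dataset <- function(x, ...) {
  cat(sprintf(
    "<hbx_dataset> %d genes x %d samples (%d id(s) dropped at alignment)\n",
    nrow(x$expression), nrow(x$samples), sum(lengths(x$dropped))
  ))
  cat("  classes:", toString(sort(unique(x$genes$hbx_class))), "\n")
  cat("  sample groups:", toString(sort(unique(x$samples$group))), "\n")
  invisible(x)
}
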