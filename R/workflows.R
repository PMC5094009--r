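# End-to-end workflows wiring the stages together: the tissue-panel
# chain (call -> normalise -> cluster -> label -> breadth/class summary ->
# exclusivity) and the staged-series chain (call -> normalise -> turnover
# -> boundaries -> temporal groups). Each run writes its tables, the
# exact config used (YAML), a stage-granular log with gene/sample counts
# (the filter audit trail) and a checksum manifest, so identical configs
# yield identical output bundles.

#' Build a workflow run configuration
#'
#' Collects every tunable of the two workflows into one serialisable
#' object. Input data may be given as file paths (`matrix`, `genes`,
#' `samples`) or as an in-memory `dataset` (an `hbx_dataset` or
#' `hbx_simulation`).
#'
#' @param matrix,genes,samples Input file paths (TSV/CSV), or `NULL` if
#'   `dataset` is supplied.
#' @param dataset Optional in-memory dataset overriding the paths.
#' @param out_dir Output directory.
#' @param threshold,cmp Expression-calling floor and boundary operator.
#' @param distance,linkage,k Clustering parameters (k = number of
#'   expression groups; 6 suits a human-style panel).
#' @param widespread_min_fraction Breadth fraction for the widespread
#'   rules.
#' @param target_group Sample-annotation group defining the exclusivity
#'   target set.
#' @param extra_targets Manual additions to the target set (e.g.
#'   `"ovary"`).
#' @param window Optional `c(rank_lo, rank_hi)` peak window.
#' @param n_boundaries Number of phase boundaries for the staged
#'   workflow.
#' @param seed Seed recorded with the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(matrix = NULL, genes = NULL, samples = NULL,
                       dataset = NULL, out_dir = tempfile("hbxprof_run_"),
                       threshold = 2, cmp = "ge",
                       distance = "correlation", linkage = "average", k = 6,
                       widespread_min_fraction = 0.9,
                       target_group = "reproductive_dev",
                       extra_targets = character(),
                       window = NULL, n_boundaries = 3, seed = 1) {
  cfg <- list(
    matrix = matrix, genes = genes, samples = samples,
    out_dir = out_dir, threshold = threshold, cmp = cmp,
    distance = distance, linkage = linkage, k = k,
    widespread_min_fraction = widespread_min_fraction,
    target_group = target_group, extra_targets = extra_targets,
    window = window, n_boundaries = n_boundaries, seed = seed
  )
  cfg$dataset <- dataset
  structure(cfg, class = "run_config")
}

config_yaml <- function(config) {
  ser <- config[setdiff(names(config), "dataset")]
  ser$dataset <- if (is.null(config$dataset)) NULL else "<in-memory>"
  yaml::as.yaml(ser)
}

load_config_dataset <- function(config, stage) {
  if (!is.null(config$dataset)) {
    d <- config$dataset
    return(list(expression = d$expression, genes = d$genes, samples = d$samples))
  }
  for (p in c("matrix", "genes", "samples")) {
    if (is.null(config[[p]])) {
      abort(sprintf("[%s] config is missing input '%s' and no dataset was supplied.",
                    stage, p))
    }
  }
  list(
    expression = read_expression_matrix(config$matrix),
    genes = read_gene_annotation(config$genes),
    samples = read_sample_annotation(config$samples)
  )
}

write_run_table <- function(x, dir, name) {
  x <- dplyr::mutate(as_tibble(x), dplyr::across(
    dplyr::where(is.list), ~ purrr::map_chr(.x, toString)
  ))
  readr::write_tsv(x, file.path(dir, name), progress = FALSE)
  name
}

finish_run <- function(dir, config, files, log_lines) {
  writeLines(config_yaml(config), file.path(dir, "config.yaml"))
  writeLines(log_lines, file.path(dir, "log.txt"))
  files <- c(files, "config.yaml", "log.txt")
  manifest <- tibble(
    file = setdiff(files, "log.txt"),
    md5 = unname(tools::md5sum(file.path(dir, setdiff(files, "log.txt"))))
  )
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"), progress = FALSE)
  manifest
}

#' Run the tissue-panel workflow
#'
#' Executes the full adult-tissue analysis chain: expression calling,
#' per-gene max-normalisation, profile clustering cut into `k` labelled
#' expression groups, breadth and per-class specificity summaries,
#' widespread-gene identification, per-sample expressed-gene counts, and
#' the exclusivity filter over the configured target group (with manual
#' additions and optional peak window). All tables are written as TSV
#' under `config$out_dir` along with the config, log and manifest.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with every intermediate and final table plus
#'   the manifest.
#' @export
run_tissue_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  say <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  dat <- load_config_dataset(config, "input")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say("input", "%d genes x %d samples", nrow(dat$expression),
      ncol(dat$expression) - 1)

  called <- call_expression(dat$expression, threshold = config$threshold,
                            cmp = config$cmp)
  say("call", "threshold %s (%s): %d genes with any expression",
      config$threshold, config$cmp, sum(rowSums(expr_matrix(called) > 0) > 0))
  norm <- normalize_to_max(called)

  dend <- cluster_genes(norm, distance = config$distance, linkage = config$linkage)
  groups <- cut_groups(dend, k = config$k)
  groups <- label_groups(groups, called, dat$samples,
                         widespread_fraction = config$widespread_min_fraction)
  say("cluster", "%d groups: %s", config$k,
      toString(sort(unique(groups$label))))

  b <- expression_breadth(called)
  csum <- class_breadth_summary(b, dat$genes)
  wide <- classify_widespread(b, min_fraction = config$widespread_min_fraction,
                              groups = groups)
  gps <- genes_per_sample(called)
  say("specificity", "%d widespread gene(s) via %s route", nrow(wide),
      unique(wide$route) %||% "breadth")

  targets <- dat$samples$sample_id[dat$samples$group == config$target_group]
  targets <- augment_target_set(targets, config$extra_targets,
                                dat$samples$sample_id)
  excl <- exclusive_to(called, targets, samples = dat$samples)
  say("exclusivity", "%d gene(s) exclusive to %d target sample(s)",
      nrow(excl), length(targets))
  window_tbl <- NULL
  if (!is.null(config$window)) {
    window_tbl <- peak_in_window(excl, dat$samples, config$window)
    say("exclusivity", "%d gene(s) peak within window [%s, %s]",
        nrow(window_tbl), config$window[1], config$window[2])
  }

  files <- c(
    write_run_table(called, config$out_dir, "called.tsv"),
    write_run_table(groups, config$out_dir, "groups.tsv"),
    write_run_table(b, config$out_dir, "breadth.tsv"),
    write_run_table(csum, config$out_dir, "class_summary.tsv"),
    write_run_table(wide, config$out_dir, "widespread.tsv"),
    write_run_table(gps, config$out_dir, "genes_per_sample.tsv"),
    write_run_table(excl, config$out_dir, "exclusive.tsv")
  )
  if (!is.null(window_tbl)) {
    files <- c(files, write_run_table(window_tbl, config$out_dir, "peak_window.tsv"))
  }
  ordered <- export_heatmap(norm, dend,
                            file.path(config$out_dir, "normalized_ordered.tsv"))
  files <- c(files, "normalized_ordered.tsv")
  manifest <- finish_run(config$out_dir, config, files, log_lines)
  invisible(list(
    called = called, normalized = norm, dendrogram = dend, groups = groups,
    breadth = b, class_summary = csum, widespread = wide,
    genes_per_sample = gps, exclusive = excl, peak_window = window_tbl,
    ordered = ordered, manifest = manifest, log = log_lines
  ))
}

#' Run the staged-series workflow
#'
#' Executes the developmental chain on a stage-ordered matrix: calling,
#' normalisation, expressed-set turnover between consecutive stages,
#' boundary detection (`n_boundaries` boundaries, i.e.
#' `n_boundaries + 1` phases) and temporal grouping with onset/offset
#' stages. Writes the turnover, boundary and group tables plus config,
#' log and manifest.
#'
#' @param config A [run_config()]; all samples must carry
#'   `temporal_rank` and there must be at least two stages.
#' @return Invisibly, a list of tables including `boundaries` (with
#'   `n_phases` attribute) and `temporal_groups`.
#' @export
run_staged_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  say <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  dat <- load_config_dataset(config, "input")
  n_stages <- ncol(dat$expression) - 1
  if (n_stages < 2) abort("[input] staged workflow needs at least 2 stages.")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say("input", "%d genes x %d stages", nrow(dat$expression), n_stages)

  called <- call_expression(dat$expression, threshold = config$threshold,
                            cmp = config$cmp)
  norm <- normalize_to_max(called)
  say("call", "%d genes expressed somewhere in the series",
      sum(rowSums(expr_matrix(called) > 0) > 0))

  turnover <- stage_turnover(called, dat$samples)
  bnd <- detect_boundaries(turnover, n_boundaries = config$n_boundaries)
  say("phases", "%d boundaries at position(s) %s -> %d phases",
      nrow(bnd), toString(bnd$position), attr(bnd, "n_phases"))
  tgroups <- assign_temporal_groups(norm, dat$samples, k = config$k,
                                    distance = config$distance,
                                    linkage = config$linkage)
  say("phases", "%d temporal group(s) + %d silent gene(s)",
      length(setdiff(unique(tgroups$group), "silent")),
      sum(tgroups$group == "silent"))

  files <- c(
    write_run_table(called, config$out_dir, "called.tsv"),
    write_run_table(turnover, config$out_dir, "turnover.tsv"),
    write_run_table(bnd, config$out_dir, "boundaries.tsv"),
    write_run_table(tgroups, config$out_dir, "temporal_groups.tsv")
  )
  manifest <- finish_run(config$out_dir, config, files, log_lines)
  invisible(list(
    called = called, normalized = norm, turnover = turnover,
    boundaries = bnd, n_phases = attr(bnd, "n_phases"),
    temporal_groups = tgroups, manifest = manifest, log = log_lines
  ))
}
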