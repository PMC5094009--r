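# Fixtures built in code, and independent brute-force oracles used to
# cross-check the vectorised implementations. The oracles deliberately
# use nothing from the package's own computation paths: plain nested
# loops over the wide tibble.

toy_matrix <- function() {
  tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    s1 = c(0, 2, 4),
    s2 = c(1, 3, 5)
  )
}

random_matrix <- function(seed, n_genes = 50, n_samples = 20, max_value = 10) {
  set.seed(seed)
  m <- matrix(round(runif(n_genes * n_samples, 0, max_value), 3),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                   tibble::as_tibble(m))
}

stage_annotation <- function(stages) {
  tibble::tibble(
    sample_id = stages,
    category = "developmental_stage",
    group = "embryo",
    temporal_rank = seq_along(stages) - 1L
  )
}

# --- brute-force oracles -------------------------------------------------

oracle_breadth <- function(called) {
  samp <- setdiff(names(called), "gene_id")
  out <- integer(nrow(called))
  for (i in seq_len(nrow(called))) {
    n <- 0L
    for (s in samp) if (called[[s]][i] > 0) n <- n + 1L
    out[i] <- n
  }
  tibble::tibble(gene_id = called$gene_id, breadth = out)
}

oracle_genes_per_sample <- function(called) {
  samp <- setdiff(names(called), "gene_id")
  out <- integer(length(samp))
  for (j in seq_along(samp)) {
    n <- 0L
    for (i in seq_len(nrow(called))) if (called[[samp[j]]][i] > 0) n <- n + 1L
    out[j] <- n
  }
  tibble::tibble(sample_id = samp, n_genes = out)
}

oracle_exclusive <- function(called, targets) {
  samp <- setdiff(names(called), "gene_id")
  other <- setdiff(samp, targets)
  keep <- character()
  for (i in seq_len(nrow(called))) {
    any_target <- FALSE
    any_other <- FALSE
    for (s in targets) if (called[[s]][i] > 0) any_target <- TRUE
    for (s in other) if (called[[s]][i] > 0) any_other <- TRUE
    if (any_target && !any_other) keep <- c(keep, called$gene_id[i])
  }
  keep
}

oracle_turnover <- function(called, stages) {
  out <- numeric(length(stages) - 1)
  for (i in seq_len(length(stages) - 1)) {
    a <- called$gene_id[called[[stages[i]]] > 0]
    b <- called$gene_id[called[[stages[i + 1]]] > 0]
    u <- union(a, b)
    out[i] <- if (length(u) == 0) 0 else 1 - length(intersect(a, b)) / length(u)
  }
  out
}

# Archetype counts for a staged series with an arbitrary number of phases.
default_counts_for <- function(n_phases) {
  counts <- stats::setNames(
    replicate(n_phases, c(ANTP = 20), simplify = FALSE),
    sprintf("phase_%d", seq_len(n_phases))
  )
  counts$silent <- c(PRD = 5)
  counts
}

# Drop the breadth table's class/attribute decoration for value comparison.
plain_breadth <- function(b) {
  attr(b, "n_samples") <- NULL
  class(b) <- class(tibble::tibble())
  tibble::as_tibble(b)
}
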