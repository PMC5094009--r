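# Internal helpers shared across modules, plus small exported utilities.

# Convert a wide expression tibble (gene_id + numeric sample columns) to a
# base matrix with gene ids as rownames. Validation happens here so every
# module gets the same invariants for free.
expr_matrix <- function(x, arg = "x") {
  x <- check_expression(x, arg = arg)
  m <- as.matrix(x[, setdiff(names(x), "gene_id"), drop = FALSE])
  rownames(m) <- x$gene_id
  m
}

# Inverse of expr_matrix().
expr_tibble <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(gene_id = rownames(m)), out)
}

# Validate a wide expression tibble: first column gene ids (renamed to
# gene_id if needed), unique ids, all remaining columns numeric, finite,
# non-negative, no missing cells. Errors carry coordinates so a bad value
# in a large table can be found.
check_expression <- function(x, arg = "x") {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame (gene_id + sample columns).", arg))
  }
  if (ncol(x) < 2) {
    abort(sprintf("`%s` must have a gene id column and at least one sample column.", arg))
  }
  x <- as_tibble(x)
  names(x)[1] <- "gene_id"
  x$gene_id <- as.character(x$gene_id)
  dup <- x$gene_id[duplicated(x$gene_id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate gene id(s): %s", toString(unique(dup))))
  }
  samp <- setdiff(names(x), "gene_id")
  dup_s <- samp[duplicated(samp)]
  if (length(dup_s) > 0) {
    abort(sprintf("Duplicate sample id(s): %s", toString(unique(dup_s))))
  }
  for (s in samp) {
    v <- x[[s]]
    if (!is.numeric(v)) {
      abort(sprintf("Sample column '%s' is not numeric.", s))
    }
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad) > 0) {
      abort(sprintf(
        "Invalid expression value %s at gene '%s', sample '%s' (values must be finite and >= 0).",
        format(v[bad[1]]), x$gene_id[bad[1]], s
      ))
    }
  }
  x
}

check_samples_present <- function(ids, have, what = "sample") {
  missing <- setdiff(ids, have)
  if (length(missing) > 0) {
    abort(sprintf("Unknown %s id(s): %s", what, toString(missing)))
  }
  invisible(ids)
}

# Jaccard distance between two character sets; 0 when both are empty.
jaccard_distance <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  1 - length(intersect(a, b)) / u
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same items.
#' Used throughout the package to score recovery of planted archetypes by
#' clustering; 1 means identical partitions up to relabelling, 0 is the
#' expected value for independent random partitions.
#'
#' @param a,b Vectors of cluster labels of equal length (any atomic type).
#' @return A single number in \[-1, 1\].
#' @export
#' @examples
#' ari(c(1, 1, 2, 2), c("x", "x", "y", "y")) # 1
ari <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have the same length.")
  n <- length(a)
  if (n == 0) return(NaN)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# Run code with a temporary RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards so simulation helpers do not perturb
# user scripts.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}
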