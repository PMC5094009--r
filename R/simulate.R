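# Seeded synthetic data with planted truth. Two presets mirror the scale
# of the study designs the package targets: a 242-gene x 59-sample human
# style tissue panel (adult tissues, immune cell types, reproductive
# tissues and seven preimplantation stages) and a 278-gene x 12-stage
# mouse-style developmental series with four planted phases.
#
# Value model: an expressed entry is exp(meanlog + u_s + g + eps) where
# u_s is a per-sample profile shared by all genes of an archetype
# (sd profile_sd), g a per-gene offset (sd gene_sd) and eps residual
# noise (sd resid_sd); the three standard deviations default to 0.6 /
# 0.6 / 0.5 so total log-scale spread is ~1 around meanlog = 3. The
# shared profile makes same-archetype genes positively correlated, as
# co-regulated genes are. Draws are clipped from below at the calling
# threshold so a planted expressed entry is always called expressed.
# Background (unexpressed) entries are uniform on [0, background_max]
# with background_max strictly below the threshold.

default_panel_counts <- function() {
  list(
    widespread = c(TALE = 6, ZF = 8, CERS = 3, PRD = 1, SINE = 1, CUT = 1),
    neural = c(ANTP = 30, PRD = 15, LIM = 8, POU = 4, SINE = 3),
    immune = c(ANTP = 10, PRD = 8, POU = 6, CUT = 4, ZF = 4, HNF = 3),
    organ = c(ANTP = 40, PRD = 12, LIM = 8, HNF = 4, SINE = 3, PROS = 2, CUT = 1),
    exclusive_peak = c(PRD = 14, ANTP = 5, POU = 2, CERS = 1, ZF = 1),
    silent = c(ANTP = 16, PRD = 5, LIM = 5, SINE = 3, CUT = 2, PROS = 2, ZF = 1)
  )
}

preimplantation_stages <- c("oocyte", "zygote", "2cell", "4cell",
                            "8cell", "morula", "blastocyst")

default_panel_samples <- function() {
  neural <- c("cerebral_cortex", "hippocampus", "amygdala", "cerebellum",
              "corpus_callosum", "parietal_lobe", "substantia_nigra",
              "fetal_brain", "retina", "optic_nerve", "spinal_cord",
              "frontal_lobe")
  immune_cells <- c("b_cells", "t_cells", "monocytes", "neutrophils")
  immune_tissue <- c("bone_marrow", "spleen", "thymus", "lymph_node")
  organ <- c("liver", "kidney", "heart", "lung", "pancreas", "stomach",
             "colon", "duodenum", "ileum", "gall_bladder", "bladder",
             "prostate", "skin", "adipose", "skeletal_muscle",
             "smooth_muscle", "esophagus", "thyroid", "adrenal_gland",
             "pituitary", "salivary_gland", "tongue", "trachea", "aorta",
             "coronary_artery", "bone", "cartilage", "cornea",
             "mammary_gland")
  tibble(
    sample_id = c(preimplantation_stages, "testis", "placenta", "ovary",
                  neural, immune_cells, immune_tissue, organ),
    category = c(rep("developmental_stage", 7), rep("adult_tissue", 3),
                 rep("adult_tissue", length(neural)),
                 rep("cell_type", length(immune_cells)),
                 rep("adult_tissue", length(immune_tissue)),
                 rep("adult_tissue", length(organ))),
    group = c(rep("reproductive_dev", 10), rep("neural", length(neural)),
              rep("immune", length(immune_cells) + length(immune_tissue)),
              rep("organ", length(organ))),
    temporal_rank = c(0:6, rep(NA_integer_, 3 + length(neural) + 8 + length(organ)))
  )
}

# Planted peak stages for the exclusive_peak archetype, recycled over its
# genes: 13 of the default 23 peak in the 8-cell..morula window, six at
# other preimplantation stages, four in adult reproductive tissues.
default_peak_samples <- function(n) {
  base <- c(rep(c("8cell", "morula"), length.out = 13),
            "oocyte", "oocyte", "zygote", "zygote", "blastocyst", "blastocyst",
            "testis", "placenta", "ovary", "testis")
  rep(base, length.out = n)
}

draw_expressed <- function(n_genes, support, n_samples, meanlog, profile_sd,
                           gene_sd, resid_sd, threshold) {
  u <- rnorm(length(support), 0, profile_sd)
  g <- rnorm(n_genes, 0, gene_sd)
  eps <- matrix(rnorm(n_genes * length(support), 0, resid_sd),
                nrow = n_genes)
  pmax(exp(meanlog + outer(g, u, "+") + eps), threshold)
}

#' Simulate a human-style tissue expression panel
#'
#' Generates an FPKM-like matrix with planted gene archetypes over a
#' fixed 59-sample design (seven preimplantation stages; testis, placenta
#' and ovary; 12 neural, 8 immune and 29 other adult samples):
#'
#' * `widespread` — expressed in every sample;
#' * `neural`, `immune`, `organ` — expressed in exactly that sample
#'   group (module-specific);
#' * `exclusive_peak` — expressed only in the `reproductive_dev` group,
#'   with a planted peak stage boosted to the row maximum;
#' * `silent` — background everywhere.
#'
#' Defaults plant 20 widespread, 60 neural, 35 immune, 70 organ, 23
#' exclusive and 34 silent genes (242 total), with homeobox classes
#' skewed so ANTP/PRD fall mostly in tissue-specific archetypes and
#' TALE/ZF/CERS in the widespread one. Generation is a deterministic
#' function of the seed; the caller's RNG state is untouched.
#'
#' @param seed Integer seed.
#' @param counts Named list archetype -> named integer vector of gene
#'   counts per homeobox class (default [default_panel_counts()] shape).
#' @param meanlog,profile_sd,gene_sd,resid_sd Log-scale location and
#'   spread components of expressed values.
#' @param background_max Upper bound of the sub-threshold background
#'   (must be below `threshold`).
#' @param threshold Calling threshold the generator guarantees planted
#'   expression clears.
#' @return A list of class `hbx_simulation`: `expression`, `genes`,
#'   `samples`, `truth` (gene_id, archetype, peak_sample).
#' @export
#' @examples
#' sim <- simulate_tissue_panel(seed = 1)
#' dim(sim$expression)
simulate_tissue_panel <- function(seed,
                                  counts = default_panel_counts(),
                                  meanlog = 3, profile_sd = 0.6,
                                  gene_sd = 0.6, resid_sd = 0.5,
                                  background_max = 1.5, threshold = 2) {
  if (background_max >= threshold) {
    abort("`background_max` must be strictly below `threshold`.")
  }
  known <- c("widespread", "neural", "immune", "organ", "exclusive_peak", "silent")
  bad <- setdiff(names(counts), known)
  if (length(bad) > 0) abort(sprintf("Unknown archetype(s): %s", toString(bad)))
  bad_cls <- setdiff(unlist(lapply(counts, names)), homeobox_classes)
  if (length(bad_cls) > 0) abort(sprintf("Unknown class(es) in counts: %s", toString(bad_cls)))
  samples <- default_panel_samples()
  n_samples <- nrow(samples)
  with_seed(seed, {
    gene_rows <- purrr::imap(counts, function(cls_counts, arch) {
      tibble(archetype = arch,
             hbx_class = rep(names(cls_counts), times = cls_counts))
    })
    genes <- dplyr::bind_rows(gene_rows)
    n_genes <- nrow(genes)
    if (n_genes == 0) {
      m <- matrix(numeric(0), nrow = 0, ncol = n_samples,
                  dimnames = list(character(), samples$sample_id))
      empty <- structure(list(
        expression = expr_tibble(m),
        genes = tibble(gene_id = character(), hbx_class = character(),
                       subclass = character()),
        samples = samples,
        truth = tibble(gene_id = character(), archetype = character(),
                       peak_sample = character())
      ), class = "hbx_simulation")
      return(empty)
    }
    genes$gene_id <- sprintf("%s_%03d", genes$hbx_class,
                             stats::ave(seq_len(n_genes), genes$hbx_class,
                                        FUN = seq_along))
    m <- matrix(runif(n_genes * n_samples, 0, background_max),
                nrow = n_genes,
                dimnames = list(genes$gene_id, samples$sample_id))
    support_of <- list(
      widespread = samples$sample_id,
      neural = samples$sample_id[samples$group == "neural"],
      immune = samples$sample_id[samples$group == "immune"],
      organ = samples$sample_id[samples$group == "organ"],
      exclusive_peak = samples$sample_id[samples$group == "reproductive_dev"],
      silent = character()
    )
    truth <- tibble(gene_id = genes$gene_id, archetype = genes$archetype,
                    peak_sample = NA_character_)
    for (arch in unique(genes$archetype)) {
      idx <- which(genes$archetype == arch)
      support <- support_of[[arch]]
      if (length(support) == 0 || length(idx) == 0) next
      m[idx, support] <- draw_expressed(length(idx), support, n_samples,
                                        meanlog, profile_sd, gene_sd,
                                        resid_sd, threshold)
      if (arch == "exclusive_peak") {
        peaks <- default_peak_samples(length(idx))
        for (j in seq_along(idx)) {
          m[idx[j], peaks[j]] <- 1.5 * max(m[idx[j], support])
        }
        truth$peak_sample[idx] <- peaks
      }
    }
    structure(list(
      expression = expr_tibble(m),
      genes = tibble(gene_id = genes$gene_id, hbx_class = genes$hbx_class,
                     subclass = NA_character_),
      samples = samples,
      truth = truth
    ), class = "hbx_simulation")
  })
}

canonical_mouse_stages <- c("oocyte", "zygote", "2cell", "4cell", "8cell",
                            "morula", "blastocyst", "e7.5", "e8.5", "e9.5",
                            "e10.5", "e11.5")

default_series_counts <- function() {
  list(
    maternal = c(PRD = 25, ANTP = 10, LIM = 5, POU = 5, ZF = 5),
    ega_burst = c(PRD = 30, ANTP = 5, TALE = 5),
    cleavage_blastocyst = c(ANTP = 20, PRD = 10, POU = 10, SINE = 5,
                            TALE = 5, ZF = 10),
    postimplantation = c(ANTP = 60, PRD = 10, LIM = 10, HNF = 5, CUT = 5,
                         PROS = 3, SINE = 4, CERS = 3),
    silent = c(ANTP = 14, PRD = 7, LIM = 4, ZF = 3)
  )
}

#' Simulate a staged developmental expression series
#'
#' Generates a stage-ordered matrix in which each temporal archetype is
#' expressed only within its phase, phases being the intervals delimited
#' by the planted boundary positions (a boundary at position p falls
#' between the stages of rank p-1 and p). The default plants the
#' four-phase design — maternal (oocyte–zygote), an EGA burst confined to
#' the 2-cell stage, cleavage-to-blastocyst, and postimplantation — over
#' 12 canonical mouse stages with boundaries (2, 3, 7) and 278 genes.
#'
#' The number of non-silent archetype entries in `counts` must equal
#' `length(boundaries) + 1`; archetypes are assigned to phases in list
#' order.
#'
#' @param seed Integer seed.
#' @param n_stages Number of stages (12 uses canonical stage names).
#' @param boundaries Strictly increasing planted boundary positions in
#'   1..n_stages-1.
#' @param counts Named list archetype -> named class-count vector; the
#'   optional `silent` entry is background-only.
#' @inheritParams simulate_tissue_panel
#' @return A list of class `hbx_simulation`: `expression`, `genes`,
#'   `samples`, `truth` (gene_id, archetype, onset, offset) with
#'   attribute `boundaries`.
#' @export
simulate_staged_series <- function(seed,
                                   n_stages = 12,
                                   boundaries = c(2, 3, 7),
                                   counts = default_series_counts(),
                                   meanlog = 3, profile_sd = 0.6,
                                   gene_sd = 0.6, resid_sd = 0.5,
                                   background_max = 1.5, threshold = 2) {
  boundaries <- as.integer(boundaries)
  if (length(boundaries) == 0 || is.unsorted(boundaries, strictly = TRUE) ||
      any(boundaries < 1) || any(boundaries > n_stages - 1)) {
    abort("`boundaries` must be strictly increasing within 1..n_stages-1.")
  }
  if (background_max >= threshold) {
    abort("`background_max` must be strictly below `threshold`.")
  }
  phase_arch <- setdiff(names(counts), "silent")
  n_phases <- length(boundaries) + 1
  if (length(phase_arch) != n_phases) {
    abort(sprintf("`counts` must name %d non-silent archetypes for %d boundaries.",
                  n_phases, length(boundaries)))
  }
  stages <- if (n_stages == 12) canonical_mouse_stages else sprintf("stage_%02d", seq_len(n_stages))
  samples <- tibble(sample_id = stages, category = "developmental_stage",
                    group = "embryo", temporal_rank = seq_len(n_stages) - 1L)
  phase_id <- phase_of_stages(boundaries, n_stages)
  with_seed(seed, {
    genes <- dplyr::bind_rows(purrr::imap(counts, function(cc, arch) {
      tibble(archetype = arch, hbx_class = rep(names(cc), times = cc))
    }))
    n_genes <- nrow(genes)
    genes$gene_id <- sprintf("m%s_%03d", genes$hbx_class,
                             stats::ave(seq_len(n_genes), genes$hbx_class,
                                        FUN = seq_along))
    m <- matrix(runif(n_genes * n_stages, 0, background_max),
                nrow = n_genes, dimnames = list(genes$gene_id, stages))
    truth <- tibble(gene_id = genes$gene_id, archetype = genes$archetype,
                    onset = NA_integer_, offset = NA_integer_)
    for (p in seq_len(n_phases)) {
      arch <- phase_arch[p]
      idx <- which(genes$archetype == arch)
      support <- stages[phase_id == p]
      if (length(idx) == 0) next
      m[idx, support] <- draw_expressed(length(idx), support, n_stages,
                                        meanlog, profile_sd, gene_sd,
                                        resid_sd, threshold)
      truth$onset[idx] <- min(which(phase_id == p)) - 1L
      truth$offset[idx] <- max(which(phase_id == p)) - 1L
    }
    out <- structure(list(
      expression = expr_tibble(m),
      genes = tibble(gene_id = genes$gene_id, hbx_class = genes$hbx_class,
                     subclass = NA_character_),
      samples = samples,
      truth = truth
    ), class = "hbx_simulation")
    attr(out, "boundaries") <- boundaries
    out
  })
}

#' Corrupt an expression matrix with dropout and multiplicative noise
#'
#' Degrades the planted signal to stress downstream recovery. Both
#' corruptions act on the expressed entries (values at or above
#' `threshold`): each is zeroed with probability `dropout_rate`, and the
#' survivors are multiplied by log-normal noise `exp(N(0, noise_scale))`
#' (which can push a value below the calling threshold — that is the
#' point). Sub-threshold background is left untouched: it is already the
#' generator's noise-floor model.
#'
#' @param x Expression tibble.
#' @param dropout_rate Probability in \[0, 1\] of zeroing an expressed
#'   entry.
#' @param noise_scale Log-scale sd of multiplicative noise (0 = none).
#' @param seed Optional integer seed.
#' @param threshold Expression floor defining which entries count as
#'   expressed (default 2).
#' @return A corrupted expression tibble of the same shape.
#' @export
corrupt_expression <- function(x, dropout_rate = 0, noise_scale = 0,
                               seed = NULL, threshold = 2) {
  if (dropout_rate < 0 || dropout_rate > 1) abort("`dropout_rate` must be in [0, 1].")
  if (noise_scale < 0) abort("`noise_scale` must be >= 0.")
  m <- expr_matrix(x)
  with_seed(seed, {
    expressed <- which(m >= threshold)
    if (length(expressed) > 0) {
      if (noise_scale > 0) {
        m[expressed] <- m[expressed] * rlnorm(length(expressed), 0, noise_scale)
      }
      if (dropout_rate > 0) {
        drop <- expressed[runif(length(expressed)) < dropout_rate]
        m[drop] <- 0
      }
    }
    expr_tibble(m)
  })
}

#' @export
print.hbx_simulation <- function(x, ...) {
  cat(sprintf("<hbx_simulation> %d genes x %d samples\n",
              nrow(x$expression), nrow(x$samples)))
  print(table(x$truth$archetype))
  invisible(x)
}

#' Write a simulated dataset to a directory
#'
#' Emits `matrix.tsv`, `genes.tsv`, `samples.tsv` and `truth.tsv` so a
#' simulated panel can be consumed through the same file interface as
#' real data.
#'
#' @param sim An `hbx_simulation`.
#' @param dir Output directory (created if needed).
#' @return The paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "hbx_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.tsv", "genes.tsv", "samples.tsv", "truth.tsv"))
  write_expression_matrix(sim$expression, paths[1])
  readr::write_tsv(sim$genes, paths[2], progress = FALSE)
  readr::write_tsv(sim$samples, paths[3], progress = FALSE)
  readr::write_tsv(sim$truth, paths[4], progress = FALSE)
  invisible(paths)
}
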