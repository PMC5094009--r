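test_that("generation is a deterministic function of the seed", {
  a <- simulate_tissue_panel(seed = 7)
  b <- simulate_tissue_panel(seed = 7)
  expect_equal(a$expression, b$expression)
  expect_equal(a$truth, b$truth)
  c <- simulate_tissue_panel(seed = 8)
  expect_false(isTRUE(all.equal(a$expression, c$expression)))
  # caller's RNG stream is not perturbed
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(simulate_tissue_panel(seed = 7)); x2 <- runif(1)
  expect_equal(x1, x2)
})

test_that("the default panel mirrors the study scale with planted structure", {
  sim <- simulate_tissue_panel(seed = 1)
  expect_equal(nrow(sim$expression), 242)
  expect_equal(ncol(sim$expression) - 1, 59)
  expect_equal(nrow(sim$samples), 59)
  expect_true(all(sim$genes$hbx_class %in% homeobox_classes))
  expect_equal(sum(sim$truth$archetype == "widespread"), 20)
  expect_equal(sum(sim$truth$archetype == "exclusive_peak"), 23)

  called <- call_expression(sim$expression)
  b <- expression_breadth(called)
  wide_truth <- sim$truth$gene_id[sim$truth$archetype == "widespread"]
  expect_true(all(b$breadth[b$gene_id %in% wide_truth] == 59))
  silent_truth <- sim$truth$gene_id[sim$truth$archetype == "silent"]
  expect_true(all(b$breadth[b$gene_id %in% silent_truth] == 0))

  # exclusive genes peak at their planted stage
  targets <- sim$samples$sample_id[sim$samples$group == "reproductive_dev"]
  ex <- exclusive_to(called, targets)
  planted <- sim$truth[sim$truth$archetype == "exclusive_peak", ]
  expect_equal(sort(ex$gene_id), sort(planted$gene_id))
  expect_equal(ex$peak_sample,
               planted$peak_sample[match(ex$gene_id, planted$gene_id)])
})

test_that("an empty archetype spec yields an empty matrix over the full sample design", {
  sim <- simulate_tissue_panel(seed = 1, counts = list())
  expect_equal(nrow(sim$expression), 0)
  expect_equal(nrow(sim$samples), 59)
  expect_error(simulate_tissue_panel(seed = 1, counts = list(nonsense = c(ANTP = 2))),
               "Unknown archetype")
  expect_error(simulate_tissue_panel(seed = 1, background_max = 2.5),
               "strictly below")
})

test_that("the staged series confines each archetype to its phase", {
  sim <- simulate_staged_series(seed = 4)
  expect_equal(nrow(sim$expression), 278)
  expect_equal(nrow(sim$samples), 12)
  expect_equal(attr(sim, "boundaries"), c(2L, 3L, 7L))
  called <- call_expression(sim$expression)
  m <- as.matrix(called[, -1])
  rownames(m) <- called$gene_id
  ranks <- sim$samples$temporal_rank

  maternal <- sim$truth$gene_id[sim$truth$archetype == "maternal"]
  expect_true(all(m[maternal, ranks > 1] == 0))
  expect_true(all(rowSums(m[maternal, ranks <= 1] > 0) > 0))

  burst <- sim$truth$gene_id[sim$truth$archetype == "ega_burst"]
  expect_true(all(m[burst, ranks != 2] == 0))
  # one-stage archetype: onset equals offset
  tg <- assign_temporal_groups(normalize_to_max(called), sim$samples, k = 4)
  expect_true(all(tg$onset[tg$gene_id %in% burst] == 2))
  expect_true(all(tg$offset[tg$gene_id %in% burst] == 2))
})

test_that("malformed staged specs error", {
  expect_error(simulate_staged_series(seed = 1, boundaries = c(3, 2)),
               "strictly increasing")
  expect_error(simulate_staged_series(seed = 1, boundaries = c(0, 5)),
               "strictly increasing")
  expect_error(simulate_staged_series(seed = 1, boundaries = c(2, 5)),
               "non-silent archetypes")
})

test_that("corrupt_expression: identity at zero, total dropout silences, dropout is binomial", {
  sim <- simulate_tissue_panel(seed = 9)
  expect_equal(corrupt_expression(sim$expression, 0, 0, seed = 1), sim$expression)

  dead <- corrupt_expression(sim$expression, dropout_rate = 1, seed = 1)
  called <- call_expression(dead)
  expect_true(all(as.matrix(called[, -1]) == 0))

  # dropout count ~ Binomial(n_expressed, rate) across seeds
  m <- as.matrix(sim$expression[, -1])
  n_expressed <- sum(m >= 2)
  rate <- 0.05
  dropped <- vapply(1:200, function(s) {
    cm <- as.matrix(corrupt_expression(sim$expression, dropout_rate = rate,
                                       seed = s)[, -1])
    sum(m >= 2 & cm == 0)
  }, numeric(1))
  expected <- n_expressed * rate
  sd_bin <- sqrt(n_expressed * rate * (1 - rate))
  expect_lt(abs(mean(dropped) - expected), 3 * sd_bin / sqrt(200))
  # background is never touched
  cm <- as.matrix(corrupt_expression(sim$expression, 0.5, 0.5, seed = 3)[, -1])
  expect_equal(cm[m < 2], m[m < 2])
})

test_that("write_simulation emits the four-file TSV interface that reads back", {
  dir <- withr::local_tempdir()
  sim <- simulate_tissue_panel(seed = 2)
  write_simulation(sim, dir)
  expect_equal(read_expression_matrix(file.path(dir, "matrix.tsv")),
               sim$expression, tolerance = 1e-12)
  ann <- read_annotations(file.path(dir, "genes.tsv"), file.path(dir, "samples.tsv"))
  expect_equal(ann$genes$gene_id, sim$genes$gene_id)
  expect_equal(ann$samples, sim$samples)
})
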