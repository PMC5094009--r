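two_block_matrix <- function(n_a = 6, n_b = 6, n_samples = 10) {
  half <- n_samples / 2
  prof_a <- c(rep(1, half), rep(0, half))
  m <- rbind(
    matrix(rep(prof_a, n_a), nrow = n_a, byrow = TRUE),
    matrix(rep(1 - prof_a, n_b), nrow = n_b, byrow = TRUE)
  )
  dimnames(m) <- list(sprintf("g%02d", seq_len(n_a + n_b)),
                      sprintf("s%02d", seq_len(n_samples)))
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)), tibble::as_tibble(m))
}

test_that("identical profiles merge first at height zero", {
  m <- tibble::tibble(gene_id = c("a", "b", "c"),
                      s1 = c(1, 1, 0), s2 = c(0, 0, 1))
  dend <- cluster_genes(m, distance = "euclidean")
  expect_equal(sort(dend$hclust$merge[1, ]), c(-2, -1)) # genes 1 and 2
  expect_equal(dend$hclust$height[1], 0)
  # heights non-decreasing (average linkage is monotone)
  expect_true(!is.unsorted(dend$hclust$height))
})

test_that("a planted two-block matrix is recovered exactly at k = 2", {
  m <- two_block_matrix()
  for (dist in c("correlation", "euclidean")) {
    groups <- cut_groups(cluster_genes(m, distance = dist), k = 2)
    truth <- rep(1:2, each = 6)
    expect_equal(ari(groups$group, truth), 1)
  }
})

test_that("cut extremes give singletons and one whole-set group; cuts nest", {
  m <- random_matrix(7, n_genes = 12, n_samples = 6)
  dend <- cluster_genes(normalize_to_max(call_expression(m)))
  expect_equal(dplyr::n_distinct(cut_groups(dend, k = 12)$group), 12)
  expect_equal(unique(cut_groups(dend, k = 1)$group), 1L)
  expect_error(cut_groups(dend, k = 0), "must be in")
  expect_error(cut_groups(dend, k = 13), "must be in")
  expect_error(cut_groups(dend, k = 3, h = 1), "exactly one")
  # nested refinement: every k+1 group lies inside one k group
  for (k in 2:6) {
    a <- cut_groups(dend, k = k)$group
    b <- cut_groups(dend, k = k + 1)$group
    expect_true(all(tapply(a, b, dplyr::n_distinct) == 1))
  }
})

test_that("clustering is invariant under row permutation (ARI = 1)", {
  m <- normalize_to_max(call_expression(random_matrix(21, n_genes = 30, n_samples = 12)))
  set.seed(1)
  perm <- sample(nrow(m))
  g1 <- cut_groups(cluster_genes(m), k = 4)
  g2 <- cut_groups(cluster_genes(m[perm, ]), k = 4)
  joined <- dplyr::inner_join(g1, g2, by = "gene_id")
  expect_equal(ari(joined$group.x, joined$group.y), 1)
})

test_that("correlation distance errors on an all-constant matrix and isolates silent rows", {
  allzero <- tibble::tibble(gene_id = c("a", "b"), s1 = c(0, 0), s2 = c(0, 0))
  expect_error(cluster_genes(allzero), "euclidean")

  mixed <- two_block_matrix(4, 4)
  mixed <- dplyr::bind_rows(mixed, tibble::tibble(
    gene_id = c("z1", "z2"),
    !!!setNames(as.list(rep(0, 10)), setdiff(names(mixed), "gene_id"))
  ))
  groups <- cut_groups(cluster_genes(mixed), k = 3)
  truth <- c(rep(1, 4), rep(2, 4), rep(3, 2))
  expect_equal(ari(groups$group, truth), 1)
})

test_that("ari agrees with the mclust implementation on random partitions", {
  skip_if_not_installed("mclust")
  set.seed(42)
  for (i in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(ari(1:5, c(2, 2, 4, 4, 1)), mclust::adjustedRandIndex(1:5, c(2, 2, 4, 4, 1)))
})

test_that("group labelling follows peak sites, breadth and the tie rule", {
  samples <- tibble::tibble(
    sample_id = c("ctx", "hip", "blood", "liver"),
    category = "adult_tissue",
    group = c("neural", "neural", "immune", "organ"),
    temporal_rank = NA_integer_
  )
  called <- tibble::tibble(
    gene_id = c("n1", "n2", "w1", "z1", "t1"),
    ctx = c(5, 8, 4, 0, 6),
    hip = c(3, 0, 5, 0, 0),
    blood = c(0, 0, 3, 0, 6),
    liver = c(0, 0, 6, 0, 0)
  )
  groups <- tibble::tibble(gene_id = called$gene_id,
                           group = c(1L, 1L, 2L, 3L, 4L))
  lab <- label_groups(groups, called, samples)
  expect_equal(lab$label[lab$gene_id == "n1"], "neural")
  expect_equal(lab$label[lab$gene_id == "w1"], "widespread") # breadth 4/4
  expect_equal(lab$label[lab$gene_id == "z1"], "no_expression")
  # t1 peaks tie ctx/blood -> earliest column is ctx (neural), single member
  expect_equal(lab$label[lab$gene_id == "t1"], "neural")
  expect_false(any(lab$ambiguous[lab$label %in% c("widespread", "no_expression")]))
})

test_that("label ties between dominant sample groups are lexicographic and flagged", {
  samples <- tibble::tibble(
    sample_id = c("ctx", "blood"), category = "adult_tissue",
    group = c("neural", "immune"), temporal_rank = NA_integer_
  )
  called <- tibble::tibble(gene_id = c("a", "b"),
                           ctx = c(9, 0), blood = c(0, 9))
  groups <- tibble::tibble(gene_id = c("a", "b"), group = c(1L, 1L))
  lab <- label_groups(groups, called, samples)
  expect_equal(unique(lab$label), "immune") # lexicographically first
  expect_true(all(lab$ambiguous))
})

test_that("export_heatmap writes the leaf-ordered matrix deterministically", {
  m <- normalize_to_max(call_expression(random_matrix(13, n_genes = 15, n_samples = 6)))
  dend <- cluster_genes(m)
  tf1 <- withr::local_tempfile(fileext = ".tsv")
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  out <- export_heatmap(m, dend, tf1)
  export_heatmap(m, dend, tf2)
  expect_equal(out$gene_id, dend$gene_ids[dend$hclust$order])
  expect_identical(readLines(tf1), readLines(tf2)) # byte-identical re-export
})

test_that("heatmap image dimensions scale with matrix shape", {
  skip_if_not_installed("png")
  small <- normalize_to_max(random_matrix(1, n_genes = 10, n_samples = 5))
  big <- normalize_to_max(random_matrix(1, n_genes = 200, n_samples = 40))
  f_small <- withr::local_tempfile(fileext = ".png")
  f_big <- withr::local_tempfile(fileext = ".png")
  export_heatmap(small, cluster_genes(small), withr::local_tempfile(fileext = ".tsv"),
                 image_path = f_small)
  export_heatmap(big, cluster_genes(big), withr::local_tempfile(fileext = ".tsv"),
                 image_path = f_big)
  d_small <- dim(png::readPNG(f_small))
  d_big <- dim(png::readPNG(f_big))
  expect_gt(d_big[1], d_small[1])
  expect_gt(d_big[2], d_small[2])
})
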