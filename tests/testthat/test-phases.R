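phase_toy <- function() {
  # 4 stages; expressed sets: {A,B,C}, {B,C,D}, {B,C,D}, {E}
  m <- tibble::tibble(
    gene_id = c("A", "B", "C", "D", "E"),
    st0 = c(5, 4, 3, 0, 0),
    st1 = c(0, 4, 3, 6, 0),
    st2 = c(0, 2, 2, 6, 0),
    st3 = c(0, 0, 0, 0, 9)
  )
  list(m = m, samples = stage_annotation(c("st0", "st1", "st2", "st3")))
}

test_that("turnover is the Jaccard distance between consecutive expressed sets", {
  toy <- phase_toy()
  tv <- stage_turnover(toy$m, toy$samples)
  expect_equal(tv$position, 1:3)
  expect_equal(tv$turnover, c(0.5, 0, 1)) # {A,B,C} vs {B,C,D} = 1 - 2/4
  expect_equal(tv$from_stage, c("st0", "st1", "st2"))
  # agreement with the loop oracle
  expect_equal(tv$turnover, oracle_turnover(toy$m, toy$samples$sample_id))
})

test_that("turnover handles empty sets and unranked samples", {
  m <- tibble::tibble(gene_id = c("a", "b"), st0 = c(0, 0), st1 = c(0, 0),
                      st2 = c(3, 0))
  tv <- stage_turnover(m, stage_annotation(c("st0", "st1", "st2")))
  expect_equal(tv$turnover, c(0, 1)) # both empty -> 0; empty vs {a} -> 1

  ann <- stage_annotation(c("st0", "st1", "st2"))
  ann$temporal_rank[2] <- NA
  expect_error(stage_turnover(m, ann), "without temporal_rank.*st1")
})

test_that("turnover lies in [0,1] and reversing stage order reverses the scores", {
  called <- call_expression(random_matrix(12, n_genes = 50, n_samples = 8,
                                          max_value = 5))
  ann <- stage_annotation(setdiff(names(called), "gene_id"))
  tv <- stage_turnover(called, ann)
  expect_true(all(tv$turnover >= 0 & tv$turnover <= 1))
  rev_ann <- ann
  rev_ann$temporal_rank <- rev(ann$temporal_rank)
  expect_equal(stage_turnover(called, rev_ann)$turnover, rev(tv$turnover))
})

test_that("boundary detection takes the largest turnovers with early tie-break", {
  tv <- tibble::tibble(position = 1:3, from_stage = c("a", "b", "c"),
                       to_stage = c("b", "c", "d"),
                       turnover = c(0.1, 0.9, 0.2))
  bd <- detect_boundaries(tv, 1)
  expect_equal(bd$position, 2)
  expect_equal(attr(bd, "n_phases"), 2L)

  tied <- tibble::tibble(position = 1:4, from_stage = letters[1:4],
                         to_stage = letters[2:5],
                         turnover = c(0.5, 0.9, 0.9, 0.5))
  expect_equal(detect_boundaries(tied, 3)$position, c(1, 2, 3)) # earlier 0.5 wins

  expect_equal(detect_boundaries(tv, 3)$position, 1:3) # every gap a boundary
  expect_error(detect_boundaries(tv, 0), "must be in")
  expect_error(detect_boundaries(tv, 4), "must be in")
})

test_that("planted boundaries are recovered exactly at zero noise, at any positions", {
  for (bnd in list(c(2, 3, 7), c(2, 5, 9), c(1, 10))) {
    counts <- default_counts_for(length(bnd) + 1)
    sim <- simulate_staged_series(seed = 5, boundaries = bnd, counts = counts)
    tv <- stage_turnover(call_expression(sim$expression), sim$samples)
    expect_equal(detect_boundaries(tv, length(bnd))$position, bnd)
  }
})

test_that("phase ids follow boundary positions", {
  expect_equal(phase_of_stages(c(2, 3, 7), 12),
               c(1, 1, 2, 3, 3, 3, 3, 4, 4, 4, 4, 4))
  expect_error(phase_of_stages(c(3, 2), 12), "strictly increasing")
  expect_error(phase_of_stages(c(0, 2), 12), "strictly increasing")
})

test_that("temporal groups summarise onset/offset and reserve a silent group", {
  # hand-built archetypes over 6 ranked stages
  m <- tibble::tibble(
    gene_id = c("mat1", "mat2", "burst1", "burst2", "late1", "late2", "off"),
    st0 = c(1, 1, 0, 0, 0, 0, 0),
    st1 = c(0.8, 0.9, 0, 0, 0, 0, 0),
    st2 = c(0, 0, 1, 1, 0, 0, 0),
    st3 = c(0, 0, 0, 0, 0.2, 0.4, 0),
    st4 = c(0, 0, 0, 0, 1, 1, 0),
    st5 = c(0, 0, 0, 0, 0.9, 0.8, 0)
  )
  ann <- stage_annotation(sprintf("st%d", 0:5))
  tg <- assign_temporal_groups(m, ann, k = 3)
  expect_equal(tg$group[tg$gene_id == "off"], "silent")
  expect_true(is.na(tg$onset[tg$gene_id == "off"]))
  expect_equal(tg$onset[tg$gene_id == "mat1"], 0)
  expect_equal(tg$offset[tg$gene_id == "mat1"], 1)
  expect_equal(tg$onset[tg$gene_id == "burst1"], 2) # one-stage burst: onset == offset
  expect_equal(tg$offset[tg$gene_id == "burst1"], 2)
  expect_equal(tg$onset[tg$gene_id == "late1"], 3)
  expect_equal(tg$offset[tg$gene_id == "late1"], 5)
  expect_true(all(tg$onset <= tg$offset, na.rm = TRUE))
  # the three archetypes form the three clusters
  arch <- c(1, 1, 2, 2, 3, 3)
  expect_equal(ari(tg$group[tg$group != "silent"], arch), 1)
})
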