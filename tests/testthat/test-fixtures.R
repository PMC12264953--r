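# The synthetic task generator itself.

test_that("tasks are byte-identical per seed", {
  a <- make_task(seed = 7L, n_corpus = 120L)
  b <- make_task(seed = 7L, n_corpus = 120L)
  expect_identical(a, b)
  c2 <- make_task(seed = 8L, n_corpus = 120L)
  expect_false(identical(a$corpus, c2$corpus))
})

test_that("design families have the promised decomposition structure", {
  task <- shared_task()
  for (s in head(task$partial_designs, 8)) {
    ss <- find_scaffold(s, task$decorations, alpha = 1)$success_score
    expect_true(ss > 0 && ss < 1)
  }
  for (s in head(task$negative_designs, 8)) {
    expect_equal(find_scaffold(s, task$decorations,
                               alpha = 1)$success_score, 0)
  }
  # scaffolds from different ring families are 2D-distinguishable
  fs1 <- find_scaffold(task$positive_designs[1], task$decorations, 1)
  fs3 <- find_scaffold(task$positive_designs[3], task$decorations, 1)
  expect_gt(jaccard_distance(ecfp(fs1$scaffold), ecfp(fs3$scaffold)), 0)
})

test_that("the corpus is clean and contains the positive family", {
  task <- shared_task()
  expect_true(all(!is.na(vapply(task$corpus, canonicalize, character(1)))))
  expect_true(all(task$positive_designs %in% task$corpus))
  expect_equal(anyDuplicated(task$corpus), 0L)
})

test_that("entropy panels are class-controlled by construction", {
  hom <- make_homogeneous_panel(12)
  expect_equal(length(unique(vapply(hom, function(s) {
    bm_framework(s)$cyclic_class
  }, character(1)))), 1L)
  dis <- make_distinct_panel(12)
  expect_equal(length(unique(vapply(dis, function(s) {
    bm_framework(s)$cyclic_class
  }, character(1)))), 12L)
})

test_that("conformer pairs overlay to identity", {
  pair <- shared_conformer_pair()
  expect_equal(dim(pair$reference$xyz), dim(pair$moved$xyz))
  expect_false(isTRUE(all.equal(pair$reference$xyz, pair$moved$xyz)))
  sc <- align_and_score(pair$moved, pair$reference,
                        reward_config(align_starts = 6L))
  expect_equal(sc$rho, 1, tolerance = 1e-3)
  # a different molecule of similar size scores strictly below identity
  other <- generate_conformers("CCc1ccncc1", max_n = 1L)[[1]]
  sc2 <- align_and_score(other, pair$reference,
                         reward_config(align_starts = 6L))
  expect_lt(sc2$rho, 0.999)
})
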