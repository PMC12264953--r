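# The staged scoring function.

test_that("the final reward is the weighted harmonic mean", {
  cfg <- reward_config()
  for (s in c(0.2, 0.5, 0.9)) {
    expect_equal(final_reward(s, s, cfg), s)  # equal inputs are preserved
  }
  expect_equal(final_reward(0.5, 1.0, cfg), 2.5 / 4.0)  # hand-evaluated
  expect_equal(final_reward(0, 0.8, cfg), 0)
  expect_equal(final_reward(0.8, 0, cfg), 0)
})

test_that("harmonic-mean bounds and monotonicity hold", {
  cfg <- reward_config()
  set.seed(21)
  for (i in 1:50) {
    a <- runif(1); b <- runif(1)
    f <- final_reward(a, b, cfg)
    expect_gte(f, min(a, b) - 1e-12)
    expect_lte(f, max(a, b) + 1e-12)
    # monotone in each argument
    expect_gte(final_reward(min(1, a + 0.1), b, cfg), f)
    expect_gte(final_reward(a, min(1, b + 0.1), cfg), f)
  }
  # raising w_2D pulls the reward toward the 2D score
  lo <- final_reward(0.3, 0.9, reward_config(w_2d = 0.5, w_3d = 1))
  hi <- final_reward(0.3, 0.9, reward_config(w_2d = 3, w_3d = 1))
  expect_lt(hi, lo)
})

test_that("the molecule filter derives thresholds from the reference", {
  task <- shared_task()
  ref <- shared_ref2d()
  props <- ref$properties
  expect_equal(ref$cfg$mw_max, props$molecular_weight + 100)
  expect_equal(ref$cfg$rotatable_max, props$rotatable_bonds + 3L)
  expect_equal(ref$cfg$stereocenter_max, props$stereocenters + 2L)
  # the reference passes its own filter
  expect_true(molecule_filter(task$reference, ref$cfg))
  expect_true(molecule_filter("c1ccccc1", ref$cfg))
  # an oversized molecule fails and receives no reward
  big <- paste0(paste(rep("C", 40), collapse = ""), "c1ccccc1")
  expect_false(molecule_filter(big, ref$cfg))
  expect_equal(score_design(big, ref)$final, 0)
})

test_that("2D scores behave as Jaccard distances on scaffolds", {
  expect_equal(score_2d("*c1ccc(*)cc1", "*c1ccc(*)cc1"), 0)
  s <- score_2d("*c1ccc(*)cc1", "*c1ccc(*)nc1")
  expect_true(s > 0 && s < 1)
})

test_that("staged scoring applies filter, partial and full rewards", {
  ref <- shared_ref2d()
  task <- shared_task()
  expect_equal(score_design(task$negative_designs[1], ref)$final, 0)
  b <- score_design(task$partial_designs[1], ref)
  expect_equal(b$final, 0.3)
  expect_true(is.na(b$s2d) && is.na(b$s3d))
  # a perfect self-copy is the worst possible scaffold hop
  self <- score_design(task$reference, ref)
  expect_equal(self$success_score, 1)
  expect_equal(self$s2d, 0)
  expect_equal(self$final, 0)
  # a true hop scores in (0, 1]
  hop <- score_design(task$positive_designs[3], ref)
  expect_equal(hop$success_score, 1)
  expect_gt(hop$final, 0.5)
  # invalid SMILES score 0 but are flagged
  inv <- score_design("C1CC", ref)
  expect_false(inv$valid)
  expect_equal(inv$final, 0)
})

test_that("partial decompositions never trigger 3D scoring", {
  task <- shared_task()
  calls <- new.env(); calls$n <- 0L
  counting_cfg <- reward_config(score3d_fun = function(mol, ref, cfg) {
    calls$n <- calls$n + 1L
    1
  })
  ref <- reference_pack(task$reference, task$decorations, cfg = counting_cfg)
  score_design(task$partial_designs[1], ref)
  score_design(task$negative_designs[1], ref)
  expect_equal(calls$n, 0L)           # short-circuit before stage 3
  score_design(task$positive_designs[2], ref)
  expect_equal(calls$n, 1L)           # full decomposition reaches stage 3
})

test_that("vectorized scoring caches by canonical structure", {
  ref <- shared_ref2d()
  task <- shared_task()
  cache <- new.env()
  out <- score_designs(c(task$positive_designs[1], task$positive_designs[1],
                         task$partial_designs[1]), ref, cache = cache)
  expect_equal(nrow(out), 3L)
  expect_equal(out$final[1], out$final[2])
  expect_equal(length(ls(cache)), 2L)
})
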