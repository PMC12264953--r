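# Conformer generation and the shape/color overlay scorer. These tests
# define the backend contract: range, self-overlay identity and rigid
# invariance. Any swapped-in scorer must pass them.

test_that("stereoisomer enumeration is 2^k over unassigned centers", {
  expect_equal(enumerate_stereoisomers("c1ccccc1"), canonicalize("c1ccccc1"))
  expect_length(enumerate_stereoisomers("CC(N)CO"), 2L)
  expect_length(enumerate_stereoisomers("CC(N)C(O)CC"), 4L)
})

test_that("conformer ensembles respect caps and reject macrocycles", {
  ens <- generate_conformers("c1ccccc1", max_n = 4L)
  expect_gte(length(ens), 1L)
  ens8 <- generate_conformers("CCCCCCCC", max_n = 8L)
  expect_lte(length(ens8), 8L)
  expect_gte(length(ens8), 2L)  # a flexible chain yields several poses

  macro <- generate_conformers("C1CCCCCCCCCCCCC1")  # 14-membered ring
  expect_length(macro, 0L)
  expect_equal(attr(macro, "reason"), "macrocycle")
  expect_equal(best_conformer_score("C1CCCCCCCCCCCCC1",
                                    shared_conformer_pair()$reference), 0)
})

test_that("self-overlay scores identity and rigid motion is removed", {
  pair <- shared_conformer_pair()
  cfg <- reward_config(align_starts = 6L)
  self <- align_and_score(pair$reference, pair$reference, cfg)
  expect_equal(self$shape, 1, tolerance = 1e-3)
  expect_equal(self$color, 1, tolerance = 1e-3)
  expect_equal(self$rho, 1, tolerance = 1e-3)

  moved <- align_and_score(pair$moved, pair$reference, cfg)
  expect_equal(moved$shape, 1, tolerance = 1e-3)
  expect_equal(moved$color, 1, tolerance = 1e-3)

  # translation by 100 A changes nothing after alignment
  far <- align_and_score(
    transform_conformer(pair$reference, diag(3), c(100, 0, 0)),
    pair$reference, cfg)
  expect_equal(far$rho, 1, tolerance = 1e-3)
})

test_that("rho is the weighted mean of shape and color", {
  pair <- shared_conformer_pair()
  cfg <- reward_config(align_starts = 4L)
  other <- generate_conformers("c1ccncc1CO", max_n = 1L)[[1]]
  sc <- align_and_score(other, pair$reference, cfg)
  expect_equal(sc$rho,
               (sc$shape * cfg$w_s + sc$color * cfg$w_c) /
                 (cfg$w_s + cfg$w_c))
  expect_gte(sc$rho, min(sc$shape, sc$color) - 1e-12)
  expect_lte(sc$rho, max(sc$shape, sc$color) + 1e-12)
  expect_true(sc$shape >= 0 && sc$shape <= 1)
  expect_true(sc$color >= 0 && sc$color <= 1)
  expect_lt(sc$shape, 1)  # a different molecule does not overlay perfectly
})

test_that("the ensemble score is the max over conformer scores", {
  pair <- shared_conformer_pair()
  cfg <- reward_config(align_starts = 4L, max_conformers_per_isomer = 3L)
  ens <- generate_conformers("CCCO", max_n = 3L,
                             seed = cfg$conformer_seed, cfg = cfg)
  rhos <- vapply(ens, function(cf) {
    align_and_score(cf, pair$reference, cfg)$rho
  }, numeric(1))
  s3d <- best_conformer_score("CCCO", pair$reference, cfg)
  expect_equal(s3d, max(rhos), tolerance = 1e-6)
  expect_true(all(s3d >= rhos - 1e-9))
})
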