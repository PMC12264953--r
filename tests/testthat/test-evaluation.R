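# Design-set analysis: entropy, retrieval curves, quality filters,
# distance panels.

test_that("scaled Shannon entropy has the documented boundary behavior", {
  expect_equal(sse(c(one_class = 50)), 0)
  expect_equal(sse(rep(1, 50)), 1)
  expect_equal(sse(c(2, 2)), 0.5)   # 1 bit over log2(4) = 2 bits
  expect_error(sse(c(1)))
  # exact formula and label-permutation invariance on random counts
  set.seed(8)
  for (i in 1:20) {
    counts <- sample(1:6, sample(2:6, 1), replace = TRUE)
    n <- sum(counts)
    p <- counts / n
    expect_equal(sse(counts), -sum(p * log2(p)) / log2(n))
    expect_equal(sse(counts), sse(rev(counts)))
  }
})

test_that("retrieval curves span the documented extremes", {
  # one dominant scaffold: flat at full height after the first design
  flat <- retrieval_curve(vapply(1:10, function(i) {
    paste0(paste(rep("C", i), collapse = ""), "c1ccccc1")
  }, character(1)))
  expect_equal(flat$frac_scaffolds, rep(1, 10))
  expect_equal(flat$frac_designs, (1:10) / 10)

  # all-unique scaffolds: the diagonal
  diag_set <- make_distinct_panel(8)
  dg <- retrieval_curve(diag_set)
  expect_equal(dg$frac_scaffolds, dg$frac_designs)

  # mixed set, hand-counted: frameworks with counts 5, 2, 2, 1
  mixed <- c(rep("Cc1ccccc1", 5), rep("Cc1ccncc1", 2),
             rep("CC1CCCCC1", 2), "Cc1ccsc1")
  mc <- retrieval_curve(mixed)
  expect_equal(mc$frac_scaffolds,
               c(1, 1, 1, 1, 1, 2, 2, 3, 3, 4) / 4)
  expect_equal(tail(mc$frac_designs, 1), 1)
  expect_equal(tail(mc$frac_scaffolds, 1), 1)
  expect_true(all(diff(mc$frac_scaffolds) >= 0))  # monotone
})

test_that("the quality filter panel eliminates by rule", {
  task <- shared_task()
  clean <- task$positive_designs[1:3]
  qf <- quality_filter(clean, task$decorations)
  expect_equal(length(qf$passed), 3L)
  expect_true(all(qf$counts[c("decoration_inclusion", "pains")] == 0))

  # a catalogued pan-assay motif is eliminated
  qf2 <- quality_filter("O=C1C=CC(=O)C=C1", task$decorations)
  expect_equal(length(qf2$passed), 0L)
  expect_gte(qf2$counts[["pains"]], 1L)

  # a fuzzy decoration variant passes generation-time scoring at
  # alpha = 0.9 but fails the exact alpha = 1 quality check
  decs10 <- list(decoration("*CCCCCCCCCC"), decoration("*CN"))
  ref10 <- canonicalize("CCCCCCCCCCc1ccc(CN)cc1")
  variant <- canonicalize("CCCCCCCCCc1ccc(CN)cc1")  # nonyl, not decyl
  expect_equal(find_scaffold(variant, decs10, alpha = 0.9)$success_score, 1)
  expect_lt(find_scaffold(variant, decs10, alpha = 1)$success_score, 1)
  qf3 <- quality_filter(variant, decs10)
  expect_equal(qf3$counts[["decoration_inclusion"]], 1L)

  # rule order does not change the retained set (independent predicates)
  both <- c(clean, "O=C1C=CC(=O)C=C1", variant)
  a <- quality_filter(both, task$decorations)$passed
  b <- quality_filter(rev(both), task$decorations)$passed
  expect_setequal(a, b)
})

test_that("distance panels match a brute-force recomputation", {
  task <- shared_task()
  ref <- shared_ref2d()
  expect_warning(
    self_rep <- distance_panel(task$reference, ref),
    regexp = NA)
  expect_equal(unname(self_rep$molecule_distance["mean"]), 0)
  expect_equal(unname(self_rep$scaffold_distance["mean"]), 0)

  designs <- c(task$positive_designs[1:5], task$partial_designs[1:3])
  rep <- distance_panel(designs, ref)
  # independent loop oracle for the molecule distances
  ref_fp <- ecfp(task$reference)
  d <- vapply(designs, function(s) jaccard_distance(ecfp(s), ref_fp),
              numeric(1))
  expect_equal(unname(rep$molecule_distance["mean"]), mean(d))
  expect_equal(unname(rep$molecule_distance["sd"]), sd(d))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(rep$n_without_scaffold, 3L)  # partials have no decomposition
  expect_equal(rep$n_valid, 8L)
  expect_equal(rep$unique_fraction, 1)
})

test_that("the accessibility heuristic penalizes complexity", {
  simple <- accessibility_score("CCO")
  complex_mol <- accessibility_score("CC(N)C(O)C1CCC2CCCCC2C1")
  expect_lt(simple, complex_mol)
  expect_gt(accessibility_score("C1CCCCCCCCCCCC1"),
            accessibility_score("C1CCCCC1"))  # macrocycle penalty
})
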