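# The reinforcement-learning engine: augmented likelihood, loss, diversity
# filter, inception, and run determinism.

test_that("the augmented NLL is the exact affine formula", {
  expect_equal(augmented_nll(10, 0, 128), 10)
  expect_equal(augmented_nll(10, 0.5, 0), 10)
  expect_equal(augmented_nll(30, 1, 128), -98)
  expect_error(augmented_nll(10, 1.5, 128))
})

test_that("the policy loss is the mean squared residual", {
  expect_equal(policy_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(policy_loss(c(1, -1), c(0, 0)), 1)
  base <- policy_loss(c(4, 2), c(1, 5))
  expect_equal(policy_loss(3 * c(4, 2), 3 * c(1, 5)), 9 * base)
  expect_error(policy_loss(numeric(0), numeric(0)))
})

test_that("the diversity filter zeroes over-produced scaffolds", {
  # 31 distinct alkylbenzenes share the benzene framework
  smiles <- vapply(1:31, function(i) {
    canonicalize(paste0(paste(rep("C", i), collapse = ""), "c1ccccc1"))
  }, character(1))
  scored <- data.frame(smiles = smiles, canonical = smiles, valid = TRUE,
                       filtered = FALSE, success_score = 1, s2d = 0.9,
                       s3d = 1, final = 0.9, stringsAsFactors = FALSE)
  df <- diversity_filter()
  adj <- apply_diversity_filter(scored, df, rl_config())
  expect_equal(adj[1:30], rep(0.9, 30))
  expect_equal(adj[31], 0)
  expect_equal(nrow(df_memory(df)), 31L)  # stored even when penalized

  # partial rewards never enter memory or counting
  part <- data.frame(smiles = "CCc1ccccc1", canonical = "CCc1ccccc1",
                     valid = TRUE, filtered = FALSE, success_score = 0.5,
                     s2d = NA, s3d = NA, final = 0.3)
  df2 <- diversity_filter()
  adj2 <- apply_diversity_filter(part, df2, rl_config())
  expect_equal(adj2, 0.3)
  expect_equal(nrow(df_memory(df2)), 0L)

  # a fresh filter leaves a fresh batch untouched
  df3 <- diversity_filter()
  adj3 <- apply_diversity_filter(scored[1:5, ], df3, rl_config())
  expect_equal(adj3, scored$final[1:5])
})

test_that("the inception buffer is a bounded priority queue", {
  mem <- inception_memory()
  empty <- inception_step(mem, data.frame(smiles = character(0),
                                          final = numeric(0),
                                          nll_prior = numeric(0)),
                          memory_size = 5L, sample_size = 3L)
  expect_equal(nrow(empty), 0L)

  batch <- data.frame(smiles = paste0("s", 1:8), final = (1:8) / 10,
                      nll_prior = rnorm(8))
  set.seed(1)
  inception_step(mem, batch, memory_size = 5L, sample_size = 2L)
  expect_equal(nrow(mem$tab), 5L)
  expect_equal(sort(mem$tab$final, decreasing = TRUE),
               c(0.8, 0.7, 0.6, 0.5, 0.4))
  # a better design evicts the current worst
  inception_step(mem, data.frame(smiles = "best", final = 0.95,
                                 nll_prior = 0), 5L, 2L)
  expect_true("best" %in% mem$tab$smiles)
  expect_false(any(mem$tab$final < 0.5))
})

test_that("identical seeds give identical runs; sigma = 0 gives no drive", {
  corp <- c("CCO", "CCN", "CCC", "CCCO", "CCCN", "CCOC", "CC(C)O",
            "CCc1ccccc1", "CCc1ccc(CN)cc1", "NCc1ccccc1")
  tiny <- smiles_lm(corp, epochs = 25L, d_hid = 24L, d_emb = 12L,
                    lr = 0.01, seed = 3L)
  ref <- shared_ref2d()
  cfg <- rl_config(epochs = 4L, batch_size = 12L, lr = 1e-3, seed = 17L,
                   inception_sample_size = 3L)
  r1 <- scaffhop_rl(tiny, ref, cfg)
  r2 <- scaffhop_rl(tiny, ref, cfg)
  expect_identical(r1$logs, r2$logs)
  expect_identical(r1$batches, r2$batches)

  # without reward scaling the agent stays at the prior
  r0 <- scaffhop_rl(tiny, ref, rl_config(epochs = 5L, batch_size = 12L,
                                         sigma = 0, lr = 1e-3, seed = 17L))
  expect_true(all(r0$logs$loss < 1))  # agent NLLs track prior NLLs
})

test_that("logged batches satisfy the augmented-likelihood identities", {
  run <- shared_rl_run()
  for (ep in c(1, 50, 117, 200)) {
    b <- run$batches[[ep]]
    expect_equal(b$nll_aug, b$nll_prior - run$cfg$sigma * b$reward)
    expect_equal(run$logs$loss[ep], mean((b$nll_aug - b$nll_agent)^2))
  }
  # the diversity-filter memory holds only high scorers
  expect_true(all(run$memory$final >= run$cfg$memory_threshold))
  expect_true(all(run$memory$success_score == 1))
  expect_equal(anyDuplicated(run$memory$smiles), 0L)
})
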