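# The SMILES language model: tokenizer, gradients, sampling, training and
# transfer learning.

test_that("tokenization round-trips every corpus string", {
  pool <- fixture_smiles_pool()
  vocab <- smiles_vocab(pool)
  for (s in head(pool, 150)) {
    toks <- smiles_tokens(s)
    expect_identical(paste(toks, collapse = ""), s)
    ids <- encode_smiles(vocab, s)
    expect_identical(decode_ids(vocab, ids), s)
  }
  expect_null(smiles_tokens("C~C"))   # unknown character
})

test_that("analytic gradients match finite differences", {
  set.seed(3)
  vocab <- smiles_vocab(c("CCO", "CC"))
  model <- structure(list(par = init_params(length(vocab$tokens), 5L, 7L, 2L),
                          vocab = vocab, d_emb = 5L, d_hid = 7L,
                          n_layers = 2L), class = "smiles_lm")
  mat <- pad_batch(vocab, c("CCO", "CC"))
  w <- c(0.7, 1.3)
  bw <- lm_backward(model, mat, w)
  numgrad <- function(k, idx) {
    eps <- 1e-5
    m1 <- model; m1$par[[k]][idx] <- m1$par[[k]][idx] + eps
    m2 <- model; m2$par[[k]][idx] <- m2$par[[k]][idx] - eps
    (sum(lm_forward(m1, mat)$nll * w) -
       sum(lm_forward(m2, mat)$nll * w)) / (2 * eps)
  }
  for (k in names(model$par)) {
    idx <- sample(length(model$par[[k]]), min(5L, length(model$par[[k]])))
    for (i in idx) {
      expect_equal(bw$grad[[k]][i], numgrad(k, i), tolerance = 1e-4)
    }
  }
})

test_that("a degenerate corpus is memorized", {
  m <- smiles_lm(rep("CCO", 5), epochs = 150L, d_hid = 24L, d_emb = 12L,
                 lr = 0.01, seed = 1L)
  s <- sample_smiles(m, 300, seed = 2L)
  expect_gt(mean(s$smiles == "CCO"), 0.8)
  expect_lt(nll_smiles(m, "CCO"), 0.3)
})

test_that("sampling is seeded-deterministic and greedy at T -> 0", {
  m <- smiles_lm(c("CCO", "CCC", "CCN"), epochs = 60L, d_hid = 24L,
                 d_emb = 12L, lr = 0.01, seed = 1L)
  a <- sample_smiles(m, 50, seed = 9L)
  b <- sample_smiles(m, 50, seed = 9L)
  expect_identical(a, b)
  g1 <- sample_smiles(m, 5, temperature = 0, seed = 1L)
  g2 <- sample_smiles(m, 5, temperature = 0, seed = 99L)
  expect_identical(g1$smiles, g2$smiles)       # greedy ignores the RNG
  expect_equal(length(unique(g1$smiles)), 1L)  # and is the modal string
})

test_that("sampling frequencies agree with exp(-NLL)", {
  m <- smiles_lm(c("CC", "CCO"), epochs = 250L, d_hid = 24L, d_emb = 12L,
                 lr = 0.01, seed = 4L)
  n <- 10000L
  smp <- sample_smiles(m, n, seed = 11L)
  for (s in c("CC", "CCO")) {
    p_model <- exp(-nll_smiles(m, s))
    p_emp <- mean(smp$smiles == s)
    se <- sqrt(p_model * (1 - p_model) / n)
    expect_lt(abs(p_emp - p_model), 5 * se + 1e-4)
  }
  # the reported NLLs equal the teacher-forced NLLs of the same strings
  done <- smp[1:20, ]
  expect_equal(done$nll, nll_smiles(m, done$smiles), tolerance = 1e-8)
})

test_that("the toy prior generates mostly valid molecules", {
  prior <- shared_prior()
  # held-out NLL decreases over training
  expect_lt(prior$log$val_nll[nrow(prior$log)], prior$log$val_nll[1])
  s <- sample_smiles(prior, 256, seed = 7L)
  valid <- !is.na(vapply(s$smiles, canonicalize, character(1)))
  expect_gt(mean(valid), 0.8)
})

test_that("fine-tuning raises the reference sampling frequency", {
  task <- shared_task()
  tuned <- suppressWarnings(
    finetune(shared_prior(), task$reference, max_epochs = 10L,
             n_check = 1000L, seed = 42L))
  log <- attr(tuned, "finetune_log")
  expect_gt(log$ref_freq[nrow(log)], log$ref_freq[1])
  if (isTRUE(attr(tuned, "converged"))) {
    expect_gt(log$ref_freq[nrow(log)], 0.05)
  }
  # fine-tuning does not destroy validity
  s <- sample_smiles(tuned, 200, seed = 5L)
  valid <- !is.na(vapply(s$smiles, canonicalize, character(1)))
  expect_gt(mean(valid), 0.5)
})

test_that("an already-converged prior returns at once", {
  m <- smiles_lm(rep("CCO", 5), epochs = 150L, d_hid = 24L, d_emb = 12L,
                 lr = 0.01, seed = 1L)
  tuned <- finetune(m, "CCO", max_epochs = 3L, n_check = 400L, seed = 2L)
  log <- attr(tuned, "finetune_log")
  expect_equal(nrow(log), 1L)      # stopped before any training epoch
  expect_true(attr(tuned, "converged"))
})
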