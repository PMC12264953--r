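# Shared fixtures, built once per test run. The task, prior and the
# 200-epoch reinforcement-learning run are expensive, so tests share them
# through memoized getters.

.shared <- new.env(parent = emptyenv())

shared_task <- function() {
  if (is.null(.shared$task)) {
    .shared$task <- make_task(seed = 42L, n_corpus = 400L)
  }
  .shared$task
}

shared_prior <- function() {
  if (is.null(.shared$prior)) {
    .shared$prior <- smiles_lm(shared_task()$corpus, epochs = 50L,
                               d_hid = 96L, d_emb = 48L, lr = 5e-3,
                               seed = 42L)
  }
  .shared$prior
}

# reference pack with the 3D stage stubbed to 1 (2D-only campaigns)
shared_ref2d <- function() {
  if (is.null(.shared$ref2d)) {
    task <- shared_task()
    .shared$ref2d <- reference_pack(
      task$reference, task$decorations,
      cfg = reward_config(score3d_fun = function(mol, ref, cfg) 1))
  }
  .shared$ref2d
}

# the desk-scale learning experiment: 200 epochs x 64 samples, seed 42
shared_rl_run <- function() {
  if (is.null(.shared$run)) {
    .shared$run <- scaffhop_rl(
      shared_prior(), shared_ref2d(),
      rl_config(epochs = 200L, batch_size = 64L, lr = 8e-4, seed = 42L))
  }
  .shared$run
}

shared_conformer_pair <- function() {
  if (is.null(.shared$cpair)) {
    .shared$cpair <- make_conformer_pair(seed = 42L)
  }
  .shared$cpair
}

# small pool of valid drug-like fixture SMILES for property tests
fixture_smiles_pool <- function() {
  task <- shared_task()
  unique(c(task$positive_designs, task$partial_designs,
           task$negative_designs, task$corpus))
}

random_bitset <- function(n, max_bit = 64L) {
  sort(sample.int(max_bit, n)) - 1L
}

as_fp <- function(bits) {
  structure(list(on_bits = as.integer(bits), radius = 3L, nbits = 2048L),
            class = "ecfp")
}
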