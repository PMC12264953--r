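## Reinforcement learning: augmented-likelihood policy updates with a
## Bemis-Murcko diversity filter and inception memory.
##
## Per epoch the agent samples a batch of SMILES, the staged reward scores
## them, the diversity filter zeroes rewards of over-produced scaffolds, and
## the agent is pulled toward the augmented target
## NLL_Aug = NLL_Prior - sigma * S_F by minimizing
## mean((NLL_Aug - NLL_Agent)^2).

#' Reinforcement-learning configuration
#'
#' Defaults are the method's standard settings: reward scaling
#' `sigma = 128`, 64 samples per epoch at temperature 1, diversity-filter
#' bucket limit 30, memory threshold 0.4, seed 42.
#'
#' @param sigma Reward scaling factor (nats per unit reward).
#' @param batch_size Strings sampled per epoch.
#' @param epochs Reinforcement-learning epochs.
#' @param df_bucket_limit Rewards are zeroed once a Bemis-Murcko framework
#'   has produced more than this many high-scoring designs.
#' @param memory_threshold Designs scoring at least this enter the
#'   diversity-filter memory (must exceed the partial reward).
#' @param inception_memory_size,inception_sample_size Capacity of the
#'   inception buffer and replayed strings per epoch (0 disables inception).
#' @param lr Agent Adam learning rate.
#' @param temperature Sampling temperature.
#' @param seed Seed for the whole run (sampling and updates).
#' @return Object of class `rl_config`.
#' @export
rl_config <- function(sigma = 128, batch_size = 64L, epochs = 2000L,
                      df_bucket_limit = 30L, memory_threshold = 0.4,
                      inception_memory_size = 100L,
                      inception_sample_size = 10L, lr = 1e-4,
                      temperature = 1.0, seed = 42L) {
  stopifnot(sigma >= 0, batch_size >= 1, epochs >= 1, memory_threshold > 0)
  structure(list(sigma = sigma, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 df_bucket_limit = as.integer(df_bucket_limit),
                 memory_threshold = memory_threshold,
                 inception_memory_size = as.integer(inception_memory_size),
                 inception_sample_size = as.integer(inception_sample_size),
                 lr = lr, temperature = temperature,
                 seed = as.integer(seed)),
            class = "rl_config")
}

#' Augmented negative log-likelihood
#'
#' `NLL_Aug = NLL_Prior - sigma * S_F`: the likelihood target combining
#' chemical plausibility with the scoring-function reward.
#'
#' @param nll_prior Prior NLL(s) in nats.
#' @param s_f Final reward(s) in `[0, 1]`.
#' @param sigma Reward scaling factor.
#' @return Augmented NLL(s).
#' @export
augmented_nll <- function(nll_prior, s_f, sigma = 128) {
  stopifnot(all(s_f >= 0 & s_f <= 1))
  nll_prior - sigma * s_f
}

#' Policy loss
#'
#' Mean squared difference between the augmented target NLLs and the agent
#' NLLs over a batch; zero exactly when the agent matches the target.
#'
#' @param nll_aug,nll_agent Numeric vectors of equal length (non-empty).
#' @return The scalar loss.
#' @export
policy_loss <- function(nll_aug, nll_agent) {
  if (length(nll_aug) == 0L || length(nll_aug) != length(nll_agent)) {
    stop("batch must be non-empty with matching NLL vectors", call. = FALSE)
  }
  mean((nll_aug - nll_agent)^2)
}

## -- diversity filter ---------------------------------------------------------

#' Create an empty diversity filter
#'
#' Tracks how many high-scoring designs each Bemis-Murcko framework has
#' produced and stores every design scoring at least the memory threshold.
#' The stored designs are "the generated designs" of a run.
#'
#' @return Object of class `diversity_filter` (mutable environment).
#' @export
diversity_filter <- function() {
  e <- new.env(parent = emptyenv())
  e$counts <- new.env(parent = emptyenv())
  e$memory <- list()
  e$memory_keys <- character(0)
  class(e) <- "diversity_filter"
  e
}

#' @export
print.diversity_filter <- function(x, ...) {
  cat("<diversity filter> ", length(ls(x$counts)), " framework bucket(s), ",
      length(x$memory), " design(s) in memory\n", sep = "")
  invisible(x)
}

#' Diversity-filter memory as a data frame
#'
#' @param df A `diversity_filter`.
#' @return `data.frame` of stored designs with reward columns.
#' @export
df_memory <- function(df) {
  if (length(df$memory) == 0L) {
    return(data.frame(smiles = character(0), success_score = numeric(0),
                      s2d = numeric(0), s3d = numeric(0), final = numeric(0),
                      framework = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(df$memory, as.data.frame))
}

framework_key <- function(canonical) {
  fw <- bm_framework(canonical)
  if (!nzchar(fw$framework_smiles)) fw$cyclic_class else fw$framework_smiles
}

#' Apply the diversity filter to a scored batch
#'
#' High-scoring designs (final reward at or above the memory threshold) are
#' counted per Bemis-Murcko framework and stored in the filter memory; once
#' a framework has produced more than `df_bucket_limit` of them, further
#' designs with that framework receive reward 0 (a hard cutoff, not a graded
#' penalty). Lower-scoring designs pass through unchanged.
#'
#' @param scored A `data.frame` from [score_designs()].
#' @param df A `diversity_filter` (mutated in place).
#' @param cfg An [rl_config()].
#' @return Numeric vector of adjusted rewards.
#' @export
apply_diversity_filter <- function(scored, df, cfg = rl_config()) {
  adjusted <- scored$final
  for (i in seq_len(nrow(scored))) {
    if (!scored$valid[i] || is.na(scored$canonical[i])) next
    if (scored$final[i] < cfg$memory_threshold) next
    key <- framework_key(scored$canonical[i])
    cnt <- (df$counts[[key]] %||% 0L) + 1L
    df$counts[[key]] <- cnt
    if (cnt > cfg$df_bucket_limit) adjusted[i] <- 0
    if (!(scored$canonical[i] %in% df$memory_keys)) {
      df$memory_keys <- c(df$memory_keys, scored$canonical[i])
      df$memory[[length(df$memory) + 1L]] <- list(
        smiles = scored$canonical[i],
        success_score = scored$success_score[i],
        s2d = scored$s2d[i], s3d = scored$s3d[i], final = scored$final[i],
        framework = key)
    }
  }
  adjusted
}

## -- inception ----------------------------------------------------------------

inception_memory <- function() {
  e <- new.env(parent = emptyenv())
  e$tab <- data.frame(smiles = character(0), final = numeric(0),
                      nll_prior = numeric(0), stringsAsFactors = FALSE)
  e
}

#' Update the inception buffer and draw replay strings
#'
#' The buffer keeps the best-scoring unique designs seen so far (bounded
#' priority buffer ranked by final reward). Each epoch a random subset is
#' replayed: their squared augmented-likelihood residuals are added to the
#' policy loss to re-expose the agent to past high scorers.
#'
#' @param mem Inception memory (environment from `inception_memory()`).
#' @param batch `data.frame` with `smiles`, `final`, `nll_prior` columns.
#' @param memory_size Buffer capacity.
#' @param sample_size Strings to draw.
#' @return `data.frame` of drawn entries (possibly zero rows).
#' @export
inception_step <- function(mem, batch, memory_size = 100L,
                           sample_size = 10L) {
  keep <- batch[batch$final > 0 & !is.na(batch$smiles), , drop = FALSE]
  if (nrow(keep) > 0L) {
    tab <- rbind(mem$tab, keep[, c("smiles", "final", "nll_prior")])
    tab <- tab[!duplicated(tab$smiles), , drop = FALSE]
    tab <- tab[order(-tab$final), , drop = FALSE]
    mem$tab <- utils::head(tab, memory_size)
  }
  if (nrow(mem$tab) == 0L || sample_size <= 0L) {
    return(mem$tab[integer(0), , drop = FALSE])
  }
  idx <- base::sample.int(nrow(mem$tab), min(sample_size, nrow(mem$tab)))
  mem$tab[idx, , drop = FALSE]
}

## -- the run ------------------------------------------------------------------

#' Run a reinforcement-learning campaign
#'
#' Starting from a trained prior, repeatedly samples a batch of SMILES,
#' scores them with the staged reward, applies the diversity filter, and
#' updates the agent toward the augmented likelihood target (one Adam step
#' per epoch on the combined batch + inception loss). The run is fully
#' deterministic given the seed (with the default 2D pipeline or any
#' deterministic 3D override).
#'
#' @param prior A trained [smiles_lm()]; the agent starts as a copy.
#' @param reference A [reference_pack()].
#' @param cfg An [rl_config()].
#' @param reward_cfg Optional [reward_config()] override (defaults to the
#'   pack's).
#' @param verbose Print a progress line every 10 epochs.
#' @return Object of class `scaffhop_rl` with elements `agent`, `filter`
#'   (the diversity filter), `memory` (its data frame), `logs` (per-epoch),
#'   `batches` (per-epoch scored batches) and the configurations.
#' @export
scaffhop_rl <- function(prior, reference, cfg = rl_config(),
                        reward_cfg = NULL, verbose = FALSE) {
  stopifnot(inherits(prior, "smiles_lm"), inherits(reference,
                                                   "reference_pack"))
  if (is.null(reward_cfg)) reward_cfg <- reference$cfg
  agent <- prior
  opt <- adam_init(agent$par)
  dfilter <- diversity_filter()
  imem <- inception_memory()
  score_cache <- new.env(parent = emptyenv())
  set.seed(cfg$seed)
  logs <- vector("list", cfg$epochs)
  batches <- vector("list", cfg$epochs)

  for (ep in seq_len(cfg$epochs)) {
    smp <- sample_smiles(agent, cfg$batch_size,
                         temperature = cfg$temperature)
    scored <- score_designs(smp$smiles, reference, reward_cfg,
                            cache = score_cache)
    reward <- apply_diversity_filter(scored, dfilter, cfg)
    nll_prior <- nll_smiles(prior, smp$smiles)
    nll_aug <- augmented_nll(nll_prior, reward, cfg$sigma)

    # replay the raw sampled strings (guaranteed within the agent alphabet)
    inc_batch <- data.frame(smiles = smp$smiles, final = reward,
                            nll_prior = nll_prior, stringsAsFactors = FALSE)
    inc <- inception_step(imem, inc_batch, cfg$inception_memory_size,
                          cfg$inception_sample_size)

    all_smiles <- c(smp$smiles, inc$smiles)
    mat <- pad_batch(agent$vocab, all_smiles)
    nll_agent_all <- lm_forward(agent, mat)$nll
    n_b <- length(smp$smiles)
    nll_agent <- nll_agent_all[seq_len(n_b)]
    aug_all <- c(nll_aug,
                 if (nrow(inc) > 0L)
                   augmented_nll(inc$nll_prior, inc$final, cfg$sigma))
    wts <- c(rep(2 / n_b, n_b),
             if (nrow(inc) > 0L) rep(2 / nrow(inc), nrow(inc)))
    weights <- wts * (nll_agent_all - aug_all)
    bw <- lm_backward(agent, mat, weights)
    st <- adam_step(agent$par, bw$grad, opt, lr = cfg$lr)
    agent$par <- st$par
    opt <- st$opt

    loss <- policy_loss(nll_aug, nll_agent)
    batch_df <- data.frame(
      smiles = smp$smiles, canonical = scored$canonical,
      valid = scored$valid, success_score = scored$success_score,
      s2d = scored$s2d, s3d = scored$s3d, final = scored$final,
      reward = reward, nll_prior = nll_prior, nll_agent = nll_agent,
      nll_aug = nll_aug, stringsAsFactors = FALSE)
    batches[[ep]] <- batch_df
    logs[[ep]] <- data.frame(
      epoch = ep, mean_reward = mean(reward),
      frac_valid = mean(scored$valid),
      frac_full = mean(!is.na(scored$success_score) &
                         scored$success_score == 1),
      n_high = sum(reward >= cfg$memory_threshold),
      n_memory = length(dfilter$memory), loss = loss)
    # keep the transient backprop churn from inflating the R heap
    if (ep %% 20L == 0L) gc(full = TRUE)
    if (verbose && ep %% 10L == 0L) {
      message(sprintf(
        "epoch %4d  mean reward %.3f  full decompositions %2.0f%%  memory %d",
        ep, mean(reward), 100 * logs[[ep]]$frac_full,
        length(dfilter$memory)))
    }
  }
  structure(list(agent = agent, filter = dfilter,
                 memory = df_memory(dfilter),
                 logs = do.call(rbind, logs), batches = batches,
                 cfg = cfg, reward_cfg = reward_cfg,
                 reference = reference),
            class = "scaffhop_rl")
}

#' @export
print.scaffhop_rl <- function(x, ...) {
  cat("<reinforcement-learning run> ", nrow(x$logs), " epochs x ",
      x$cfg$batch_size, " samples (sigma = ", x$cfg$sigma, ")\n", sep = "")
  n <- nrow(x$logs)
  k <- min(20L, n)
  cat("  mean reward, first ", k, " epochs: ",
      round(mean(x$logs$mean_reward[seq_len(k)]), 4), "\n", sep = "")
  cat("  mean reward, last  ", k, " epochs: ",
      round(mean(x$logs$mean_reward[(n - k + 1L):n]), 4), "\n", sep = "")
  cat("  designs in memory: ", nrow(x$memory), "\n", sep = "")
  invisible(x)
}

#' @export
summary.scaffhop_rl <- function(object, ...) {
  print(object)
  if (nrow(object$memory) > 0L) {
    cat("\nTop designs in memory:\n")
    m <- object$memory[order(-object$memory$final), ]
    print(utils::head(m, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.scaffhop_rl <- function(x, ...) {
  graphics::plot(x$logs$epoch, x$logs$mean_reward, type = "l",
                 xlab = "epoch", ylab = "mean reward",
                 main = "Reinforcement-learning reward curve", ...)
  graphics::lines(stats::lowess(x$logs$epoch, x$logs$mean_reward, f = 0.3),
                  col = 2, lwd = 2)
  invisible(x)
}

#' @export
simulate.scaffhop_rl <- function(object, nsim = 1, seed = NULL, ...) {
  sample_smiles(object$agent, n = nsim, seed = seed, ...)
}
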