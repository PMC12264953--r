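## SMILES language model: tokenizer vocabulary and an LSTM network trained by
## teacher forcing. The network (embedding, stacked LSTM cells, softmax
## output) and its backward pass are implemented directly in base R matrix
## algebra; correctness is established by finite-difference gradient checks
## and by the agreement between sampling frequencies and exp(-NLL).

#' Build a token vocabulary from a SMILES corpus
#'
#' The vocabulary always contains the pad/begin/end control tokens and a base
#' set of common SMILES tokens, plus every token observed in the corpus.
#' Tokenize-then-detokenize is the identity on every corpus string.
#'
#' @param corpus Character vector of SMILES strings.
#' @return Object of class `smiles_vocab`.
#' @export
smiles_vocab <- function(corpus) {
  base <- c("C", "c", "N", "n", "O", "o", "S", "s", "P", "F", "Cl", "Br",
            "I", "B", "*", "(", ")", "=", "#", "-", "+", as.character(1:9),
            "[nH]", "[O-]", "[N+]", "[NH+]")
  seen <- unique(unlist(lapply(corpus, smiles_tokens)))
  if (any(vapply(corpus, function(s) is.null(smiles_tokens(s)), logical(1)))) {
    stop("corpus contains untokenizable SMILES", call. = FALSE)
  }
  tokens <- c("<pad>", "^", "$", sort(unique(c(base, seen)), method = "radix"))
  structure(list(tokens = tokens,
                 index = stats::setNames(seq_along(tokens), tokens),
                 pad = 1L, begin = 2L, end = 3L),
            class = "smiles_vocab")
}

encode_smiles <- function(vocab, smiles) {
  toks <- smiles_tokens(smiles)
  if (is.null(toks)) stop("untokenizable SMILES: ", smiles, call. = FALSE)
  ids <- unname(vocab$index[toks])
  if (anyNA(ids)) stop("SMILES contains tokens outside the vocabulary: ",
                       smiles, call. = FALSE)
  c(vocab$begin, ids, vocab$end)
}

decode_ids <- function(vocab, ids) {
  ids <- ids[!(ids %in% c(vocab$pad, vocab$begin, vocab$end))]
  paste(vocab$tokens[ids], collapse = "")
}

## -- parameter initialization -------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

init_params <- function(vocab_size, d_emb, d_hid, n_layers) {
  rmat <- function(nr, nc, scale) {
    matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
  }
  par <- list(E = rmat(vocab_size, d_emb, 0.08))
  for (l in seq_len(n_layers)) {
    d_in <- if (l == 1L) d_emb else d_hid
    par[[paste0("W", l)]] <- rmat(d_in + d_hid, 4L * d_hid,
                                  1 / sqrt(d_in + d_hid))
    b <- numeric(4L * d_hid)
    b[(d_hid + 1L):(2L * d_hid)] <- 1  # forget-gate bias
    par[[paste0("b", l)]] <- b
  }
  par$W_out <- rmat(d_hid, vocab_size, 1 / sqrt(d_hid))
  par$b_out <- numeric(vocab_size)
  par
}

## -- forward / backward -------------------------------------------------------

# One LSTM time step for all layers. state: list of list(h, c) per layer.
lstm_step <- function(par, n_layers, d_hid, x_emb, state, keep_cache = FALSE) {
  inp <- x_emb
  caches <- if (keep_cache) vector("list", n_layers) else NULL
  for (l in seq_len(n_layers)) {
    h_prev <- state[[l]]$h
    c_prev <- state[[l]]$c
    zin <- cbind(inp, h_prev)
    z <- zin %*% par[[paste0("W", l)]]
    z <- sweep(z, 2, par[[paste0("b", l)]], "+")
    H <- d_hid
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    if (keep_cache) {
      caches[[l]] <- list(zin = zin, i = i, f = f, g = g, o = o,
                          c_prev = c_prev, cc = cc, tc = tc)
    }
    state[[l]] <- list(h = h, c = cc)
    inp <- h
  }
  list(state = state, h_top = inp, caches = caches)
}

zero_state <- function(n_layers, batch, d_hid) {
  lapply(seq_len(n_layers), function(l) {
    list(h = matrix(0, batch, d_hid), c = matrix(0, batch, d_hid))
  })
}

row_log_softmax <- function(logits) {
  m <- apply(logits, 1, max)
  z <- logits - m
  z - log(rowSums(exp(z)))
}

# Teacher-forced forward over a padded id matrix. Returns per-sequence NLL
# (in nats, end token included) and, optionally, the caches for backprop.
lm_forward <- function(model, ids_mat, keep_cache = FALSE) {
  par <- model$par
  B <- nrow(ids_mat)
  Tm <- ncol(ids_mat) - 1L
  state <- zero_state(model$n_layers, B, model$d_hid)
  nll <- numeric(B)
  caches <- if (keep_cache) vector("list", Tm) else NULL
  probs_cache <- if (keep_cache) vector("list", Tm) else NULL
  for (t in seq_len(Tm)) {
    x <- ids_mat[, t]
    y <- ids_mat[, t + 1L]
    mask <- (x != model$vocab$pad) & (y != model$vocab$pad)
    emb <- par$E[x, , drop = FALSE]
    st <- lstm_step(par, model$n_layers, model$d_hid, emb, state,
                    keep_cache = keep_cache)
    state <- st$state
    logits <- sweep(st$h_top %*% par$W_out, 2, par$b_out, "+")
    # pad/begin are structurally impossible continuations; excluding them
    # keeps teacher-forced NLLs identical to the sampling distribution's
    logits[, model$vocab$pad] <- -Inf
    logits[, model$vocab$begin] <- -Inf
    logp <- row_log_softmax(logits)
    sel <- cbind(seq_len(B), y)
    nll <- nll - ifelse(mask, logp[sel], 0)
    if (keep_cache) {
      caches[[t]] <- list(x = x, y = y, mask = mask, lstm = st$caches,
                          h_top = st$h_top)
      probs_cache[[t]] <- exp(logp)
    }
  }
  list(nll = nll, caches = caches, probs = probs_cache)
}

# Gradient of sum_i weights[i] * NLL_i with respect to all parameters.
lm_backward <- function(model, ids_mat, weights) {
  par <- model$par
  fw <- lm_forward(model, ids_mat, keep_cache = TRUE)
  B <- nrow(ids_mat)
  Tm <- ncol(ids_mat) - 1L
  H <- model$d_hid
  L <- model$n_layers
  grad <- lapply(par, function(p) if (is.matrix(p)) p * 0 else numeric(length(p)))
  dh_next <- lapply(seq_len(L), function(l) matrix(0, B, H))
  dc_next <- lapply(seq_len(L), function(l) matrix(0, B, H))
  for (t in rev(seq_len(Tm))) {
    cache <- fw$caches[[t]]
    probs <- fw$probs[[t]]
    w <- weights * cache$mask
    dlogits <- probs
    sel <- cbind(seq_len(B), cache$y)
    dlogits[sel] <- dlogits[sel] - 1
    dlogits <- dlogits * w
    grad$W_out <- grad$W_out + crossprod(cache$h_top, dlogits)
    grad$b_out <- grad$b_out + colSums(dlogits)
    dh <- dlogits %*% t(par$W_out)  # gradient flowing in from above
    for (l in rev(seq_len(L))) {
      dh_l <- dh_next[[l]] + dh
      cc <- cache$lstm[[l]]
      dc <- dc_next[[l]] + dh_l * cc$o * (1 - cc$tc^2)
      do_ <- dh_l * cc$tc
      di <- dc * cc$g
      dg <- dc * cc$i
      df <- dc * cc$c_prev
      dc_prev <- dc * cc$f
      dz <- cbind(di * cc$i * (1 - cc$i),
                  df * cc$f * (1 - cc$f),
                  dg * (1 - cc$g^2),
                  do_ * cc$o * (1 - cc$o))
      Wl <- paste0("W", l); bl <- paste0("b", l)
      grad[[Wl]] <- grad[[Wl]] + crossprod(cc$zin, dz)
      grad[[bl]] <- grad[[bl]] + colSums(dz)
      dzin <- dz %*% t(par[[Wl]])
      d_in <- ncol(cc$zin) - H
      dinp <- dzin[, seq_len(d_in), drop = FALSE]
      dh_next[[l]] <- dzin[, d_in + seq_len(H), drop = FALSE]
      dc_next[[l]] <- dc_prev
      dh <- dinp  # flows into the lower layer's output at this time step
      if (l == 1L) {
        xi <- cache$x
        for (b in seq_len(B)) {
          grad$E[xi[b], ] <- grad$E[xi[b], ] + dinp[b, ]
        }
      }
    }
  }
  list(grad = grad, nll = fw$nll)
}

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0), t = 0L)
}

adam_step <- function(par, grad, opt, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (k in names(par)) {
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * grad[[k]]
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * grad[[k]]^2
    mhat <- opt$m[[k]] / (1 - beta1^opt$t)
    vhat <- opt$v[[k]] / (1 - beta2^opt$t)
    par[[k]] <- par[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, opt = opt)
}

pad_batch <- function(vocab, smiles_list) {
  ids <- lapply(smiles_list, function(s) encode_smiles(vocab, s))
  Tm <- max(vapply(ids, length, integer(1)))
  mat <- matrix(vocab$pad, length(ids), Tm)
  for (i in seq_along(ids)) mat[i, seq_along(ids[[i]])] <- ids[[i]]
  mat
}

## -- the fitting function -----------------------------------------------------

#' Fit a SMILES language model
#'
#' Trains an LSTM next-token model on a corpus of SMILES strings by
#' teacher-forced maximum likelihood (Adam). This is the "prior" of a
#' reinforcement-learning campaign. Network defaults are desk scale; the
#' architecture (layers/units/embedding) is fully configurable.
#'
#' @param corpus Character vector of SMILES strings.
#' @param epochs Training epochs.
#' @param d_emb,d_hid,n_layers Embedding size, hidden units per layer,
#'   number of stacked LSTM layers.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param val_frac Fraction of the corpus held out for validation NLL.
#' @param seed RNG seed for initialization, shuffling and the validation
#'   split.
#' @param verbose Print per-epoch NLL.
#' @return Object of class `smiles_lm` with the trained parameters, the
#'   vocabulary and a per-epoch log (`train_nll`, `val_nll`).
#' @export
smiles_lm <- function(corpus, epochs = 10L, d_emb = 32L, d_hid = 64L,
                      n_layers = 1L, batch_size = 32L, lr = 3e-3,
                      val_frac = 0.1, seed = 42L, verbose = FALSE) {
  corpus <- unique(corpus[nzchar(corpus)])
  if (length(corpus) == 0L) stop("empty corpus", call. = FALSE)
  set.seed(seed)
  vocab <- smiles_vocab(corpus)
  model <- structure(list(
    par = init_params(length(vocab$tokens), d_emb, d_hid, n_layers),
    vocab = vocab, d_emb = d_emb, d_hid = d_hid, n_layers = n_layers,
    seed = seed
  ), class = "smiles_lm")

  n_val <- if (length(corpus) >= 20L) max(1L, round(val_frac * length(corpus)))
           else 0L
  val <- if (n_val > 0L) base::sample(corpus, n_val) else character(0)
  train <- setdiff(corpus, val)

  opt <- adam_init(model$par)
  log <- data.frame(epoch = integer(0), train_nll = numeric(0),
                    val_nll = numeric(0))
  for (ep in seq_len(epochs)) {
    idx <- base::sample(length(train))
    tot <- 0; nseq <- 0L
    for (start in seq(1L, length(idx), by = batch_size)) {
      sl <- idx[start:min(start + batch_size - 1L, length(idx))]
      mat <- pad_batch(vocab, train[sl])
      bw <- lm_backward(model, mat, rep(1 / length(sl), length(sl)))
      st <- adam_step(model$par, bw$grad, opt, lr = lr)
      model$par <- st$par
      opt <- st$opt
      tot <- tot + sum(bw$nll)
      nseq <- nseq + length(sl)
    }
    vnll <- if (length(val) > 0L) {
      mean(lm_forward(model, pad_batch(vocab, val))$nll)
    } else NA_real_
    log <- rbind(log, data.frame(epoch = ep, train_nll = tot / nseq,
                                 val_nll = vnll))
    if (verbose) {
      message(sprintf("epoch %d  train NLL %.3f  val NLL %.3f", ep,
                      tot / nseq, vnll))
    }
  }
  model$log <- log
  model
}

#' @export
print.smiles_lm <- function(x, ...) {
  cat("<SMILES language model> ", x$n_layers, " LSTM layer(s) x ", x$d_hid,
      " units, embedding ", x$d_emb, ", vocabulary ",
      length(x$vocab$tokens), " tokens\n", sep = "")
  if (!is.null(x$log) && nrow(x$log) > 0L) {
    last <- x$log[nrow(x$log), ]
    cat("  trained ", last$epoch, " epoch(s); final train NLL ",
        round(last$train_nll, 3), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.smiles_lm <- function(object, ...) {
  npar <- sum(vapply(object$par, length, numeric(1)))
  cat("SMILES language model\n")
  print(object)
  cat("  parameters: ", npar, "\n", sep = "")
  if (!is.null(object$log)) print(object$log)
  invisible(object)
}

#' Negative log-likelihood of a SMILES string under the model
#'
#' Sum of per-token negative log probabilities (nats), end token included.
#'
#' @param model A `smiles_lm`.
#' @param smiles Character vector of SMILES strings (must be tokenizable
#'   within the model vocabulary).
#' @return Numeric vector of NLLs.
#' @export
nll_smiles <- function(model, smiles) {
  stopifnot(inherits(model, "smiles_lm"))
  if (length(smiles) == 0L) return(numeric(0))
  lm_forward(model, pad_batch(model$vocab, smiles))$nll
}

#' Sample SMILES strings from the model
#'
#' Token-by-token ancestral sampling from the temperature-scaled next-token
#' distribution. The reported NLL of each string is always the model NLL at
#' temperature 1 (the quantity used by the reinforcement-learning loss).
#'
#' @param model A `smiles_lm`.
#' @param n Number of strings.
#' @param temperature Softmax temperature (`T -> 0` approaches greedy
#'   decoding).
#' @param seed Optional seed; when supplied, sampling is reproducible.
#' @param max_len Maximum token length before truncation.
#' @return `data.frame` with columns `smiles` and `nll`.
#' @export
sample_smiles <- function(model, n, temperature = 1.0, seed = NULL,
                          max_len = 100L) {
  stopifnot(inherits(model, "smiles_lm"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  par <- model$par
  vocab <- model$vocab
  V <- length(vocab$tokens)
  state <- zero_state(model$n_layers, n, model$d_hid)
  cur <- rep(vocab$begin, n)
  alive <- rep(TRUE, n)
  nll <- numeric(n)
  seqs <- vector("list", n)
  for (step in seq_len(max_len)) {
    emb <- par$E[cur, , drop = FALSE]
    st <- lstm_step(par, model$n_layers, model$d_hid, emb, state)
    state <- st$state
    logits <- sweep(st$h_top %*% par$W_out, 2, par$b_out, "+")
    logits[, vocab$pad] <- -Inf
    logits[, vocab$begin] <- -Inf
    logp1 <- row_log_softmax(logits)                 # temperature-1 NLL
    logps <- if (temperature == 1) logp1 else
      row_log_softmax(logits / max(temperature, 1e-6))
    nxt <- integer(n)
    for (b in which(alive)) {
      p <- exp(logps[b, ])
      if (temperature <= 1e-6) {
        nxt[b] <- which.max(logits[b, ])
      } else {
        nxt[b] <- base::sample.int(V, 1L, prob = p)
      }
      nll[b] <- nll[b] - logp1[b, nxt[b]]
    }
    for (b in which(alive)) {
      if (nxt[b] == vocab$end) {
        alive[b] <- FALSE
      } else {
        seqs[[b]] <- c(seqs[[b]], nxt[b])
      }
    }
    cur[alive] <- nxt[alive]
    cur[!alive] <- vocab$end
    if (!any(alive)) break
  }
  smiles <- vapply(seqs, function(s) paste(vocab$tokens[s], collapse = ""),
                   character(1))
  data.frame(smiles = smiles, nll = nll, stringsAsFactors = FALSE)
}

#' @export
simulate.smiles_lm <- function(object, nsim = 1, seed = NULL, ...) {
  sample_smiles(object, n = nsim, seed = seed, ...)
}

## -- transfer learning --------------------------------------------------------

#' Fine-tune a prior on a reference molecule
#'
#' Transfer learning toward a single reference structure: each epoch trains
#' on a batch of randomized SMILES enumerations of the reference (literal
#' single-string training degenerates), samples `n_check` strings and
#' measures how often the canonical reference is produced. The first model
#' whose reference sampling frequency exceeds `threshold` (default 5%) is
#' returned; otherwise the model at `max_epochs` is returned with a warning.
#'
#' @param prior A trained `smiles_lm`.
#' @param reference Reference SMILES (must be valid).
#' @param max_epochs Maximum fine-tuning epochs (default 20).
#' @param n_check Strings sampled per epoch for the stopping rule (default
#'   10000).
#' @param threshold Reference sampling-frequency stopping threshold.
#' @param steps_per_epoch Gradient steps per epoch.
#' @param batch_size Augmented batch size per step.
#' @param lr Adam learning rate.
#' @param seed RNG seed.
#' @return A `smiles_lm` with attributes `finetune_log` (per-epoch reference
#'   frequency) and `converged`.
#' @export
finetune <- function(prior, reference, max_epochs = 20L, n_check = 10000L,
                     threshold = 0.05, steps_per_epoch = 8L,
                     batch_size = 24L, lr = 1e-2, seed = 42L) {
  stopifnot(inherits(prior, "smiles_lm"))
  ref_mol <- parse_molecule(reference)
  if (is.null(ref_mol)) stop("invalid reference SMILES", call. = FALSE)
  set.seed(seed)
  model <- prior
  opt <- adam_init(model$par)
  freqs <- numeric(0)

  ref_freq <- function(m) {
    smp <- sample_smiles(m, n_check, temperature = 1.0)
    tab <- table(smp$smiles)
    hits <- 0L
    for (s in names(tab)) {
      can <- canonicalize(s)
      if (!is.na(can) && can == ref_mol$smiles) hits <- hits + tab[[s]]
    }
    hits / n_check
  }

  f0 <- ref_freq(model)
  freqs <- c(freqs, f0)
  if (f0 > threshold) {
    attr(model, "finetune_log") <- data.frame(epoch = 0L, ref_freq = f0)
    attr(model, "converged") <- TRUE
    return(model)
  }
  for (ep in seq_len(max_epochs)) {
    for (s in seq_len(steps_per_epoch)) {
      aug <- unique(c(ref_mol$smiles,
                      randomized_smiles(ref_mol, batch_size - 1L)))
      aug <- aug[vapply(aug, function(x)
        !is.null(tryCatch(encode_smiles(model$vocab, x),
                          error = function(e) NULL)), logical(1))]
      mat <- pad_batch(model$vocab, aug)
      bw <- lm_backward(model, mat, rep(1 / length(aug), length(aug)))
      st <- adam_step(model$par, bw$grad, opt, lr = lr)
      model$par <- st$par
      opt <- st$opt
    }
    f <- ref_freq(model)
    freqs <- c(freqs, f)
    if (f > threshold) {
      attr(model, "finetune_log") <- data.frame(epoch = 0:ep,
                                                ref_freq = freqs)
      attr(model, "converged") <- TRUE
      return(model)
    }
  }
  warning("fine-tuning did not reach the reference sampling-frequency ",
          "threshold within ", max_epochs, " epochs (last frequency ",
          format(freqs[length(freqs)], digits = 3), ")")
  attr(model, "finetune_log") <- data.frame(epoch = 0:max_epochs,
                                            ref_freq = freqs)
  attr(model, "converged") <- FALSE
  model
}
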