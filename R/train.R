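# Next-token training: unconditional pre-training on unlabeled SMILES and
# conditional fine-tuning on <compound, target> pairs, both under the
# conditional negative log-likelihood
#   NLL(S | c) = - sum_{i=1..N} ln P(t_i | t_{1:i-1}, c),
# with the condition entering only through the logits (via the
# condition-attention sublayer). Teacher forcing: position i of the logits
# is scored against token i+1.

#' Training configuration
#'
#' Defaults follow a standard small-GPT recipe: Adam at 3e-4 with linear
#' warmup and global gradient-norm clipping.
#'
#' @param batch_size Sequences per optimizer step.
#' @param learning_rate Peak Adam learning rate.
#' @param n_epochs Number of passes over the training split.
#' @param seed Seed for shuffling, dropout, and the held-out split.
#' @param warmup_steps Linear learning-rate warmup steps.
#' @param clip_norm Global gradient-norm clip.
#' @param beta1,beta2,eps Adam moments/stabilizer.
#' @param valid_fraction Fraction of sequences held out for the per-epoch
#'   validation NLL.
#' @param scope `"all"`: fine-tuning updates every weight plus the
#'   condition embeddings; `"embeddings"`: only the condition embeddings.
#' @return A `condsmiles_tcfg` list.
#' @export
training_config <- function(batch_size = 32L, learning_rate = 3e-4,
                            n_epochs = 10L, seed = 1L, warmup_steps = 500L,
                            clip_norm = 1.0, beta1 = 0.9, beta2 = 0.999,
                            eps = 1e-8, valid_fraction = 0.1,
                            scope = c("all", "embeddings")) {
  scope <- match.arg(scope)
  stopifnot(batch_size >= 1L, learning_rate > 0, n_epochs >= 0L,
            warmup_steps >= 0L, clip_norm > 0,
            valid_fraction >= 0, valid_fraction < 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 n_epochs = as.integer(n_epochs), seed = as.integer(seed),
                 warmup_steps = as.integer(warmup_steps),
                 clip_norm = clip_norm, beta1 = beta1, beta2 = beta2,
                 eps = eps, valid_fraction = valid_fraction, scope = scope),
            class = "condsmiles_tcfg")
}

#' Sequence negative log-likelihood
#'
#' `-sum_i ln P(target_i | logits_i)`: the negative log of the chain-rule
#' product of the per-step softmax probabilities, in nats. Targets follow
#' the next-token convention (the input sequence shifted left by one, EOS
#' included); PAD positions must already be excluded by the caller.
#'
#' @param logits n x V matrix of next-token logits.
#' @param target_indices Length-n integer vector of 0-based target indices.
#' @return Non-negative scalar (nats).
#' @export
sequence_nll <- function(logits, target_indices) {
  tgt <- as.integer(target_indices)
  if (!is.matrix(logits) || nrow(logits) != length(tgt)) {
    stop("logits must be an n x V matrix matching length(target_indices)",
         call. = FALSE)
  }
  if (any(tgt < 0L | tgt >= ncol(logits))) {
    stop("target index out of range", call. = FALSE)
  }
  n <- nrow(logits)
  mx <- logits[cbind(seq_len(n), max.col(logits, ties.method = "first"))]
  lse <- mx + log(rowSums(exp(logits - mx)))
  -sum(logits[cbind(seq_len(n), tgt + 1L)] - lse)
}

# softmax rows of a logits matrix
softmax_rows <- function(logits) {
  n <- nrow(logits)
  mx <- logits[cbind(seq_len(n), max.col(logits, ties.method = "first"))]
  e <- exp(logits - mx)
  e / rowSums(e)
}

# one sequence: forward + loss + flat gradient (scaled by `weight`)
seq_loss_grad <- function(idx, condition_id, params, config, weight,
                          training = TRUE) {
  n <- length(idx) - 1L
  inp <- idx[seq_len(n)]
  tgt <- idx[-1L]
  fwd <- decoder_forward(inp, condition_id, params, config,
                         want_cache = TRUE, training = training)
  p <- softmax_rows(fwd$logits)
  nll <- -sum(log(p[cbind(seq_len(n), tgt + 1L)]))
  dlogits <- p * weight
  dlogits[cbind(seq_len(n), tgt + 1L)] <-
    dlogits[cbind(seq_len(n), tgt + 1L)] - weight
  grads <- decoder_backward(fwd, dlogits, params, config)
  list(nll = nll, n_tokens = n, flat = flatten_params(grads))
}

# mean per-token NLL over sequences, no dropout, no gradients
corpus_nll <- function(sequences, conditions, params, config) {
  tot <- 0
  ntok <- 0L
  for (i in seq_along(sequences)) {
    idx <- sequences[[i]]
    n <- length(idx) - 1L
    logits <- decoder_forward(idx[seq_len(n)], conditions[[i]], params, config)
    tot <- tot + sequence_nll(logits, idx[-1L])
    ntok <- ntok + n
  }
  tot / ntok
}

# core loop shared by pretrain() and finetune()
run_training <- function(params, config, sequences, conditions, tcfg,
                         trainable_mask = NULL) {
  set.seed(tcfg$seed)
  skel <- param_skeleton(params)
  theta <- flatten_params(params)
  n_par <- length(theta)
  m <- numeric(n_par)
  v <- numeric(n_par)
  step <- 0L
  n_seq <- length(sequences)
  n_valid <- floor(tcfg$valid_fraction * n_seq)
  perm <- sample.int(n_seq)
  valid_ids <- perm[seq_len(n_valid)]
  train_ids <- setdiff(perm, valid_ids)
  live <- params
  eval_nll <- function() {
    ids <- if (n_valid > 0L) valid_ids else train_ids
    corpus_nll(sequences[ids], conditions[ids], live, config)
  }
  log_rows <- list(data.frame(epoch = 0L, train_nll = NA_real_,
                              valid_nll = eval_nll(), seconds = 0))
  for (epoch in seq_len(tcfg$n_epochs)) {
    t0 <- proc.time()[["elapsed"]]
    order_ids <- sample(train_ids)
    ep_nll <- 0
    ep_tok <- 0L
    batch_starts <- seq(1L, length(order_ids), by = tcfg$batch_size)
    for (bs in batch_starts) {
      ids <- order_ids[bs:min(bs + tcfg$batch_size - 1L, length(order_ids))]
      tok_in_batch <- sum(vapply(sequences[ids], length, integer(1)) - 1L)
      w <- 1 / tok_in_batch
      gacc <- numeric(n_par)
      for (id in ids) {
        r <- seq_loss_grad(sequences[[id]], conditions[[id]], live, config, w)
        gacc <- gacc + r$flat
        ep_nll <- ep_nll + r$nll
        ep_tok <- ep_tok + r$n_tokens
      }
      if (!is.null(trainable_mask)) gacc[!trainable_mask] <- 0
      gn <- sqrt(sum(gacc * gacc))
      if (is.finite(gn) && gn > tcfg$clip_norm) {
        gacc <- gacc * (tcfg$clip_norm / gn)
      }
      step <- step + 1L
      lr <- tcfg$learning_rate *
        if (tcfg$warmup_steps > 0L) min(1, step / tcfg$warmup_steps) else 1
      m <- tcfg$beta1 * m + (1 - tcfg$beta1) * gacc
      v <- tcfg$beta2 * v + (1 - tcfg$beta2) * gacc * gacc
      mhat <- m / (1 - tcfg$beta1^step)
      vhat <- v / (1 - tcfg$beta2^step)
      theta <- theta - lr * mhat / (sqrt(vhat) + tcfg$eps)
      live <- structure(unflatten_params(theta, skel),
                        class = "condsmiles_params")
    }
    log_rows[[epoch + 1L]] <- data.frame(
      epoch = epoch, train_nll = ep_nll / ep_tok, valid_nll = eval_nll(),
      seconds = proc.time()[["elapsed"]] - t0)
  }
  list(params = live, log = do.call(rbind, log_rows))
}

encode_corpus <- function(smiles, vocab) {
  lapply(smiles, encode_smiles, vocab = vocab)
}

#' Pre-train the base (unconditional) model
#'
#' Next-token training on an unlabeled SMILES corpus with the condition
#' memory fixed at zero (base mode): the model learns the SMILES grammar
#' and the structure distribution of the corpus, with no target
#' information.
#'
#' @param corpus Character vector of SMILES, or a [molecule_records()]
#'   data.frame (labels are ignored).
#' @param config A [model_config()]; its `vocab_size` is overridden by the
#'   vocabulary built from (or supplied with) the corpus.
#' @param tcfg A [training_config()].
#' @param vocab Optional pre-built vocabulary; default builds one from the
#'   corpus.
#' @return A `condsmiles_model`: list with `params`, `config`, `vocab`,
#'   `condition_labels`, and the per-epoch `log` (epoch 0 is the NLL of the
#'   freshly initialized model on the held-out split).
#' @export
pretrain <- function(corpus, config, tcfg = training_config(), vocab = NULL) {
  smiles <- if (is.data.frame(corpus)) corpus$smiles else corpus
  if (length(smiles) == 0L) stop("empty corpus", call. = FALSE)
  if (is.null(vocab)) vocab <- build_vocabulary(smiles)
  cfg <- config
  cfg$vocab_size <- length(vocab)
  sequences <- encode_corpus(smiles, vocab)
  too_long <- vapply(sequences, length, integer(1)) > cfg$max_len
  if (any(too_long)) {
    stop(sum(too_long), " sequences exceed max_len=", cfg$max_len,
         call. = FALSE)
  }
  params <- init_params(cfg, seed = tcfg$seed)
  conditions <- rep(list(NULL), length(sequences))
  if (tcfg$n_epochs == 0L) {
    res <- list(params = params,
                log = data.frame(epoch = integer(0), train_nll = numeric(0),
                                 valid_nll = numeric(0), seconds = numeric(0)))
  } else {
    res <- run_training(params, cfg, sequences, conditions, tcfg)
  }
  structure(list(params = res$params, config = cfg, vocab = vocab,
                 condition_labels = character(0), log = res$log),
            class = "condsmiles_model")
}

#' Fine-tune on compound-target pairs
#'
#' Starts from the pre-trained weights and trains under the conditional
#' NLL, feeding each sequence's target-specific embedding e_c as the keys
#' and values of the condition-attention sublayer. All weights plus the
#' condition embeddings are updated by default (`scope = "all"` in the
#' training config); `scope = "embeddings"` freezes the shared weights.
#'
#' @param model A `condsmiles_model` from [pretrain()].
#' @param pairs [molecule_records()] data.frame; every row must have a
#'   `target_id`.
#' @param tcfg A [training_config()].
#' @return The fine-tuned `condsmiles_model` with `condition_labels` set
#'   (sorted unique target ids, mapped to 0-based condition indices).
#' @export
finetune <- function(model, pairs, tcfg = training_config(n_epochs = 5L)) {
  stopifnot(inherits(model, "condsmiles_model"))
  if (!is.data.frame(pairs) || is.null(pairs$target_id) ||
      anyNA(pairs$target_id)) {
    stop("every fine-tuning record needs a target_id", call. = FALSE)
  }
  labels <- model$condition_labels
  if (length(labels) == 0L) labels <- sort(unique(pairs$target_id))
  unknown <- setdiff(unique(pairs$target_id), labels)
  if (length(unknown) > 0L) {
    stop("unknown target_id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(labels) > model$config$n_conditions) {
    stop(length(labels), " condition labels but model was configured for ",
         model$config$n_conditions, call. = FALSE)
  }
  cond_ids <- match(pairs$target_id, labels) - 1L
  sequences <- encode_corpus(pairs$smiles, model$vocab)
  conditions <- as.list(cond_ids)
  mask <- if (tcfg$scope == "embeddings") {
    cond_emb_flat_mask(model$params)
  }
  if (tcfg$n_epochs == 0L) {
    res <- list(params = model$params,
                log = data.frame(epoch = integer(0), train_nll = numeric(0),
                                 valid_nll = numeric(0), seconds = numeric(0)))
  } else {
    res <- run_training(model$params, model$config, sequences, conditions,
                        tcfg, trainable_mask = mask)
  }
  structure(list(params = res$params, config = model$config,
                 vocab = model$vocab, condition_labels = labels,
                 log = res$log),
            class = "condsmiles_model")
}

#' @export
print.condsmiles_model <- function(x, ...) {
  cat(sprintf("<condsmiles_model> %d layers, d_model=%d, vocab=%d",
              x$config$n_layers, x$config$d_model, x$config$vocab_size))
  if (length(x$condition_labels) > 0L) {
    cat(", conditions: ", paste(x$condition_labels, collapse = ", "), sep = "")
  }
  if (nrow(x$log) > 0L) {
    cat(sprintf("\n  last held-out NLL/token: %.4f nats",
                utils::tail(x$log$valid_nll, 1)))
  }
  cat("\n")
  invisible(x)
}

#' Write a training log as CSV
#'
#' Columns: epoch, train_nll, valid_nll, seconds.
#'
#' @param model A `condsmiles_model`.
#' @param path Output path.
#' @export
write_training_log <- function(model, path) {
  utils::write.csv(model$log, path, row.names = FALSE)
  invisible(path)
}
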