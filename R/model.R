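# Conditional decoder-only Transformer over SMILES tokens.
#
# Each of the n_layers identical layers applies, in order and each wrapped
# in a residual connection followed by layer normalization (post-LN):
#   1. masked multi-head self-attention over the token positions,
#   2. multi-head attention whose keys and values are the condition memory
#      e_c (the target-specific embedding; an all-zero memory in base mode),
#   3. a position-wise feed-forward network (ReLU).
# Token embeddings are scaled by sqrt(d_model) and summed with sinusoidal
# positional encodings. Logits come from a separate (untied) output
# projection.

#' Model configuration
#'
#' @param vocab_size Number of tokens, including the three specials.
#' @param n_layers Number of decoder layers.
#' @param n_heads Attention heads `h`.
#' @param d_model Width of the residual stream.
#' @param d_k,d_v Per-head key/query and value width.
#' @param d_ff Hidden width of the feed-forward sublayer.
#' @param max_len Maximum sequence length (tokens incl. BOS/EOS).
#' @param n_conditions Number of condition (target) labels; 0 for a
#'   base-only, unconditional model.
#' @param cond_memory_len Number of memory slots `m` in the condition
#'   embedding e_c (default 1: a single vector serving as the one key and
#'   one value of the condition-attention sublayer).
#' @param dropout Dropout probability applied during training.
#' @return A `condsmiles_config` list.
#' @export
model_config <- function(vocab_size,
                         n_layers = 8L, n_heads = 8L, d_model = 256L,
                         d_k = 32L, d_v = 32L, d_ff = 1024L,
                         max_len = 100L, n_conditions = 0L,
                         cond_memory_len = 1L, dropout = 0.1) {
  cfg <- list(vocab_size = as.integer(vocab_size),
              n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
              d_model = as.integer(d_model), d_k = as.integer(d_k),
              d_v = as.integer(d_v), d_ff = as.integer(d_ff),
              max_len = as.integer(max_len),
              n_conditions = as.integer(n_conditions),
              cond_memory_len = as.integer(cond_memory_len),
              dropout = as.numeric(dropout))
  with(cfg, {
    stopifnot(vocab_size >= 4L, n_layers >= 1L, n_heads >= 1L, d_model >= 1L,
              d_k >= 1L, d_v >= 1L, d_ff >= 1L, max_len >= 2L,
              n_conditions >= 0L, cond_memory_len >= 1L,
              dropout >= 0, dropout < 1)
  })
  structure(cfg, class = "condsmiles_config")
}

#' Desk-scale ("tiny") configuration preset
#'
#' Two layers at width 64 — enough to learn the toy grammar in minutes on
#' one CPU, used throughout the test-suite.
#'
#' @inheritParams model_config
#' @param ... Overrides passed to [model_config()].
#' @export
tiny_config <- function(vocab_size, n_conditions = 0L, ...) {
  model_config(vocab_size, n_layers = 2L, n_heads = 4L, d_model = 64L,
               d_k = 16L, d_v = 16L, d_ff = 256L, max_len = 40L,
               n_conditions = n_conditions, dropout = 0, ...)
}

#' @export
print.condsmiles_config <- function(x, ...) {
  cat(sprintf(
    "<condsmiles_config> %d layers, %d heads, d_model=%d, d_ff=%d, vocab=%d, conditions=%d\n",
    x$n_layers, x$n_heads, x$d_model, x$d_ff, x$vocab_size, x$n_conditions))
  invisible(x)
}

#' Initialize decoder parameters
#'
#' Weight matrices and embeddings are drawn N(0, 0.02^2); biases and
#' layer-norm offsets start at zero, layer-norm scales at one. Attention
#' projections carry no bias (so a zero condition memory yields an exactly
#' zero condition-attention output). Deterministic given `seed`.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return A `condsmiles_params` nested list of tensors.
#' @export
init_params <- function(config, seed = 1L) {
  stopifnot(inherits(config, "condsmiles_config"))
  set.seed(as.integer(seed))
  d <- config$d_model
  h <- config$n_heads
  dk <- config$d_k
  dv <- config$d_v
  sd0 <- 0.02
  rnd <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sd0), nr, nc)
  attn_block <- function() list(
    Wq = rnd(d, h * dk), Wk = rnd(d, h * dk), Wv = rnd(d, h * dv),
    Wo = rnd(h * dv, d))
  layers <- lapply(seq_len(config$n_layers), function(l) list(
    self_attn = attn_block(),
    ln1_g = rep(1, d), ln1_b = rep(0, d),
    cond_attn = attn_block(),
    ln2_g = rep(1, d), ln2_b = rep(0, d),
    ff_W1 = rnd(d, config$d_ff), ff_b1 = rep(0, config$d_ff),
    ff_W2 = rnd(config$d_ff, d), ff_b2 = rep(0, d),
    ln3_g = rep(1, d), ln3_b = rep(0, d)))
  params <- list(
    tok_emb = rnd(config$vocab_size, d),
    cond_emb = lapply(seq_len(config$n_conditions),
                      function(cc) rnd(config$cond_memory_len, d)),
    layers = layers,
    out_W = rnd(d, config$vocab_size),
    out_b = rep(0, config$vocab_size))
  structure(params, class = "condsmiles_params")
}

#' Causal (autoregressive) attention mask
#'
#' Entry (i, j) is `TRUE` iff position i may attend to position j, i.e.
#' j <= i: a lower-triangular truth pattern.
#'
#' @param n Sequence length (>= 1).
#' @return n x n logical matrix.
#' @export
causal_mask <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("causal_mask needs n >= 1", call. = FALSE)
  outer(seq_len(n), seq_len(n), `>=`)
}

# multiply each column j of x by g[j] (column-major fast path; avoids sweep)
colscale <- function(x, g) x * rep(g, each = nrow(x))

# add b[j] to each column j of x
coladd <- function(x, b) x + rep(b, each = nrow(x))

# row-wise softmax; -Inf entries get exactly zero weight. Errors if a row
# is fully masked (softmax undefined).
row_softmax <- function(s) {
  n <- nrow(s)
  mx <- s[cbind(seq_len(n), max.col(s, ties.method = "first"))]
  if (any(!is.finite(mx))) {
    stop("attention row with all positions masked: softmax undefined",
         call. = FALSE)
  }
  e <- exp(s - mx)
  e / rowSums(e)
}

layer_norm <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(y = coladd(colscale(xhat, g), b), xhat = xhat, inv = inv)
}

#' Multi-head scaled dot-product attention
#'
#' Projects queries, keys, and values `h` times, applies
#' softmax(Q_i K_i^T / sqrt(d_k)) V_i per head, concatenates the heads and
#' projects with W^O. Masked positions are set to -Inf before the softmax
#' and therefore receive exactly zero weight.
#'
#' @param queries n x d_model matrix.
#' @param keys,values m x d_model matrices.
#' @param weights List with projection matrices `Wq`, `Wk`, `Wv`
#'   (d_model x h*d_k / h*d_k / h*d_v) and `Wo` (h*d_v x d_model).
#' @param n_heads,d_k,d_v Head count and per-head widths.
#' @param mask Optional n x m logical matrix; `TRUE` = may attend.
#' @param want_cache Internal: also return activations for backprop.
#' @return n x d_model output matrix (or a list when `want_cache`).
#' @export
multi_head_attention <- function(queries, keys, values, weights,
                                 n_heads, d_k, d_v, mask = NULL,
                                 want_cache = FALSE) {
  qp <- queries %*% weights$Wq
  kp <- keys %*% weights$Wk
  vp <- values %*% weights$Wv
  n <- nrow(qp)
  o_concat <- matrix(0, n, n_heads * d_v)
  a_heads <- vector("list", n_heads)
  scale <- 1 / sqrt(d_k)
  for (i in seq_len(n_heads)) {
    kc <- ((i - 1L) * d_k + 1L):(i * d_k)
    vc <- ((i - 1L) * d_v + 1L):(i * d_v)
    s <- tcrossprod(qp[, kc, drop = FALSE], kp[, kc, drop = FALSE]) * scale
    if (!is.null(mask)) s[!mask] <- -Inf
    a <- row_softmax(s)
    o_concat[, vc] <- a %*% vp[, vc, drop = FALSE]
    if (want_cache) a_heads[[i]] <- a
  }
  out <- o_concat %*% weights$Wo
  if (!want_cache) return(out)
  list(out = out, qp = qp, kp = kp, vp = vp, a = a_heads,
       o_concat = o_concat, q_in = queries, k_in = keys, v_in = values)
}

# memoized sinusoidal positional-encoding table
the_pe <- new.env(parent = emptyenv())
positional_encoding <- function(max_len, d_model) {
  key <- paste0(max_len, "x", d_model)
  pe <- the_pe[[key]]
  if (!is.null(pe)) return(pe)
  pos <- seq_len(max_len) - 1
  i <- seq_len(ceiling(d_model / 2)) - 1
  ang <- outer(pos, 1 / 10000^(2 * i / d_model))
  pe <- matrix(0, max_len, d_model)
  pe[, seq(1, d_model, by = 2)] <- sin(ang)[, seq_along(seq(1, d_model, by = 2))]
  pe[, seq(2, d_model, by = 2)] <- cos(ang)[, seq_along(seq(2, d_model, by = 2))]
  the_pe[[key]] <- pe
  pe
}

cond_memory <- function(params, config, condition_id) {
  if (is.null(condition_id)) {
    return(matrix(0, config$cond_memory_len, config$d_model))
  }
  condition_id <- as.integer(condition_id)
  if (is.na(condition_id) || condition_id < 0L ||
      condition_id >= config$n_conditions) {
    stop("condition_id ", condition_id, " out of range [0, ",
         config$n_conditions, ")", call. = FALSE)
  }
  params$cond_emb[[condition_id + 1L]]
}

# inverted-dropout mask (NULL when p == 0 or not training)
drop_mask <- function(nr, nc, p, training) {
  if (!training || p <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= p) / (1 - p), nr, nc)
}

apply_drop <- function(x, m) if (is.null(m)) x else x * m

#' Decoder forward pass
#'
#' Computes next-token logits for every position of a token sequence.
#' Logits at position i depend only on tokens at positions <= i (enforced
#' by the causal mask, exactly) and on the condition memory e_c.
#' `condition_id = NULL` runs base mode: the condition memory is the zero
#' matrix, making the condition-attention sublayer contribute exactly zero
#' before its residual.
#'
#' @param token_indices Integer vector of 0-based vocabulary indices
#'   (length n <= max_len).
#' @param condition_id 0-based condition index, or `NULL` for base mode.
#' @param params From [init_params()] or training.
#' @param config The matching [model_config()].
#' @param want_cache Internal: keep activations for backprop.
#' @param training Internal: apply dropout (consumes RNG).
#' @return n x vocab_size matrix of logits (or a list when `want_cache`).
#' @export
decoder_forward <- function(token_indices, condition_id, params, config,
                            want_cache = FALSE, training = FALSE) {
  idx <- as.integer(token_indices)
  n <- length(idx)
  if (n < 1L) stop("empty token sequence", call. = FALSE)
  if (n > config$max_len) {
    stop("sequence length ", n, " exceeds max_len ", config$max_len,
         call. = FALSE)
  }
  if (any(idx < 0L | idx >= config$vocab_size)) {
    stop("token index out of range", call. = FALSE)
  }
  d <- config$d_model
  mem <- cond_memory(params, config, condition_id)
  x <- params$tok_emb[idx + 1L, , drop = FALSE] * sqrt(d) +
    positional_encoding(config$max_len, d)[seq_len(n), , drop = FALSE]
  p <- config$dropout
  dm_emb <- drop_mask(n, d, p, training)
  x <- apply_drop(x, dm_emb)
  mask <- causal_mask(n)
  caches <- if (want_cache) vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    lay <- params$layers[[l]]
    sa <- multi_head_attention(x, x, x, lay$self_attn, config$n_heads,
                               config$d_k, config$d_v, mask,
                               want_cache = want_cache)
    sa_out <- if (want_cache) sa$out else sa
    dm1 <- drop_mask(n, d, p, training)
    r1 <- x + apply_drop(sa_out, dm1)
    ln1 <- layer_norm(r1, lay$ln1_g, lay$ln1_b)
    ca <- multi_head_attention(ln1$y, mem, mem, lay$cond_attn,
                               config$n_heads, config$d_k, config$d_v,
                               mask = NULL, want_cache = want_cache)
    ca_out <- if (want_cache) ca$out else ca
    dm2 <- drop_mask(n, d, p, training)
    r2 <- ln1$y + apply_drop(ca_out, dm2)
    ln2 <- layer_norm(r2, lay$ln2_g, lay$ln2_b)
    h_pre <- coladd(ln2$y %*% lay$ff_W1, lay$ff_b1)
    h_act <- h_pre * (h_pre > 0)
    ff <- coladd(h_act %*% lay$ff_W2, lay$ff_b2)
    dm3 <- drop_mask(n, d, p, training)
    r3 <- ln2$y + apply_drop(ff, dm3)
    ln3 <- layer_norm(r3, lay$ln3_g, lay$ln3_b)
    if (want_cache) {
      caches[[l]] <- list(x_in = x, sa = sa, dm1 = dm1, ln1 = ln1,
                          ca = ca, dm2 = dm2, ln2 = ln2,
                          h_pre = h_pre, h_act = h_act, dm3 = dm3, ln3 = ln3)
    }
    x <- ln3$y
  }
  logits <- coladd(x %*% params$out_W, params$out_b)
  if (!want_cache) return(logits)
  list(logits = logits, x_final = x, caches = caches, idx = idx,
       dm_emb = dm_emb, mem = mem, condition_id = condition_id)
}
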