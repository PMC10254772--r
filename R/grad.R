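# Hand-derived backward pass for the conditional decoder.
#
# Gradient structures mirror the parameter structure field-for-field so a
# flattened gradient vector aligns with the flattened parameter vector; the
# optimizer works entirely on flat vectors.

# reverse of layer_norm: dy -> (dx, dgamma, dbeta)
ln_backward <- function(dy, ln, g) {
  xhat <- ln$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxh <- colscale(dy, g)
  dx <- ln$inv * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat))
  list(dx = dx, dg = dgamma, db = dbeta)
}

# reverse of multi_head_attention given its forward cache
mha_backward <- function(dout, cache, w, n_heads, d_k, d_v) {
  d_wo <- crossprod(cache$o_concat, dout)
  do_concat <- tcrossprod(dout, w$Wo)
  n <- nrow(cache$qp)
  m <- nrow(cache$kp)
  dqp <- matrix(0, n, n_heads * d_k)
  dkp <- matrix(0, m, n_heads * d_k)
  dvp <- matrix(0, m, n_heads * d_v)
  scale <- 1 / sqrt(d_k)
  for (i in seq_len(n_heads)) {
    kc <- ((i - 1L) * d_k + 1L):(i * d_k)
    vc <- ((i - 1L) * d_v + 1L):(i * d_v)
    a <- cache$a[[i]]
    do_i <- do_concat[, vc, drop = FALSE]
    da <- tcrossprod(do_i, cache$vp[, vc, drop = FALSE])
    dvp[, vc] <- crossprod(a, do_i)
    ds <- a * (da - rowSums(da * a))
    dqp[, kc] <- ds %*% cache$kp[, kc, drop = FALSE] * scale
    dkp[, kc] <- crossprod(ds, cache$qp[, kc, drop = FALSE]) * scale
  }
  list(d_Wq = crossprod(cache$q_in, dqp),
       d_Wk = crossprod(cache$k_in, dkp),
       d_Wv = crossprod(cache$v_in, dvp),
       d_Wo = d_wo,
       dq_in = tcrossprod(dqp, w$Wq),
       dk_in = tcrossprod(dkp, w$Wk),
       dv_in = tcrossprod(dvp, w$Wv))
}

# full backward pass: d(loss)/d(logits) -> nested gradient list shaped
# exactly like `params`
decoder_backward <- function(fwd, dlogits, params, config) {
  d <- config$d_model
  h <- config$n_heads
  g_out_w <- crossprod(fwd$x_final, dlogits)
  g_out_b <- colSums(dlogits)
  dx <- tcrossprod(dlogits, params$out_W)
  g_layers <- vector("list", config$n_layers)
  dmem <- NULL
  for (l in rev(seq_len(config$n_layers))) {
    cc <- fwd$caches[[l]]
    lay <- params$layers[[l]]
    b3 <- ln_backward(dx, cc$ln3, lay$ln3_g)
    dff <- apply_drop(b3$dx, cc$dm3)
    dz2 <- b3$dx
    g_ff_w2 <- crossprod(cc$h_act, dff)
    g_ff_b2 <- colSums(dff)
    dh <- tcrossprod(dff, lay$ff_W2) * (cc$h_pre > 0)
    g_ff_w1 <- crossprod(cc$ln2$y, dh)
    g_ff_b1 <- colSums(dh)
    dz2 <- dz2 + tcrossprod(dh, lay$ff_W1)
    b2 <- ln_backward(dz2, cc$ln2, lay$ln2_g)
    dca <- apply_drop(b2$dx, cc$dm2)
    dz1 <- b2$dx
    ab <- mha_backward(dca, cc$ca, lay$cond_attn, h, config$d_k, config$d_v)
    dz1 <- dz1 + ab$dq_in
    dmem_l <- ab$dk_in + ab$dv_in
    dmem <- if (is.null(dmem)) dmem_l else dmem + dmem_l
    b1 <- ln_backward(dz1, cc$ln1, lay$ln1_g)
    dsa <- apply_drop(b1$dx, cc$dm1)
    dx <- b1$dx
    sb <- mha_backward(dsa, cc$sa, lay$self_attn, h, config$d_k, config$d_v)
    dx <- dx + sb$dq_in + sb$dk_in + sb$dv_in
    g_layers[[l]] <- list(
      self_attn = list(Wq = sb$d_Wq, Wk = sb$d_Wk, Wv = sb$d_Wv, Wo = sb$d_Wo),
      ln1_g = b1$dg, ln1_b = b1$db,
      cond_attn = list(Wq = ab$d_Wq, Wk = ab$d_Wk, Wv = ab$d_Wv, Wo = ab$d_Wo),
      ln2_g = b2$dg, ln2_b = b2$db,
      ff_W1 = g_ff_w1, ff_b1 = g_ff_b1, ff_W2 = g_ff_w2, ff_b2 = g_ff_b2,
      ln3_g = b3$dg, ln3_b = b3$db)
  }
  dx0 <- apply_drop(dx, fwd$dm_emb)
  g_tok <- matrix(0, config$vocab_size, d)
  acc <- rowsum(dx0 * sqrt(d), group = fwd$idx)
  g_tok[as.integer(rownames(acc)) + 1L, ] <- acc
  g_cond <- lapply(seq_len(config$n_conditions),
                   function(i) matrix(0, config$cond_memory_len, d))
  if (!is.null(fwd$condition_id)) {
    g_cond[[as.integer(fwd$condition_id) + 1L]] <- dmem
  }
  list(tok_emb = g_tok, cond_emb = g_cond, layers = g_layers,
       out_W = g_out_w, out_b = g_out_b)
}

# ---- flat-vector parameter utilities ------------------------------------

flatten_params <- function(params) {
  as.numeric(unlist(params, use.names = FALSE))
}

param_skeleton <- function(params) {
  if (is.list(params)) return(lapply(params, param_skeleton))
  list(d = dim(params), n = length(params))
}

unflatten_params <- function(vec, skel) {
  pos <- 0L
  rec <- function(s) {
    if (is.list(s) && is.null(s$n)) return(lapply(s, rec))
    v <- vec[(pos + 1L):(pos + s$n)]
    pos <<- pos + s$n
    if (!is.null(s$d)) dim(v) <- s$d
    v
  }
  out <- rec(skel)
  stopifnot(pos == length(vec))
  out
}

# flat index range of the condition-embedding block (for fine-tuning scope)
cond_emb_flat_mask <- function(params) {
  n_tok <- length(params$tok_emb)
  n_cond <- sum(vapply(params$cond_emb, length, integer(1)))
  total <- length(flatten_params(params))
  mask <- rep(FALSE, total)
  if (n_cond > 0L) mask[(n_tok + 1L):(n_tok + n_cond)] <- TRUE
  mask
}
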