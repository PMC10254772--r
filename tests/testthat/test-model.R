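# Structural tests of the decoder: attention against a naive oracle,
# masking, causality, and base/conditional consistency.

ns <- asNamespace("condsmiles")

# independent oracle: per-head, per-position double loop, own softmax
naive_mha <- function(q_in, k_in, v_in, w, h, d_k, d_v, mask = NULL) {
  n <- nrow(q_in)
  m <- nrow(k_in)
  out_concat <- matrix(0, n, h * d_v)
  for (i in seq_len(h)) {
    kc <- ((i - 1) * d_k + 1):(i * d_k)
    vc <- ((i - 1) * d_v + 1):(i * d_v)
    qi <- q_in %*% w$Wq[, kc, drop = FALSE]
    ki <- k_in %*% w$Wk[, kc, drop = FALSE]
    vi <- v_in %*% w$Wv[, vc, drop = FALSE]
    for (r in seq_len(n)) {
      scores <- numeric(m)
      for (cc in seq_len(m)) {
        scores[cc] <- sum(qi[r, ] * ki[cc, ]) / sqrt(d_k)
      }
      if (!is.null(mask)) scores[!mask[r, ]] <- -Inf
      wts <- exp(scores - max(scores))
      wts <- wts / sum(wts)
      acc <- numeric(d_v)
      for (cc in seq_len(m)) acc <- acc + wts[cc] * vi[cc, ]
      out_concat[r, vc] <- acc
    }
  }
  out_concat %*% w$Wo
}

rand_weights <- function(d, h, d_k, d_v) {
  list(Wq = matrix(rnorm(d * h * d_k), d), Wk = matrix(rnorm(d * h * d_k), d),
       Wv = matrix(rnorm(d * h * d_v), d), Wo = matrix(rnorm(h * d_v * d), h * d_v))
}

test_that("multi-head attention matches the naive per-head loop oracle", {
  set.seed(123)
  for (case in 1:20) {
    h <- sample(1:3, 1)
    d_k <- sample(1:4, 1)
    d_v <- sample(1:4, 1)
    d <- sample(2:8, 1)
    n <- sample(1:8, 1)
    m <- sample(1:8, 1)
    w <- rand_weights(d, h, d_k, d_v)
    q <- matrix(rnorm(n * d), n)
    k <- matrix(rnorm(m * d), m)
    v <- matrix(rnorm(m * d), m)
    mask <- if (case %% 2 == 0 && n == m) causal_mask(n)
    got <- multi_head_attention(q, k, v, w, h, d_k, d_v, mask = mask)
    want <- naive_mha(q, k, v, w, h, d_k, d_v, mask = mask)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("single-head scalar example matches the hand softmax", {
  # Q=[[1,0]], K=I2, V rows (1,0)/(0,0) projected to one dim:
  # weight on key 1 is sigmoid(1/sqrt(2)), output = that weight
  w <- list(Wq = diag(2), Wk = diag(2), Wv = matrix(c(1, 0), 2, 1),
            Wo = matrix(c(1, 0), 1, 2))
  out <- multi_head_attention(matrix(c(1, 0), 1, 2), diag(2),
                              matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE),
                              w, n_heads = 1, d_k = 2, d_v = 1)
  expect_equal(out[1, 1], 1 / (1 + exp(-1 / sqrt(2))), tolerance = 1e-9)
  expect_equal(out[1, 1], 0.6698, tolerance = 1e-3)
})

test_that("attention over all-zero values is exactly zero", {
  set.seed(4)
  w <- rand_weights(6, 2, 3, 3)
  out <- multi_head_attention(matrix(rnorm(12), 2), matrix(rnorm(18), 3),
                              matrix(0, 3, 6), w, 2, 3, 3)
  expect_identical(out, matrix(0, 2, 6))
})

test_that("attention weights are a distribution over unmasked keys", {
  set.seed(9)
  w <- rand_weights(8, 2, 4, 4)
  x <- matrix(rnorm(40), 5)
  cache <- multi_head_attention(x, x, x, w, 2, 4, 4, mask = causal_mask(5),
                                want_cache = TRUE)
  for (a in cache$a) {
    expect_equal(rowSums(a), rep(1, 5), tolerance = 1e-6)
    expect_true(all(a[upper.tri(a)] == 0))  # masked => exactly zero weight
  }
  expect_error(
    multi_head_attention(x, x, x, w, 2, 4, 4,
                         mask = matrix(FALSE, 5, 5)),
    "masked")
})

test_that("causal mask is lower-triangular truth", {
  expect_identical(causal_mask(1), matrix(TRUE, 1, 1))
  m3 <- causal_mask(3)
  expect_identical(rowSums(m3), c(1, 2, 3))
  expect_false(m3[1, 3])
  expect_error(causal_mask(0), "n >= 1")
})

test_that("init_params is seed-deterministic and shape-consistent", {
  cfg <- tiny_config(vocab_size = 20, n_conditions = 3)
  p1 <- init_params(cfg, seed = 5)
  p2 <- init_params(cfg, seed = 5)
  expect_identical(p1, p2)
  p3 <- init_params(cfg, seed = 6)
  expect_false(identical(p1$tok_emb, p3$tok_emb))
  expect_identical(dim(p1$tok_emb), c(20L, 64L))
  expect_identical(length(p1$cond_emb), 3L)
  expect_identical(dim(p1$cond_emb[[1]]), c(1L, 64L))
  expect_identical(dim(p1$layers[[1]]$self_attn$Wq), c(64L, 64L))
  expect_identical(dim(p1$out_W), c(64L, 20L))
  expect_true(all(p1$layers[[2]]$ln3_g == 1))
  expect_true(all(p1$layers[[2]]$ff_b1 == 0))
})

test_that("logits are bitwise-causal: perturbing position j leaves i<j alone", {
  model <- make_random_tiny_model(seed = 31)
  cfg <- model$config
  v <- cfg$vocab_size
  set.seed(55)
  for (probe in 1:100) {
    n <- sample(4:12, 1)
    idx <- sample(0:(v - 1L), n, replace = TRUE)
    j <- sample(2:n, 1)
    idx2 <- idx
    idx2[j] <- (idx2[j] + sample(v - 1L, 1)) %% v
    cond <- if (probe %% 2 == 0) 0L
    l1 <- decoder_forward(idx, cond, model$params, cfg)
    l2 <- decoder_forward(idx2, cond, model$params, cfg)
    expect_identical(l1[seq_len(j - 1L), , drop = FALSE],
                     l2[seq_len(j - 1L), , drop = FALSE])
  }
})

test_that("different condition embeddings change the logits", {
  model <- make_random_tiny_model(seed = 8)
  idx <- c(1L, 4L, 5L, 6L)
  l0 <- decoder_forward(idx, 0L, model$params, model$config)
  l1 <- decoder_forward(idx, 1L, model$params, model$config)
  expect_gt(max(abs(l0 - l1)), 0)
  expect_error(decoder_forward(idx, 5L, model$params, model$config),
               "out of range")
  expect_error(decoder_forward(c(1L, 999L), NULL, model$params, model$config),
               "out of range")
})

test_that("zero condition memory: sublayer output is exactly zero and the
           base forward equals the reduced stack", {
  model <- make_random_tiny_model(seed = 13)
  cfg <- model$config
  p <- model$params
  idx <- c(1L, 3L, 7L, 4L, 9L, 2L)
  # the condition sublayer with zero memory contributes exactly zero
  zero_mem <- matrix(0, cfg$cond_memory_len, cfg$d_model)
  q <- matrix(rnorm(length(idx) * cfg$d_model), length(idx))
  out <- multi_head_attention(q, zero_mem, zero_mem,
                              p$layers[[1]]$cond_attn,
                              cfg$n_heads, cfg$d_k, cfg$d_v)
  expect_identical(out, matrix(0, length(idx), cfg$d_model))

  # reduced stack built inline: condition sublayer replaced by LN(z + 0)
  d <- cfg$d_model
  n <- length(idx)
  x <- p$tok_emb[idx + 1L, ] * sqrt(d) +
    ns$positional_encoding(cfg$max_len, d)[seq_len(n), ]
  mask <- causal_mask(n)
  for (l in seq_len(cfg$n_layers)) {
    lay <- p$layers[[l]]
    sa <- multi_head_attention(x, x, x, lay$self_attn, cfg$n_heads,
                               cfg$d_k, cfg$d_v, mask)
    z1 <- ns$layer_norm(x + sa, lay$ln1_g, lay$ln1_b)$y
    z2 <- ns$layer_norm(z1 + 0, lay$ln2_g, lay$ln2_b)$y
    hh <- ns$coladd(z2 %*% lay$ff_W1, lay$ff_b1)
    hh <- hh * (hh > 0)
    ff <- ns$coladd(hh %*% lay$ff_W2, lay$ff_b2)
    x <- ns$layer_norm(z2 + ff, lay$ln3_g, lay$ln3_b)$y
  }
  reduced_logits <- ns$coladd(x %*% p$out_W, p$out_b)
  base_logits <- decoder_forward(idx, NULL, p, cfg)
  expect_identical(base_logits, reduced_logits)
})

test_that("checkpoint save/load round-trips and validates shapes", {
  model <- make_random_tiny_model(seed = 3)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_equal(back$params, model$params)
  expect_identical(unclass(back$vocab), unclass(model$vocab))
  idx <- c(1L, 4L, 2L)
  expect_identical(decoder_forward(idx, NULL, back$params, back$config),
                   decoder_forward(idx, NULL, model$params, model$config))
  # corrupt a shape
  obj <- readRDS(path)
  obj$params$out_W <- obj$params$out_W[, -1]
  saveRDS(obj, path)
  expect_error(load_checkpoint(path), "shape mismatch")
})
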