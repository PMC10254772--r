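# NLL correctness, teacher forcing, determinism, and small training probes.
# The expensive stated-scale training runs live in test-acceptance.R and
# are shared through the lazy fixtures.

test_that("sequence NLL: uniform closed form and chain-rule oracle", {
  # uniform logits over V=4, N=3 -> 3 ln 4
  expect_equal(sequence_nll(matrix(0, 3, 4), c(0L, 1L, 3L)), 3 * log(4),
               tolerance = 1e-12)
  expect_equal(sequence_nll(matrix(5, 3, 4), c(2L, 2L, 0L)), 3 * log(4),
               tolerance = 1e-12)

  # one-hot-correct logits with growing margin -> 0
  mk <- function(margin) {
    l <- matrix(0, 2, 3)
    l[cbind(1:2, c(1L, 3L))] <- margin
    sequence_nll(l, c(0L, 2L))
  }
  expect_true(mk(20) < mk(5))
  expect_lt(mk(40), 1e-15)

  # random instances against an explicit chain-rule product
  set.seed(42)
  for (case in 1:10) {
    n <- 5L
    v <- 6L
    logits <- matrix(rnorm(n * v, sd = 3), n, v)
    tgt <- sample(0:(v - 1L), n, replace = TRUE)
    prob <- 1
    for (i in seq_len(n)) {
      p <- exp(logits[i, ]) / sum(exp(logits[i, ]))
      prob <- prob * p[tgt[i] + 1L]
    }
    expect_equal(sequence_nll(logits, tgt), -log(prob), tolerance = 1e-9)
  }
  expect_error(sequence_nll(matrix(0, 3, 4), c(0L, 1L)), "matching")
  expect_error(sequence_nll(matrix(0, 2, 4), c(0L, 7L)), "out of range")
})

test_that("teacher forcing scores position i against token i+1", {
  # hand-built 3-token molecule "CO" -> sequence BOS C O EOS
  vocab <- build_vocabulary("CO")
  model <- local({
    cfg <- tiny_config(vocab_size = length(vocab), n_conditions = 0L)
    structure(list(params = init_params(cfg, 3), config = cfg, vocab = vocab,
                   condition_labels = character(0), log = data.frame()),
              class = "condsmiles_model")
  })
  idx <- encode_smiles("CO", vocab)  # BOS C O EOS
  ns <- asNamespace("condsmiles")
  r <- ns$seq_loss_grad(idx, NULL, model$params, model$config, weight = 1,
                        training = FALSE)
  # manual: forward on (BOS, C, O), score columns (C, O, EOS)
  logits <- decoder_forward(idx[1:3], NULL, model$params, model$config)
  expect_equal(r$nll, sequence_nll(logits, idx[2:4]), tolerance = 1e-12)
  expect_identical(r$n_tokens, 3L)
})

test_that("pretrain: epoch 0 NLL is the uniform entropy, learning happens", {
  recs <- sample_toy_molecules(default_toy_spec(), n = 400, seed = 19)
  vocab <- build_vocabulary(recs$smiles)
  cfg <- tiny_config(vocab_size = length(vocab), n_conditions = 0L)
  tc <- training_config(n_epochs = 2L, seed = 4L, learning_rate = 1e-3)
  model <- pretrain(recs, cfg, tc, vocab = vocab)
  log <- model$log
  # freshly initialized logits are near zero -> NLL/token ~ ln(vocab)
  expect_equal(log$valid_nll[1], log(length(vocab)), tolerance = 0.05)
  expect_lt(tail(log$valid_nll, 1), log$valid_nll[1])
  expect_identical(nrow(log), 3L)  # epoch 0 baseline + 2 epochs
})

test_that("n_epochs = 0 returns initialized / base params unchanged", {
  recs <- sample_toy_molecules(default_toy_spec(), n = 30, seed = 2)
  vocab <- build_vocabulary(recs$smiles)
  cfg <- tiny_config(vocab_size = length(vocab), n_conditions = 2L)
  model <- pretrain(recs, cfg, training_config(n_epochs = 0L, seed = 9),
                    vocab = vocab)
  expect_equal(unclass(model$params),
               unclass(init_params(model$config, seed = 9L)))
  ft <- finetune(model, recs, training_config(n_epochs = 0L))
  expect_identical(ft$params, model$params)
  expect_identical(sort(ft$condition_labels), c("T0", "T1"))
})

test_that("empty corpus and unknown targets are errors", {
  cfg <- tiny_config(vocab_size = 10)
  expect_error(pretrain(character(0), cfg), "empty")
  recs <- sample_toy_molecules(default_toy_spec(), n = 30, seed = 2)
  vocab <- build_vocabulary(recs$smiles)
  cfg <- tiny_config(vocab_size = length(vocab), n_conditions = 1L)
  model <- pretrain(recs, cfg, training_config(n_epochs = 0L), vocab = vocab)
  expect_error(finetune(model, recs), "configured for 1")
  recs$target_id[1] <- NA
  expect_error(finetune(model, recs), "target_id")
})

test_that("training is seed-deterministic", {
  recs <- sample_toy_molecules(default_toy_spec(), n = 120, seed = 3)
  vocab <- build_vocabulary(recs$smiles)
  cfg <- tiny_config(vocab_size = length(vocab), n_conditions = 2L)
  tc <- training_config(n_epochs = 2L, seed = 11L, batch_size = 16L)
  m1 <- pretrain(recs, cfg, tc, vocab = vocab)
  m2 <- pretrain(recs, cfg, tc, vocab = vocab)
  expect_identical(m1$log$valid_nll, m2$log$valid_nll)
  expect_identical(m1$params, m2$params)
})

test_that("embedding-only fine-tuning moves only the used condition memory", {
  recs <- sample_toy_molecules(default_toy_spec(), n = 80, seed = 6)
  recs0 <- recs[recs$target_id == "T0", , drop = FALSE]
  vocab <- build_vocabulary(recs$smiles)
  cfg <- tiny_config(vocab_size = length(vocab), n_conditions = 2L)
  base <- pretrain(recs, cfg, training_config(n_epochs = 0L), vocab = vocab)
  base$condition_labels <- c("T0", "T1")
  ft <- finetune(base, recs0,
                 training_config(n_epochs = 1L, scope = "embeddings",
                                 valid_fraction = 0))
  # shared weights frozen
  expect_identical(ft$params$tok_emb, base$params$tok_emb)
  expect_identical(ft$params$layers, base$params$layers)
  expect_identical(ft$params$out_W, base$params$out_W)
  # only the condition-0 memory moved
  expect_false(identical(ft$params$cond_emb[[1]], base$params$cond_emb[[1]]))
  expect_identical(ft$params$cond_emb[[2]], base$params$cond_emb[[2]])

  # full fine-tune on single-condition pairs: the unused condition memory
  # still has no gradient path of its own
  ft2 <- finetune(base, recs0,
                  training_config(n_epochs = 1L, valid_fraction = 0))
  expect_identical(ft2$params$cond_emb[[2]], base$params$cond_emb[[2]])
  expect_false(identical(ft2$params$cond_emb[[1]], base$params$cond_emb[[1]]))
})

test_that("fine-tuned model assigns lower NLL under the matching condition", {
  ft <- trained_conditional_model()
  spec <- default_toy_spec()
  ns <- asNamespace("condsmiles")
  held0 <- sample_toy_molecules(spec, n = 40, condition_id = 0, seed = 901)
  held1 <- sample_toy_molecules(spec, n = 40, condition_id = 1, seed = 902)
  nll <- function(smiles, cond) {
    seqs <- lapply(smiles, encode_smiles, vocab = ft$vocab)
    ns$corpus_nll(seqs, rep(list(cond), length(seqs)), ft$params, ft$config)
  }
  expect_lt(nll(held0$smiles, 0L), nll(held0$smiles, 1L))
  expect_lt(nll(held1$smiles, 1L), nll(held1$smiles, 0L))
})

test_that("training log serializes as CSV", {
  ft <- trained_conditional_model()
  path <- withr::local_tempfile(fileext = ".csv")
  write_training_log(ft, path)
  back <- read.csv(path)
  expect_identical(names(back), c("epoch", "train_nll", "valid_nll",
                                  "seconds"))
  expect_identical(nrow(back), nrow(ft$log))
})
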