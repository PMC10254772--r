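# Model checkpointing: a single archive holding config, vocabulary,
# condition labels, and all parameter tensors; loading validates the shape
# table against the stored config.

#' Save / load a model checkpoint
#'
#' @param model A `condsmiles_model`.
#' @param path Checkpoint path.
#' @return `load_checkpoint()` returns the model; `save_checkpoint()` the
#'   path, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "condsmiles_model"))
  obj <- list(format = "condsmiles-checkpoint", version = 1L,
              config = unclass(model$config),
              vocab = as.list(unclass(model$vocab)),
              condition_labels = model$condition_labels,
              params = unclass(model$params),
              log = model$log)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "condsmiles-checkpoint")) {
    stop("'", path, "' is not a condsmiles checkpoint", call. = FALSE)
  }
  cfg <- do.call(model_config, obj$config[c(
    "vocab_size", "n_layers", "n_heads", "d_model", "d_k", "d_v", "d_ff",
    "max_len", "n_conditions", "cond_memory_len", "dropout")])
  ids <- as.integer(unlist(obj$vocab))
  names(ids) <- names(obj$vocab)
  vocab <- structure(sort(ids), class = "condsmiles_vocab")
  params <- structure(obj$params, class = "condsmiles_params")
  validate_param_shapes(params, cfg)
  structure(list(params = params, config = cfg, vocab = vocab,
                 condition_labels = obj$condition_labels, log = obj$log),
            class = "condsmiles_model")
}

validate_param_shapes <- function(params, config) {
  d <- config$d_model
  h <- config$n_heads
  expect_dim <- function(x, nr, nc, what) {
    if (!identical(dim(x), c(nr, nc))) {
      stop("checkpoint shape mismatch for ", what, call. = FALSE)
    }
  }
  expect_dim(params$tok_emb, config$vocab_size, d, "tok_emb")
  if (length(params$cond_emb) != config$n_conditions) {
    stop("checkpoint shape mismatch for cond_emb", call. = FALSE)
  }
  for (m in params$cond_emb) expect_dim(m, config$cond_memory_len, d, "cond_emb")
  if (length(params$layers) != config$n_layers) {
    stop("checkpoint layer count mismatch", call. = FALSE)
  }
  for (lay in params$layers) {
    expect_dim(lay$self_attn$Wq, d, h * config$d_k, "self Wq")
    expect_dim(lay$self_attn$Wo, h * config$d_v, d, "self Wo")
    expect_dim(lay$cond_attn$Wk, d, h * config$d_k, "cond Wk")
    expect_dim(lay$ff_W1, d, config$d_ff, "ff_W1")
    expect_dim(lay$ff_W2, config$d_ff, d, "ff_W2")
  }
  expect_dim(params$out_W, d, config$vocab_size, "out_W")
  invisible(TRUE)
}
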