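# Autoregressive conditional generation of SMILES.
#
# Each sequence starts from BOS and ends at EOS or max_len truncation;
# tokens are drawn from the temperature-scaled softmax (multinomial
# sampling at temperature 1 by default, with optional top-k truncation).
# Every sequence runs on its own seeded RNG stream (seed + sequence index)
# so a batch is reproducible and prefixes are invariant to max_len.

#' Sample one token index from logits
#'
#' Draws from `softmax(logits / temperature)`. Temperatures below 1e-6 are
#' treated as the argmax limit.
#'
#' @param logits Numeric vector of V logits (must be finite).
#' @param temperature Positive real.
#' @param top_k Keep only the `top_k` largest logits (0 = disabled).
#' @return 0-based sampled index; advances the R RNG.
#' @export
sample_next_token <- function(logits, temperature = 1.0, top_k = 0L) {
  if (any(!is.finite(logits))) stop("non-finite logits", call. = FALSE)
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  if (temperature < 1e-6) return(which.max(logits) - 1L)
  keep <- seq_along(logits)
  if (top_k > 0L && top_k < length(logits)) {
    keep <- order(logits, decreasing = TRUE)[seq_len(top_k)]
  }
  z <- logits[keep] / temperature
  p <- exp(z - max(z))
  p <- p / sum(p)
  keep[sample.int(length(keep), 1L, prob = p)] - 1L
}

#' Generate a batch of SMILES from a trained model
#'
#' @param model A `condsmiles_model`.
#' @param n Number of sequences to sample.
#' @param condition_id 0-based condition index, a condition label from
#'   `model$condition_labels`, or `NULL` for base (unconditional) mode.
#' @param max_len Maximum generated length in tokens (default: the model's
#'   `max_len` minus the BOS slot). Truncated sequences are kept and
#'   validity-checked.
#' @param temperature Sampling temperature.
#' @param top_k Optional top-k logit truncation (0 = disabled).
#' @param seed Batch seed; sequence i uses stream `seed + i`.
#' @return A `condsmiles_generation`: list with `raw_smiles`, `canonical`
#'   (`NA` marks an invalid molecule), `valid_flags`, `condition_id`,
#'   `condition_label`, `seed`, `temperature`.
#' @export
generate <- function(model, n, condition_id = NULL, max_len = NULL,
                     temperature = 1.0, top_k = 0L, seed = 1L) {
  stopifnot(inherits(model, "condsmiles_model"), n >= 1L)
  cfg <- model$config
  label <- NA_character_
  if (is.character(condition_id)) {
    pos <- match(condition_id, model$condition_labels)
    if (is.na(pos)) {
      stop("unknown condition label '", condition_id, "'", call. = FALSE)
    }
    label <- condition_id
    condition_id <- pos - 1L
  } else if (!is.null(condition_id)) {
    condition_id <- as.integer(condition_id)
    if (condition_id >= 0L && condition_id < length(model$condition_labels)) {
      label <- model$condition_labels[condition_id + 1L]
    }
  }
  if (!is.null(condition_id)) {
    cond_memory(model$params, cfg, condition_id)  # range check
  }
  if (is.null(max_len)) max_len <- cfg$max_len - 1L
  max_len <- min(max_len, cfg$max_len - 1L)
  vocab_names <- names(model$vocab)
  bos <- 1L
  eos <- 2L
  # PAD and BOS must never be emitted inside a sequence
  allowed <- which(!(vocab_names %in% c(PAD_TOKEN, BOS_TOKEN))) - 1L
  raw <- character(n)
  for (s in seq_len(n)) {
    set.seed(as.integer(seed) + s)
    idx <- bos
    repeat {
      logits <- decoder_forward(idx, condition_id, model$params, cfg)
      last <- logits[nrow(logits), allowed + 1L]
      tok <- allowed[sample_next_token(last, temperature, top_k) + 1L]
      if (tok == eos) break
      idx <- c(idx, tok)
      if (length(idx) - 1L >= max_len) break
    }
    raw[s] <- decode_indices(idx[-1L], model$vocab)
  }
  canonical <- canonicalize_smiles(raw)
  structure(list(raw_smiles = raw, canonical = canonical,
                 valid_flags = !is.na(canonical),
                 condition_id = condition_id, condition_label = label,
                 seed = as.integer(seed), temperature = temperature),
            class = "condsmiles_generation")
}

#' @export
print.condsmiles_generation <- function(x, ...) {
  cat(sprintf(
    "<condsmiles_generation> %d sequences, %.1f%% valid, condition=%s, T=%g, seed=%d\n",
    length(x$raw_smiles), 100 * mean(x$valid_flags),
    if (is.null(x$condition_id)) "base" else x$condition_id,
    x$temperature, x$seed))
  invisible(x)
}

#' Write a generation batch to .smi plus a JSON sidecar
#'
#' The sidecar records seed, temperature, condition, and validity so a
#' generated library is self-describing.
#'
#' @param batch A `condsmiles_generation`.
#' @param path Output `.smi` path; the sidecar is `<path>.json`.
#' @export
write_generation <- function(batch, path) {
  writeLines(batch$raw_smiles, path)
  meta <- list(n = length(batch$raw_smiles), seed = batch$seed,
               temperature = batch$temperature,
               condition_id = batch$condition_id,
               condition_label = batch$condition_label,
               valid_fraction = mean(batch$valid_flags))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
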