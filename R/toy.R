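# Seeded toy molecular grammar: valid-by-construction SMILES whose
# substituents depend on a condition label, plus a synthetic pXC50
# generator with a known feature-to-activity mapping. Stands in for a real
# pre-training corpus and target-specific activity sets so the whole
# pipeline is trainable and testable offline in minutes.
#
# Condition 0 molecules carry fluorinated substituents, condition 1
# chlorinated ones — mutually exclusive, tokenizer-visible motifs a tiny
# model can learn quickly.

#' Toy grammar specification
#'
#' Scaffold templates with a conditional slot `{S}` (and optionally a
#' neutral slot `{N}`), per-condition substituent pools, and the motif
#' SMARTS used to score condition consistency. On construction every
#' scaffold x substituent composition is canonicalized through the
#' chemistry toolkit; an unparseable composition is an error.
#'
#' @param seed Seed recorded in the spec (used by samplers that default to
#'   it).
#' @param validate Verify every composition canonicalizes (one batched
#'   bridge call); disable only when the default spec is already known
#'   good.
#' @return A `condsmiles_toy_spec`.
#' @export
toy_grammar_spec <- function(seed = 1L, validate = TRUE) {
  spec <- structure(list(
    templates = c("c1ccc({S})cc1",
                  "c1ccc({N})cc1{S}",
                  "c1cc({S})ccc1{N}",
                  "C1CCC({S})CC1",
                  "O=C({N})NC{S}",
                  "C({N})C{S}"),
    neutral_pool = c("C", "CC", "CCC", "OC", "CN"),
    cond_pools = list(c("F", "CCF", "C(F)F", "CCCF", "CC(F)F", "C(F)(F)F"),
                      c("Cl", "CCCl", "C(Cl)Cl", "CCCCl", "CC(Cl)Cl",
                        "C(Cl)(Cl)Cl")),
    motif_smarts = c("[F]", "[Cl]"),
    condition_labels = c("T0", "T1"),
    seed = as.integer(seed)), class = "condsmiles_toy_spec")
  if (validate) validate_toy_spec(spec)
  spec
}

compose_toy <- function(template, s, n) {
  out <- sub("{S}", s, template, fixed = TRUE)
  sub("{N}", n, out, fixed = TRUE)
}

validate_toy_spec <- function(spec) {
  combos <- character(0)
  for (tpl in spec$templates) {
    for (s in unlist(spec$cond_pools)) {
      for (n in spec$neutral_pool) {
        combos <- c(combos, compose_toy(tpl, s, n))
      }
    }
  }
  combos <- unique(combos)
  bad <- combos[!is_valid_smiles(combos)]
  if (length(bad) > 0L) {
    stop("toy grammar produces invalid SMILES, e.g. '", bad[1], "'",
         call. = FALSE)
  }
  # motif exclusivity: no scaffold or neutral substituent may contain a
  # conditional motif atom
  neutral_part <- c(spec$templates, spec$neutral_pool)
  if (any(grepl("F|Cl", neutral_part))) {
    stop("toy scaffolds/neutral substituents must not contain motif atoms",
         call. = FALSE)
  }
  invisible(TRUE)
}

# the validated default spec, built once per session
the_toy <- new.env(parent = emptyenv())

#' Default validated toy grammar
#' @return The memoized default `condsmiles_toy_spec`.
#' @export
default_toy_spec <- function() {
  if (is.null(the_toy$spec)) the_toy$spec <- toy_grammar_spec()
  the_toy$spec
}

#' Sample molecules from the toy grammar
#'
#' Every output is valid by construction. With `condition_id = NULL` the
#' condition is drawn uniformly per molecule; records always carry the
#' realized condition label as `target_id`.
#'
#' @param spec A [toy_grammar_spec()].
#' @param n Number of molecules (>= 1).
#' @param condition_id 0-based condition (0 = fluorinated pool,
#'   1 = chlorinated), or `NULL` to mix uniformly.
#' @param seed Seed (defaults to the spec's).
#' @return [molecule_records()] data.frame with `target_id` set.
#' @export
sample_toy_molecules <- function(spec = default_toy_spec(), n,
                                 condition_id = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "condsmiles_toy_spec"), n >= 1L)
  n_cond <- length(spec$cond_pools)
  if (!is.null(condition_id)) {
    condition_id <- as.integer(condition_id)
    if (condition_id < 0L || condition_id >= n_cond) {
      stop("unknown condition ", condition_id, call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  conds <- if (is.null(condition_id)) {
    sample.int(n_cond, n, replace = TRUE) - 1L
  } else {
    rep.int(condition_id, n)
  }
  tpl <- sample(spec$templates, n, replace = TRUE)
  neu <- sample(spec$neutral_pool, n, replace = TRUE)
  smi <- character(n)
  for (i in seq_len(n)) {
    s <- sample(spec$cond_pools[[conds[i] + 1L]], 1L)
    smi[i] <- compose_toy(tpl[i], s, neu[i])
  }
  molecule_records(smi, target_id = spec$condition_labels[conds + 1L])
}

#' Fraction of molecules carrying a condition's motif
#'
#' Substructure-matches each molecule against the condition's motif SMARTS
#' — the toy analogue of target-specificity evaluation: a well-conditioned
#' generator scores high under its matching condition and low under the
#' mismatched one.
#'
#' @param smiles_list Character vector of valid SMILES.
#' @param spec A [toy_grammar_spec()].
#' @param condition_id 0-based condition index.
#' @return Fraction in \[0, 1\].
#' @export
condition_consistency <- function(smiles_list, spec = default_toy_spec(),
                                  condition_id) {
  condition_id <- as.integer(condition_id)
  stopifnot(condition_id >= 0L, condition_id < length(spec$motif_smarts))
  if (length(smiles_list) == 0L) return(NaN)
  res <- chem_call("substruct",
                   list(smiles = as.list(smiles_list),
                        smarts = spec$motif_smarts[condition_id + 1L]))
  mean(vapply(res$match, isTRUE, logical(1)))
}

#' Attach synthetic pXC50 activities with a known mapping
#'
#' Activity is a fixed linear function of a seeded choice of fingerprint
#' bits (from the same 2048-bit FCFP6 block the QSAR featurizer uses) plus
#' Gaussian noise: a ground truth a boosted-tree model should recover. The
#' mapping (bit indices, weights, intercept) is stored in the
#' `activity_mapping` attribute for recovery tests.
#'
#' @param records [molecule_records()] data.frame.
#' @param noise_sd Gaussian noise standard deviation (pXC50 units).
#' @param seed Seed for bit choice, weights, and noise.
#' @param n_signal_bits Number of causal fingerprint bits.
#' @param intercept Baseline pXC50 (default 6.5, a typical assay scale).
#' @return `records` with `pxc50` filled and the mapping attached.
#' @export
synth_activity <- function(records, noise_sd = 0.3, seed = 1L,
                           n_signal_bits = 20L, intercept = 6.5) {
  set.seed(as.integer(seed))
  res <- chem_call("morgan", list(smiles = as.list(records$smiles),
                                  radius = 3L, n_bits = 2048L,
                                  use_features = TRUE))
  n <- nrow(records)
  bits <- Matrix::sparseMatrix(
    i = rep(seq_len(n), lengths(res$bits)),
    j = unlist(res$bits) + 1L, x = 1, dims = c(n, 2048L))
  prevalence <- Matrix::colSums(bits) / n
  candidates <- which(prevalence >= 0.15 & prevalence <= 0.85)
  if (length(candidates) < n_signal_bits) {
    candidates <- which(prevalence >= 0.05 & prevalence <= 0.95)
  }
  if (length(candidates) < n_signal_bits) {
    stop("too little fingerprint diversity for ", n_signal_bits,
         " signal bits", call. = FALSE)
  }
  sel <- sort(sample(candidates, n_signal_bits))
  w <- stats::runif(n_signal_bits, 0.3, 0.8) *
    sample(c(-1, 1), n_signal_bits, replace = TRUE)
  signal <- as.numeric(bits[, sel, drop = FALSE] %*% w)
  records$pxc50 <- intercept + signal + stats::rnorm(n, sd = noise_sd)
  attr(records, "activity_mapping") <- list(bits = sel, weights = w,
                                            intercept = intercept,
                                            noise_sd = noise_sd)
  records
}
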