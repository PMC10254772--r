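# Generative-chemistry evaluation: validity, uniqueness, novelty, fragment
# similarity (Frag), nearest-neighbour similarity (SNN), property
# Wasserstein-1 distances, and the drug-likeness property profile.
# Frag and SNN follow the MOSES reference definitions: BRICS fragment
# frequency vectors compared by cosine, and circular (Morgan) fingerprints
# of radius 2 / 1024 bits compared by Tanimoto.

#' Fraction of valid SMILES
#'
#' @param smiles Non-empty character vector (raw generated strings).
#' @return Fraction in \[0, 1\] whose canonicalization succeeds.
#' @export
validity_fraction <- function(smiles) {
  if (length(smiles) == 0L) stop("empty SMILES list", call. = FALSE)
  mean(is_valid_smiles(smiles))
}

#' Unique fraction among the first k valid molecules
#'
#' Distinct canonical forms among the first `k` entries, divided by `k`.
#'
#' @param valid_smiles Character vector of valid SMILES.
#' @param k Number of leading molecules to consider.
#' @return Fraction in \[0, 1\].
#' @export
unique_at_k <- function(valid_smiles, k) {
  k <- as.integer(k)
  if (length(valid_smiles) < k) {
    stop("need at least k=", k, " molecules, got ", length(valid_smiles),
         call. = FALSE)
  }
  canon <- canonicalize_smiles(valid_smiles[seq_len(k)])
  if (anyNA(canon)) stop("unique_at_k expects valid SMILES", call. = FALSE)
  length(unique(canon)) / k
}

#' Novelty: fraction of generated molecules absent from the training set
#'
#' Computed over distinct canonical forms of the generated set, against the
#' canonicalized training set.
#'
#' @param generated_valid Character vector of valid generated SMILES.
#' @param training_set Character vector of training SMILES.
#' @return Fraction in \[0, 1\].
#' @export
novelty <- function(generated_valid, training_set) {
  if (length(generated_valid) == 0L || length(training_set) == 0L) {
    stop("novelty needs non-empty generated and training sets", call. = FALSE)
  }
  gen <- unique(canonicalize_smiles(generated_valid))
  gen <- gen[!is.na(gen)]
  if (length(gen) == 0L) stop("no valid generated molecules", call. = FALSE)
  train <- unique(canonicalize_smiles(training_set))
  mean(!(gen %in% train))
}

brics_fragment_counts <- function(smiles) {
  canon <- canonicalize_smiles(smiles)
  canon <- canon[!is.na(canon)]
  res <- chem_call("brics", list(smiles = as.list(canon)))
  frags <- unlist(lapply(res$fragments, unlist))
  if (length(frags) == 0L) return(integer(0))
  table(frags)
}

#' Fragment similarity (Frag) between two molecule sets
#'
#' Cosine similarity between the BRICS fragment-frequency vectors of the
#' two sets. If either set yields no fragments, the similarity is defined
#' as 0 (with a warning).
#'
#' @param gen_set,ref_set Character vectors of valid SMILES.
#' @return Real in \[0, 1\].
#' @export
fragment_similarity <- function(gen_set, ref_set) {
  if (length(gen_set) == 0L || length(ref_set) == 0L) {
    stop("fragment_similarity needs two non-empty sets", call. = FALSE)
  }
  a <- brics_fragment_counts(gen_set)
  b <- brics_fragment_counts(ref_set)
  if (length(a) == 0L || length(b) == 0L) {
    warning("a set contains no fragmentable molecule; Frag defined as 0")
    return(0)
  }
  keys <- union(names(a), names(b))
  va <- as.numeric(a[keys])
  vb <- as.numeric(b[keys])
  va[is.na(va)] <- 0
  vb[is.na(vb)] <- 0
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

morgan_bit_matrix <- function(smiles, radius, n_bits) {
  res <- chem_call("morgan", list(smiles = as.list(smiles), radius = radius,
                                  n_bits = n_bits, use_features = FALSE))
  i <- integer(0)
  j <- integer(0)
  for (k in seq_along(res$bits)) {
    on <- unlist(res$bits[[k]])
    if (is.null(on)) stop("invalid SMILES at position ", k, call. = FALSE)
    i <- c(i, rep.int(k, length(on)))
    j <- c(j, as.integer(on) + 1L)
  }
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(res$bits), n_bits))
}

#' Similarity to the nearest neighbour (SNN)
#'
#' Mean over generated molecules of the maximum Tanimoto similarity
#' (circular fingerprints, radius 2, 1024 bits by default — the MOSES
#' reference parameters) to any reference molecule.
#'
#' @param gen_set,ref_set Character vectors of valid SMILES.
#' @param radius,n_bits Fingerprint parameters.
#' @return Real in \[0, 1\].
#' @export
snn <- function(gen_set, ref_set, radius = 2L, n_bits = 1024L) {
  if (length(gen_set) == 0L || length(ref_set) == 0L) {
    stop("snn needs two non-empty sets", call. = FALSE)
  }
  g <- morgan_bit_matrix(gen_set, radius, n_bits)
  r <- morgan_bit_matrix(ref_set, radius, n_bits)
  gsum <- Matrix::rowSums(g)
  rsum <- Matrix::rowSums(r)
  best <- numeric(nrow(g))
  chunk <- 512L
  for (s in seq(1L, nrow(g), by = chunk)) {
    rows <- s:min(s + chunk - 1L, nrow(g))
    inter <- as.matrix(Matrix::tcrossprod(g[rows, , drop = FALSE], r))
    uni <- outer(gsum[rows], rsum, `+`) - inter
    tan <- inter / uni
    tan[uni == 0] <- 0  # two empty fingerprints: define similarity 0
    best[rows] <- apply(tan, 1L, max)
  }
  mean(best)
}

#' Empirical Wasserstein-1 distance between two samples
#'
#' The area between the two empirical CDFs (for equal sizes this equals the
#' mean absolute difference of the sorted samples — the optimal 1-D
#' matching).
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return Non-negative real.
#' @export
wasserstein1 <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    stop("wasserstein1 needs two non-empty samples", call. = FALSE)
  }
  grid <- sort(unique(c(sample_a, sample_b)))
  if (length(grid) == 1L) return(0)
  fa <- stats::ecdf(sample_a)(grid)
  fb <- stats::ecdf(sample_b)(grid)
  k <- length(grid)
  sum(abs(fa[-k] - fb[-k]) * diff(grid))
}

#' Physico-chemical properties of a molecule set
#'
#' Per molecule: molecular weight (MW), topological polar surface area
#' (TPSA), Crippen LogP, hydrogen-bond donors/acceptors (HBD/HBA),
#' quantitative estimate of drug-likeness (QED), and synthetic
#' accessibility score (SA).
#'
#' @param smiles Character vector of valid SMILES (caller pre-filters).
#' @return data.frame with one row per molecule.
#' @export
molecular_properties <- function(smiles) {
  if (length(smiles) == 0L) stop("empty SMILES list", call. = FALSE)
  res <- chem_call("props", list(smiles = as.list(smiles)))
  num <- function(v) vapply(v, function(x) if (is.null(x)) NA_real_
                            else as.numeric(x), numeric(1))
  df <- data.frame(smiles = smiles, mw = num(res$mw), tpsa = num(res$tpsa),
                   logp = num(res$logp), hbd = num(res$hbd),
                   hba = num(res$hba), qed = num(res$qed), sa = num(res$sa),
                   stringsAsFactors = FALSE)
  if (anyNA(df$mw)) {
    stop("invalid SMILES in property input at position ",
         which(is.na(df$mw))[1], call. = FALSE)
  }
  df
}

# "good" drug-likeness ranges (NA bound = unbounded)
default_property_ranges <- function() {
  data.frame(
    property = c("mw", "tpsa", "logp", "hbd", "hba", "qed", "sa"),
    lo = c(200, 20, -1, NA, NA, 0.4, NA),
    hi = c(500, 130, 6, 5, 10, NA, 5),
    stringsAsFactors = FALSE)
}

#' Drug-likeness property profile of a molecule set
#'
#' Computes the seven standard properties per molecule, their min/max over
#' the set, and the percentage of molecules inside each "good"
#' drug-likeness range (MW 200-500, TPSA 20-130, LogP -1-6, HBD <= 5,
#' HBA <= 10, QED >= 0.4, SA <= 5).
#'
#' @param smiles Character vector of valid SMILES.
#' @param ranges Optional data.frame (property, lo, hi) overriding the
#'   default ranges; `NA` means unbounded on that side.
#' @return List with `table` (per-molecule properties), `summary`
#'   (min/max per property), `in_range` (named percentages, 0-100).
#' @export
property_profile <- function(smiles, ranges = default_property_ranges()) {
  tab <- molecular_properties(smiles)
  vals <- tab[, ranges$property, drop = FALSE]
  summary <- data.frame(property = ranges$property,
                        min = vapply(vals, min, numeric(1)),
                        max = vapply(vals, max, numeric(1)),
                        row.names = NULL, stringsAsFactors = FALSE)
  in_range <- vapply(seq_len(nrow(ranges)), function(i) {
    v <- vals[[ranges$property[i]]]
    ok <- rep(TRUE, length(v))
    if (!is.na(ranges$lo[i])) ok <- ok & v >= ranges$lo[i]
    if (!is.na(ranges$hi[i])) ok <- ok & v <= ranges$hi[i]
    100 * mean(ok)
  }, numeric(1))
  names(in_range) <- ranges$property
  list(table = tab, summary = summary, in_range = in_range)
}

#' Evaluate a generated molecule set
#'
#' Assembles the full metric report for one generation batch against
#' reference sets: validity over the raw strings, then — over valid
#' molecules only — Unique@k, novelty against the training set, Frag/SNN
#' against each provided reference split, and property Wasserstein-1
#' distances (MW, LogP, QED, SA) against the test split.
#'
#' @param generated A `condsmiles_generation` or character vector of raw
#'   generated SMILES.
#' @param ref_test Reference (test-split) SMILES, or `NULL`.
#' @param ref_test_sf Optional scaffold-split reference SMILES.
#' @param training_set Optional training SMILES (enables novelty).
#' @param k_unique Integer vector of k values for Unique@k.
#' @return A `condsmiles_metrics` list; entries that cannot be computed are
#'   `NA` with an explanatory string in `$flags`.
#' @export
evaluate_generation <- function(generated, ref_test = NULL,
                                ref_test_sf = NULL, training_set = NULL,
                                k_unique = c(1000L, 10000L)) {
  raw <- if (inherits(generated, "condsmiles_generation")) {
    generated$raw_smiles
  } else {
    generated
  }
  if (length(raw) == 0L) stop("empty generated set", call. = FALSE)
  canon <- canonicalize_smiles(raw)
  valid <- canon[!is.na(canon)]
  flags <- character(0)
  rep_out <- list(n = length(raw), valid = mean(!is.na(canon)),
                  unique_at_k = stats::setNames(rep(NA_real_,
                                                    length(k_unique)),
                                                paste0("unique_at_",
                                                       k_unique)),
                  novelty = NA_real_,
                  frag_test = NA_real_, frag_test_sf = NA_real_,
                  snn_test = NA_real_, snn_test_sf = NA_real_,
                  w1_by_property = NULL, property_profile = NULL)
  if (length(valid) == 0L) {
    rep_out$flags <- "no valid molecules: all other metrics undefined"
    return(structure(rep_out, class = "condsmiles_metrics"))
  }
  for (i in seq_along(k_unique)) {
    k <- k_unique[i]
    if (length(valid) >= k) {
      rep_out$unique_at_k[i] <- unique_at_k(valid, k)
    } else {
      flags <- c(flags, sprintf("unique_at_%d skipped: only %d valid", k,
                                length(valid)))
    }
  }
  if (!is.null(training_set)) {
    rep_out$novelty <- novelty(valid, training_set)
  } else {
    flags <- c(flags, "novelty skipped: no training set supplied")
  }
  if (!is.null(ref_test)) {
    ref_valid <- ref_test[is_valid_smiles(ref_test)]
    rep_out$frag_test <- fragment_similarity(valid, ref_valid)
    rep_out$snn_test <- snn(valid, ref_valid)
    pg <- molecular_properties(unique(valid))
    pr <- molecular_properties(unique(ref_valid))
    rep_out$w1_by_property <- c(
      mw = wasserstein1(pg$mw, pr$mw),
      logp = wasserstein1(pg$logp, pr$logp),
      qed = wasserstein1(pg$qed, pr$qed),
      sa = wasserstein1(pg$sa, pr$sa))
    rep_out$property_profile <- property_profile(unique(valid))[c("summary",
                                                                  "in_range")]
  } else {
    flags <- c(flags, "Frag/SNN/W1 skipped: no test reference supplied")
  }
  if (!is.null(ref_test_sf)) {
    sf_valid <- ref_test_sf[is_valid_smiles(ref_test_sf)]
    rep_out$frag_test_sf <- fragment_similarity(valid, sf_valid)
    rep_out$snn_test_sf <- snn(valid, sf_valid)
  }
  rep_out$flags <- flags
  structure(rep_out, class = "condsmiles_metrics")
}

#' @export
print.condsmiles_metrics <- function(x, ...) {
  cat("<condsmiles_metrics>\n")
  cat(sprintf("  valid: %.3f (n=%d)\n", x$valid, x$n))
  for (nm in names(x$unique_at_k)) {
    if (!is.na(x$unique_at_k[nm])) {
      cat(sprintf("  %s: %.3f\n", nm, x$unique_at_k[nm]))
    }
  }
  if (!is.na(x$novelty)) cat(sprintf("  novelty: %.3f\n", x$novelty))
  if (!is.na(x$frag_test)) cat(sprintf("  Frag(test): %.3f\n", x$frag_test))
  if (!is.na(x$snn_test)) cat(sprintf("  SNN(test): %.3f\n", x$snn_test))
  if (!is.null(x$w1_by_property)) {
    cat("  W1:", paste(sprintf("%s=%.3f", names(x$w1_by_property),
                               x$w1_by_property), collapse = " "), "\n")
  }
  for (f in x$flags) cat("  note:", f, "\n")
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param report A `condsmiles_metrics`.
#' @param path Output path.
#' @export
write_metrics_report <- function(report, path) {
  obj <- unclass(report)
  obj$property_profile <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}
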