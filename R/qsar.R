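# QSAR activity model: 2533-feature molecular representation (2048-bit
# FCFP6-style fingerprint + 166 MACCS keys + a fixed-width physico-chemical
# descriptor block) and a gradient-boosted regression of pXC50, with
# held-out Pearson/RMSE and top-k ranking of generated libraries.
#
# The descriptor block is the alphabetized RDKit descriptor list
# zero-padded to 319 slots so the total feature width is exactly 2533; the
# actual descriptor names are recorded in the fitted bundle.

QSAR_N_DESC_SLOTS <- 319L

#' Featurize molecules for the QSAR model
#'
#' Per molecule: 2048 hashed circular-fingerprint bits (radius 3,
#' feature-based invariants — FCFP6), 166 MACCS structural-key bits, and
#' the descriptor block. Input SMILES are canonicalized first, so two
#' spellings of the same molecule map to an identical vector; descriptor
#' NaN/Inf values are imputed to 0.
#'
#' @param smiles Character vector of valid SMILES.
#' @param n_desc_slots Width of the descriptor block (default 319).
#' @return n x (2214 + n_desc_slots) numeric matrix with attribute
#'   `desc_names`.
#' @export
featurize <- function(smiles, n_desc_slots = QSAR_N_DESC_SLOTS) {
  if (length(smiles) == 0L) {
    return(matrix(numeric(0), 0L, 2048L + 166L + n_desc_slots))
  }
  canon <- canonicalize_smiles(smiles)
  if (anyNA(canon)) {
    stop("invalid SMILES at position ", which(is.na(canon))[1], ": '",
         smiles[which(is.na(canon))[1]], "'", call. = FALSE)
  }
  out_csv <- tempfile(fileext = ".csv")
  on.exit(unlink(out_csv), add = TRUE)
  res <- chem_call("featurize", list(smiles = as.list(canon),
                                     out_csv = out_csv,
                                     n_desc_slots = n_desc_slots))
  if (length(res$bad_rows) > 0L) {
    stop("invalid SMILES at position ", res$bad_rows[[1]] + 1L,
         call. = FALSE)
  }
  x <- as.matrix(data.table::fread(out_csv, header = FALSE))
  dimnames(x) <- NULL
  if (isTRUE(res$n_imputed > 0)) {
    warning(res$n_imputed, " non-finite descriptor values imputed to 0")
  }
  attr(x, "desc_names") <- unlist(res$desc_names)
  x
}

#' Train a QSAR activity model
#'
#' Fits a gradient-boosted regression-tree model (histogram GBDT,
#' LightGBM-style, with early stopping on an internal validation fold) of
#' pXC50 on the 2533 molecular features, using a seeded random train/test
#' split, and records held-out Pearson correlation and RMSE.
#'
#' @param records [molecule_records()] data.frame with `pxc50` set
#'   (>= 50 rows required).
#' @param split_seed Seed for the train/test split and the fit.
#' @param test_fraction Held-out fraction (default 0.2).
#' @param max_iter Maximum boosting rounds.
#' @return A `condsmiles_qsar` bundle: fitted model reference,
#'   featurization spec, `test_pearson` (`NA` with a flag when the held-out
#'   activities are degenerate), `test_rmse`, split sizes and seed.
#' @export
train_qsar <- function(records, split_seed = 1L, test_fraction = 0.2,
                       max_iter = 300L) {
  ok <- !is.na(records$pxc50)
  if (sum(ok) < 50L) {
    stop("need at least 50 records with pxc50, got ", sum(ok), call. = FALSE)
  }
  records <- records[ok, , drop = FALSE]
  n <- nrow(records)
  set.seed(as.integer(split_seed))
  test_ids <- sample.int(n, max(1L, round(test_fraction * n)))
  train_ids <- setdiff(seq_len(n), test_ids)
  x <- featurize(records$smiles)
  y <- records$pxc50
  model_path <- tempfile(pattern = "condsmiles-qsar-", fileext = ".joblib")
  x_csv <- tempfile(fileext = ".csv")
  on.exit(unlink(x_csv), add = TRUE)
  data.table::fwrite(data.table::as.data.table(x[train_ids, , drop = FALSE]),
                     x_csv, col.names = FALSE)
  fit <- chem_call("qsar_fit", list(
    x_csv = x_csv, y = as.list(y[train_ids]), model_path = model_path,
    seed = as.integer(split_seed), max_iter = as.integer(max_iter)))
  pred_train <- as.numeric(unlist(fit$pred_train))
  xt_csv <- tempfile(fileext = ".csv")
  on.exit(unlink(xt_csv), add = TRUE)
  data.table::fwrite(data.table::as.data.table(x[test_ids, , drop = FALSE]),
                     xt_csv, col.names = FALSE)
  pred_test <- as.numeric(unlist(
    chem_call("qsar_predict",
              list(x_csv = xt_csv, model_path = model_path))$pred))
  y_test <- y[test_ids]
  flags <- character(0)
  pearson <- NA_real_
  if (stats::sd(y_test) > 0 && stats::sd(pred_test) > 0) {
    pearson <- stats::cor(y_test, pred_test)
  } else {
    flags <- "degenerate held-out activities: Pearson undefined"
  }
  structure(list(
    model_path = model_path,
    feature_spec = list(n_features = ncol(x),
                        n_desc_slots = QSAR_N_DESC_SLOTS,
                        desc_names = attr(x, "desc_names")),
    n_iter = fit$n_iter,
    test_pearson = pearson,
    test_rmse = sqrt(mean((pred_test - y_test)^2)),
    train_rmse = sqrt(mean((pred_train - y[train_ids])^2)),
    split_seed = as.integer(split_seed),
    n_train = length(train_ids), n_test = length(test_ids),
    flags = flags), class = "condsmiles_qsar")
}

#' @export
print.condsmiles_qsar <- function(x, ...) {
  cat(sprintf(
    "<condsmiles_qsar> %d features, %d/%d train/test, R=%.3f, RMSE=%.3f\n",
    x$feature_spec$n_features, x$n_train, x$n_test,
    x$test_pearson, x$test_rmse))
  for (f in x$flags) cat("  note:", f, "\n")
  invisible(x)
}

#' Predict pXC50 for a list of molecules
#'
#' @param bundle A `condsmiles_qsar` from [train_qsar()].
#' @param smiles_list Character vector of valid SMILES (an invalid entry is
#'   an error naming its index).
#' @return Numeric vector of predictions, order-preserving.
#' @export
predict_activity <- function(bundle, smiles_list) {
  stopifnot(inherits(bundle, "condsmiles_qsar"))
  if (length(smiles_list) == 0L) return(numeric(0))
  if (!file.exists(bundle$model_path)) {
    stop("QSAR model file no longer exists (bundles are session-scoped): ",
         bundle$model_path, call. = FALSE)
  }
  x <- featurize(smiles_list)
  x_csv <- tempfile(fileext = ".csv")
  on.exit(unlink(x_csv), add = TRUE)
  data.table::fwrite(data.table::as.data.table(x), x_csv, col.names = FALSE)
  as.numeric(unlist(chem_call(
    "qsar_predict", list(x_csv = x_csv,
                         model_path = bundle$model_path))$pred))
}

#' Save / load a QSAR bundle
#'
#' The fitted boosted-tree model lives in a side file; saving copies it
#' next to the RDS (`<path>.model`) so a bundle survives across sessions.
#'
#' @param bundle A `condsmiles_qsar`.
#' @param path Bundle path (`.rds`).
#' @return `load_qsar_bundle()` returns the bundle; `save_qsar_bundle()`
#'   the path, invisibly.
#' @export
save_qsar_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "condsmiles_qsar"))
  model_file <- paste0(path, ".model")
  if (!file.copy(bundle$model_path, model_file, overwrite = TRUE)) {
    stop("cannot copy model file ", bundle$model_path, call. = FALSE)
  }
  bundle$model_path <- basename(model_file)
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_qsar_bundle
#' @export
load_qsar_bundle <- function(path) {
  bundle <- readRDS(path)
  stopifnot(inherits(bundle, "condsmiles_qsar"))
  bundle$model_path <- file.path(dirname(path), bundle$model_path)
  if (!file.exists(bundle$model_path)) {
    stop("missing model side file ", bundle$model_path, call. = FALSE)
  }
  bundle
}

#' Rank molecules by predicted activity and keep the top k
#'
#' Descending by prediction; ties broken by canonical-SMILES lexicographic
#' order so the ranking is deterministic.
#'
#' @param smiles_list Character vector.
#' @param predictions Aligned numeric vector.
#' @param k Number to keep (<= length).
#' @return data.frame (smiles, canonical, predicted_pxc50, rank).
#' @export
select_top_k <- function(smiles_list, predictions, k) {
  stopifnot(length(smiles_list) == length(predictions))
  k <- as.integer(k)
  if (k > length(smiles_list)) {
    stop("k=", k, " exceeds list length ", length(smiles_list),
         call. = FALSE)
  }
  canon <- canonicalize_smiles(smiles_list)
  ord <- order(-predictions, canon, method = "radix")
  sel <- ord[seq_len(k)]
  data.frame(smiles = smiles_list[sel], canonical = canon[sel],
             predicted_pxc50 = predictions[sel], rank = seq_len(k),
             stringsAsFactors = FALSE)
}
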