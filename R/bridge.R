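# Batched subprocess bridge to RDKit / scikit-learn.
#
# All chemistry (SMILES parsing, canonicalization, fingerprints, descriptors,
# BRICS fragments, substructure search) and the boosted-tree QSAR fit are
# delegated to the Python toolchain; everything model-related is native R.
# Calls are batched: one python process per request, JSON in/out, matrices
# as CSV side files.

the_bridge <- new.env(parent = emptyenv())

#' Locate the Python interpreter used for chemistry operations
#'
#' The interpreter is resolved from, in order: the option
#' `condsmiles.python`, the environment variable `CONDSMILES_PYTHON`, and
#' `python` on the PATH. It must provide `rdkit`; `scikit-learn` and
#' `joblib` are additionally required for QSAR fitting.
#'
#' @return Path to the interpreter (character scalar).
#' @export
chem_python <- function() {
  py <- getOption("condsmiles.python",
                  Sys.getenv("CONDSMILES_PYTHON", unset = ""))
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) {
    stop("no python interpreter found; set options(condsmiles.python=) or ",
         "CONDSMILES_PYTHON, or put 'python' on the PATH", call. = FALSE)
  }
  py
}

chem_script <- function() {
  path <- system.file("python", "chem_ops.py", package = "condsmiles")
  if (!nzchar(path) || !file.exists(path)) {
    # during in-source development (pkgload), inst/ is mapped directly
    path <- system.file("inst", "python", "chem_ops.py", package = "condsmiles")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("cannot locate bundled chem_ops.py", call. = FALSE)
  }
  path
}

#' Run one batched chemistry operation through the Python bridge
#'
#' Low-level plumbing; the exported chemistry helpers
#' ([canonicalize_smiles()], [featurize()], ...) call this.
#'
#' @param op Operation name understood by `chem_ops.py`.
#' @param req Named list, serialized to the JSON request.
#' @return Parsed JSON reply (list).
#' @keywords internal
chem_call <- function(op, req) {
  in_path <- tempfile(fileext = ".json")
  out_path <- tempfile(fileext = ".json")
  err_path <- tempfile(fileext = ".log")
  on.exit(unlink(c(in_path, out_path, err_path)), add = TRUE)
  jsonlite::write_json(req, in_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- suppressWarnings(system2(
    chem_python(), c(shQuote(chem_script()), op, shQuote(in_path),
                     shQuote(out_path)),
    stdout = err_path, stderr = err_path))
  if (!identical(status, 0L) || !file.exists(out_path)) {
    msg <- tryCatch(paste(readLines(err_path, warn = FALSE), collapse = "\n"),
                    error = function(e) "")
    stop("chemistry bridge call '", op, "' failed (exit ", status, "):\n",
         msg, call. = FALSE)
  }
  jsonlite::read_json(out_path, simplifyVector = FALSE)
}

# session-level canonical-SMILES memo so repeated metric calls do not
# re-spawn python for molecules already seen
canon_cache_get <- function(smiles) {
  if (is.null(the_bridge$canon)) the_bridge$canon <- new.env(parent = emptyenv())
  vapply(smiles, function(s) {
    if (!nzchar(s)) return("\r<invalid>")  # empty string: never a molecule
    v <- the_bridge$canon[[s]]
    if (is.null(v)) NA_character_ else v
  }, character(1), USE.NAMES = FALSE)
}

canon_cache_put <- function(smiles, canonical) {
  for (i in seq_along(smiles)) {
    if (!nzchar(smiles[i])) next
    # NA (invalid) is cached too, as the string "\r<invalid>"
    the_bridge$canon[[smiles[i]]] <-
      if (is.na(canonical[i])) "\r<invalid>" else canonical[i]
  }
  invisible(NULL)
}
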