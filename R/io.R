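# Molecule table I/O and canonicalization.

#' Canonicalize SMILES strings
#'
#' Returns the RDKit-canonical SMILES for each parseable input and
#' `NA_character_` (the invalid marker) for unparseable input; never raises
#' on chemical invalidity — invalidity is data, not an exception. Results
#' are memoized for the session, and duplicates are sent to the chemistry
#' bridge only once.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, `NA` where invalid.
#' @examples
#' \dontrun{canonicalize_smiles(c("OCC", "CCO", "C("))}
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  out <- canon_cache_get(smiles)
  todo <- unique(smiles[is.na(out)])
  if (length(todo) > 0L) {
    res <- chem_call("canonicalize", list(smiles = as.list(todo)))
    canon <- vapply(res$canonical,
                    function(v) if (is.null(v)) NA_character_ else v,
                    character(1))
    canon_cache_put(todo, canon)
    out <- canon_cache_get(smiles)
  }
  out[out == "\r<invalid>"] <- NA_character_
  out
}

#' Test SMILES validity
#'
#' A SMILES is valid iff the chemistry toolkit parses it into a molecule.
#'
#' @param smiles Character vector.
#' @return Logical vector.
#' @export
is_valid_smiles <- function(smiles) !is.na(canonicalize_smiles(smiles))

#' Read a molecule table from .smi or CSV
#'
#' `.smi` files hold one SMILES per line (an optional whitespace-separated
#' name is ignored). CSV files need a header with at least a `smiles`
#' column; `target_id` and `pxc50` columns are carried through when present.
#' Row order is preserved; blank lines are dropped.
#'
#' @param path File path.
#' @param format `"smi"` or `"csv"`; default guesses from the extension.
#' @return A data.frame with columns `smiles`, `target_id` (character or
#'   `NA`), `pxc50` (numeric or `NA`).
#' @export
read_molecule_table <- function(path, format = c("auto", "smi", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "smi"
  }
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    smiles <- vapply(strsplit(lines, "[ \t]+"), `[[`, character(1), 1L)
    return(molecule_records(smiles))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"smiles" %in% names(df)) {
    stop("CSV '", path, "' lacks required column 'smiles'", call. = FALSE)
  }
  molecule_records(
    smiles = as.character(df$smiles),
    target_id = if ("target_id" %in% names(df)) as.character(df$target_id),
    pxc50 = if ("pxc50" %in% names(df)) as.numeric(df$pxc50))
}

#' Construct a molecule-record table
#'
#' The in-memory form of a labeled SMILES set: one row per molecule with
#' optional condition label (`target_id`) and log-activity (`pxc50`).
#'
#' @param smiles Character vector.
#' @param target_id Optional character vector of condition labels.
#' @param pxc50 Optional numeric vector of activities.
#' @param canonical Optional pre-computed canonical SMILES.
#' @return data.frame with class `condsmiles_records`.
#' @export
molecule_records <- function(smiles, target_id = NULL, pxc50 = NULL,
                             canonical = NULL) {
  n <- length(smiles)
  df <- data.frame(
    smiles = as.character(smiles),
    target_id = if (is.null(target_id)) rep(NA_character_, n)
                else as.character(target_id),
    pxc50 = if (is.null(pxc50)) rep(NA_real_, n) else as.numeric(pxc50),
    stringsAsFactors = FALSE)
  if (!is.null(canonical)) df$canonical <- as.character(canonical)
  class(df) <- c("condsmiles_records", "data.frame")
  df
}

#' Write a molecule table
#'
#' @param records data.frame with a `smiles` column (and optionally
#'   `target_id`, `pxc50`), or a character vector of SMILES.
#' @param path Output path; `.smi` writes one SMILES per line, `.csv`
#'   writes a header CSV.
#' @return `path`, invisibly.
#' @export
write_molecule_table <- function(records, path) {
  if (is.character(records)) records <- molecule_records(records)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    cols <- intersect(c("smiles", "target_id", "pxc50"), names(records))
    cols <- cols[cols == "smiles" |
                   vapply(records[cols], function(v) any(!is.na(v)),
                          logical(1))]
    keep <- records[, cols, drop = FALSE]
    utils::write.csv(keep, path, row.names = FALSE, quote = FALSE)
  } else {
    writeLines(records$smiles, path)
  }
  invisible(path)
}
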