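# SMILES tokenization and vocabulary management.
#
# The tokenizer is regex-based and reversible: bracket atoms ([nH], [O-],
# [C@@H], ...), two-letter elements Cl/Br, and %NN ring closures are single
# tokens; everything else is one character. Special tokens frame model
# input: PAD=0, BOS=1, EOS=2 (fixed indices, so padding masks are
# index-testable).

PAD_TOKEN <- "<pad>"
BOS_TOKEN <- "<bos>"
EOS_TOKEN <- "<eos>"
SPECIAL_TOKENS <- c(PAD_TOKEN, BOS_TOKEN, EOS_TOKEN)

# single-character organic/aromatic atoms, bonds, branches, ring digits,
# stereo marks; multi-character pieces are matched first
.token_regex <- paste0(
  "(\\[[^\\]]+\\]",       # bracket atom
  "|%[0-9]{2}",           # two-digit ring closure
  "|Cl|Br",               # two-letter elements
  "|[BCNOPSFIbcnops]",    # one-letter elements
  "|[0-9]",               # ring-bond digit
  "|[()=#:+\\-/\\\\@.*$~])" # branches, bonds, stereo, charge, wildcards
)

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into the token sequence the language model
#' consumes. The split is exactly reversible: `paste0()` of the tokens
#' reproduces the input.
#'
#' @param smiles Non-empty SMILES string.
#' @return Character vector of tokens (no specials).
#' @examples
#' tokenize_smiles("Clc1ccccc1")
#' @export
tokenize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) stop("cannot tokenize an empty SMILES", call. = FALSE)
  m <- gregexpr(.token_regex, smiles, perl = TRUE)[[1]]
  tokens <- regmatches(smiles, list(m))[[1]]
  if (paste0(tokens, collapse = "") != smiles) {
    # locate the first position not covered by a match
    covered <- rep(FALSE, nchar(smiles))
    for (i in seq_along(m)) {
      covered[m[i]:(m[i] + attr(m, "match.length")[i] - 1L)] <- TRUE
    }
    bad <- which(!covered)[1]
    stop(sprintf("unsupported character '%s' at position %d of \"%s\"",
                 substr(smiles, bad, bad), bad, smiles), call. = FALSE)
  }
  tokens
}

#' Reassemble a SMILES string from tokens
#'
#' Strips any PAD/BOS/EOS tokens and concatenates the rest in order.
#'
#' @param tokens Character vector of tokens.
#' @return SMILES string ("" for an empty sequence).
#' @export
detokenize <- function(tokens) {
  stopifnot(is.character(tokens) || length(tokens) == 0L)
  if (length(tokens) == 0L) return("")
  paste0(tokens[!(tokens %in% SPECIAL_TOKENS)], collapse = "")
}

#' Build a token vocabulary from a SMILES corpus
#'
#' The vocabulary is the union of tokens over the corpus plus the three
#' special tokens at fixed indices PAD=0, BOS=1, EOS=2; corpus tokens follow
#' in lexicographic order, so the mapping is deterministic under corpus
#' shuffling and duplication.
#'
#' @param corpus Non-empty character vector of SMILES strings.
#' @return A `condsmiles_vocab`: named integer vector token -> 0-based index.
#' @export
build_vocabulary <- function(corpus) {
  stopifnot(is.character(corpus))
  if (length(corpus) == 0L) stop("empty corpus", call. = FALSE)
  toks <- sort(unique(unlist(lapply(corpus, tokenize_smiles))))
  toks <- setdiff(toks, SPECIAL_TOKENS)
  ids <- seq_len(length(toks) + 3L) - 1L
  names(ids) <- c(SPECIAL_TOKENS, toks)
  structure(ids, class = "condsmiles_vocab")
}

#' @export
print.condsmiles_vocab <- function(x, ...) {
  cat("<condsmiles_vocab> ", length(x), " tokens: ",
      paste(utils::head(setdiff(names(x), SPECIAL_TOKENS), 12), collapse = " "),
      if (length(x) > 15L) " ..." else "", "\n", sep = "")
  invisible(x)
}

vocab_size <- function(vocab) length(vocab)

#' Encode a SMILES string as model-ready token indices
#'
#' Tokenizes, frames with BOS/EOS, and maps to 0-based vocabulary indices.
#'
#' @param smiles SMILES string.
#' @param vocab Vocabulary from [build_vocabulary()].
#' @return Integer vector of 0-based indices, starting with BOS, ending EOS.
#' @export
encode_smiles <- function(smiles, vocab) {
  tokens <- c(BOS_TOKEN, tokenize_smiles(smiles), EOS_TOKEN)
  idx <- unname(vocab[tokens])
  if (anyNA(idx)) {
    stop("tokens not in vocabulary: ",
         paste(unique(tokens[is.na(idx)]), collapse = " "), call. = FALSE)
  }
  as.integer(idx)
}

#' Decode 0-based token indices back to a SMILES string
#'
#' @param indices Integer vector of 0-based vocabulary indices.
#' @param vocab Vocabulary from [build_vocabulary()].
#' @return SMILES string with specials stripped.
#' @export
decode_indices <- function(indices, vocab) {
  if (length(indices) == 0L) return("")
  if (any(indices < 0L | indices >= length(vocab))) {
    stop("index out of vocabulary range", call. = FALSE)
  }
  detokenize(names(vocab)[indices + 1L])
}

#' Write / read a vocabulary as JSON
#'
#' Serialized as a `{token: index}` object.
#'
#' @param vocab Vocabulary.
#' @param path File path.
#' @return `read_vocabulary()` returns the vocabulary; `write_vocabulary()`
#'   its path, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(as.list(unclass(vocab)), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- as.integer(unlist(x))
  names(ids) <- names(x)
  ids <- sort(ids)
  stopifnot(identical(unname(ids[SPECIAL_TOKENS]), 0:2))
  structure(ids, class = "condsmiles_vocab")
}
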