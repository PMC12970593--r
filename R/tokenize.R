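# Vocabulary: 20 canonical residues, one ambiguity letter (X), one
# classification token prepended to every sequence. Id 0 is reserved for
# out-of-sequence padding inside encoders and never appears in token lists.

#' Amino-acid vocabulary used by the tokenizer
#'
#' @return A named integer vector mapping residue letters to token ids.
#'   Ids 1--20 are the canonical amino acids in alphabetical order, 21 is
#'   the ambiguity letter `X`, and 22 is the classification token that is
#'   prepended to every tokenized sequence.
#' @export
aa_vocabulary <- function() {
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  setNames(seq_len(22L), c(letters20, "X", "<cls>"))
}

.vocab <- aa_vocabulary()
.cls_id <- .vocab[["<cls>"]]
.x_id <- .vocab[["X"]]

#' Tokenize an amino-acid sequence
#'
#' Maps each residue letter to an integer token id and prepends the
#' classification token, so a sequence of `n` residues yields `n + 1`
#' tokens. Letters outside the canonical alphabet map to the ambiguity
#' token. Sequences whose token count would exceed `max_length` are
#' rejected (not truncated) with an excluded-record condition carrying the
#' sequence id, so callers can log and skip them.
#'
#' @param sequence A single amino-acid string.
#' @param max_length Maximum token count including the classification
#'   token (default 1024).
#' @param id Optional sequence id used in error conditions.
#' @return A list with `ids` (integer vector of length `n + 1`) and `n`
#'   (residue count).
#' @export
#' @examples
#' tokenize("ACDE")$ids  # 5 tokens: <cls> + 4 residues
tokenize <- function(sequence, max_length = 1024L, id = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    abort("`sequence` must be a single string.", class = "spinr_invalid_record")
  }
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) {
    abort(
      paste0("Empty sequence", if (!is.null(id)) paste0(" for record '", id, "'"), "."),
      class = "spinr_invalid_record"
    )
  }
  if (n > max_length - 1L) {
    abort(
      sprintf(
        "Sequence%s has %d residues; limit is %d (max_length %d minus the classification token). Over-length sequences are excluded, not truncated.",
        if (!is.null(id)) paste0(" '", id, "'") else "", n, max_length - 1L, max_length
      ),
      class = "spinr_excluded_record",
      id = id %||% NA_character_, n = n
    )
  }
  letters <- strsplit(sequence, "")[[1]]
  ids <- unname(.vocab[letters])
  ids[is.na(ids)] <- .x_id
  list(ids = c(.cls_id, as.integer(ids)), n = n)
}
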