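#' The fixed 21-symbol model alphabet
#'
#' Twenty amino acids in alphabetical one-letter order followed by the gap
#' character \code{"-"}. The symbol order is fixed so that one-hot encodings,
#' checkpoints and argmax decodes are portable: symbol index 1..20 are the
#' amino acids, index 21 is the gap.
#'
#' @format A character vector of length 21.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")

#' @rdname AA_ALPHABET
#' @export
GAP_INDEX <- 21L

# ambiguity / non-standard codes mapped to gap (keeps alphabet arity at 21)
AMBIGUITY_CODES <- c("X", "B", "Z", "J", "U", "O", ".")

.alphabet_lookup <- local({
  lk <- integer(0)
  lk[utf8ToInt("A"):utf8ToInt("z")] <- NA_integer_
  lk
})

#' Convert sequences to integer symbol indices
#'
#' @param seqs character vector of aligned sequences (equal length).
#' @param ambigToGap map ambiguity codes (X, B, Z, J, U, O) to the gap symbol
#'   with a warning instead of erroring.
#' @return integer matrix, one row per sequence, entries in 1..21.
#' @keywords internal
seqToInts <- function(seqs, ambigToGap = TRUE) {
  stopifnot(length(seqs) >= 1L)
  w <- nchar(seqs[1L])
  if (any(nchar(seqs) != w))
    stop("ragged sequence lengths: all aligned sequences must have equal width")
  chars <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE),
                         use.names = FALSE),
                  nrow = length(seqs), ncol = w, byrow = TRUE)
  idx <- match(chars, AA_ALPHABET)
  bad <- is.na(idx)
  if (any(bad)) {
    ambig <- chars[bad] %in% AMBIGUITY_CODES
    if (ambigToGap && all(ambig)) {
      warning(sum(bad), " ambiguity-code residue(s) (",
              paste(unique(chars[bad]), collapse = ","),
              ") mapped to gap")
      idx[bad] <- GAP_INDEX
    } else {
      stop("illegal symbol(s) outside the 21-letter alphabet: ",
           paste(unique(chars[bad][!ambig | !ambigToGap]), collapse = ", "))
    }
  }
  dim(idx) <- dim(chars)
  idx
}

#' @keywords internal
intsToSeq <- function(mat) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
  apply(mat, 1L, function(r) paste(AA_ALPHABET[r], collapse = ""))
}
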