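#' Per-column residue frequency profile of an alignment
#'
#' @param aln a [ProteinMSA-class].
#' @param pseudocount added to every (column, symbol) count before
#'   normalization; default 1/21.
#' @return numeric matrix width x 21 of frequencies, rows summing to 1.
#' @export
columnProfile <- function(aln, pseudocount = 1 / 21) {
  m <- seqToInts(aln@seqs)
  w <- ncol(m)
  counts <- matrix(pseudocount, w, 21L, dimnames = list(NULL, AA_ALPHABET))
  tab <- table(factor(rep(seq_len(w), times = nrow(m)), levels = seq_len(w)),
               factor(as.vector(t(m)), levels = 1:21))
  counts <- counts + unclass(tab)
  counts / rowSums(counts)
}

#' Align an unaligned sequence into MSA coordinates
#'
#' Global dynamic-programming alignment of a plain (ungapped) amino-acid
#' sequence against the alignment's per-column frequency profile: each
#' profile column either receives the next residue (scoring the log column
#' frequency of that residue, with pseudocount) or a gap (a linear gap
#' penalty). Residues are never skipped, so the output has exactly the
#' alignment's width and preserves residue order. This is how external
#' variants (e.g. stability-annotated homologs) are projected into the model's
#' fixed coordinate system.
#'
#' @param aln a [ProteinMSA-class] supplying the profile.
#' @param seq unaligned amino-acid string (length at most the MSA width).
#' @param gapPenalty score for leaving a column empty (default -2, linear).
#' @param pseudocount profile pseudocount (default 1/21).
#' @return aligned string of length \code{alnWidth(aln)}.
#' @export
alignToProfile <- function(aln, seq, gapPenalty = -2, pseudocount = 1 / 21) {
  seq <- toupper(gsub("-", "", seq, fixed = TRUE))
  res <- match(strsplit(seq, "")[[1L]], AA_ALPHABET[1:20])
  if (anyNA(res)) stop("sequence contains non-amino-acid symbols")
  w <- alnWidth(aln)
  m <- length(res)
  if (m > w) stop("sequence longer (", m, ") than the MSA width (", w, ")")
  prof <- columnProfile(aln, pseudocount)
  match_score <- log(prof[, 1:20, drop = FALSE])
  # S[i+1, j+1] = best score aligning first i residues into first j columns
  NEG <- -Inf
  S <- matrix(NEG, m + 1L, w + 1L)
  S[1L, ] <- gapPenalty * (0:w)
  ptr <- matrix(0L, m + 1L, w + 1L)  # 1 = match (diag), 2 = column gap (left)
  for (j in seq_len(w)) {
    sc <- match_score[j, ]
    imax <- min(m, j)
    for (i in seq_len(imax)) {
      diag_ <- S[i, j] + sc[res[i]]
      left_ <- S[i + 1L, j]
      if (!is.finite(left_)) left_ <- NEG else left_ <- left_ + gapPenalty
      if (diag_ >= left_) {
        S[i + 1L, j + 1L] <- diag_; ptr[i + 1L, j + 1L] <- 1L
      } else {
        S[i + 1L, j + 1L] <- left_; ptr[i + 1L, j + 1L] <- 2L
      }
    }
  }
  # traceback from (m, w)
  out <- character(w)
  i <- m; j <- w
  while (j > 0L) {
    if (i > 0L && ptr[i + 1L, j + 1L] == 1L) {
      out[j] <- AA_ALPHABET[res[i]]
      i <- i - 1L
    } else {
      out[j] <- "-"
    }
    j <- j - 1L
  }
  paste(out, collapse = "")
}
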