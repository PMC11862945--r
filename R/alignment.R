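#' Construct a ProteinMSA from identifiers and aligned strings
#'
#' @param ids character vector of unique identifiers.
#' @param seqs character vector of equal-length aligned sequences.
#' @param queryId identifier of the anchor sequence.
#' @return a [ProteinMSA-class] object.
#' @export
proteinMSA <- function(ids, seqs, queryId) {
  new("ProteinMSA", ids = as.character(ids),
      seqs = toupper(as.character(seqs)), queryId = as.character(queryId))
}

#' Read an aligned FASTA file into a ProteinMSA
#'
#' All records must have the same length (it is an alignment, not a sequence
#' set). Ambiguity codes (X, B, Z, J, U, O) are mapped to the gap symbol with
#' a warning when \code{ambigToGap = TRUE}, keeping the alphabet arity at 21
#' as the model architecture requires.
#'
#' @param path aligned FASTA file.
#' @param queryId identifier of the anchor sequence; must be present.
#'   \code{NULL} designates the first record (for auxiliary sets with no
#'   meaningful anchor).
#' @param ambigToGap map ambiguity codes to gap (default) instead of erroring.
#' @return a [ProteinMSA-class].
#' @export
readAlignment <- function(path, queryId = NULL, ambigToGap = TRUE) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  if (length(unique(nchar(seqs))) != 1L)
    stop("ragged record lengths in ", path, ": not an alignment")
  if (is.null(queryId)) queryId <- ids[1L]
  if (!(queryId %in% ids))
    stop("query id '", queryId, "' not found in ", path)
  pat <- sprintf("[^%s-]", paste(AA_ALPHABET[1:20], collapse = ""))
  if (any(grepl(pat, seqs))) {
    if (!ambigToGap) stop("illegal symbols in ", path)
    m <- gregexpr(pat, seqs)
    nbad <- sum(vapply(m, function(x) sum(x > 0L), 0L))
    warning(nbad, " ambiguity/non-standard residue(s) mapped to gap")
    seqs <- vapply(seqs, function(s) gsub(pat, "-", s), "", USE.NAMES = FALSE)
  }
  proteinMSA(ids, seqs, queryId)
}

#' Write a ProteinMSA (or named sequences) as aligned FASTA
#'
#' @param x a [ProteinMSA-class] or a named character vector of sequences.
#' @param path output file.
#' @export
writeAlignment <- function(x, path) {
  if (is(x, "ProteinMSA")) x <- sequences(x)
  Biostrings::writeXStringSet(Biostrings::BStringSet(x), path)
  invisible(path)
}

.gapFraction <- function(seqs) {
  w <- nchar(seqs[1L])
  (w - nchar(gsub("-", "", seqs, fixed = TRUE))) / w
}

#' Remove overly gapped sequences
#'
#' Retains every sequence whose gap fraction is at most
#' \code{maxGapFraction}. The query is always retained regardless of its gap
#' content (it anchors all downstream coordinates). Record order is preserved.
#'
#' @param aln a [ProteinMSA-class].
#' @param maxGapFraction maximum tolerated per-sequence gap fraction in [0,1].
#' @return the filtered [ProteinMSA-class].
#' @export
filterSequences <- function(aln, maxGapFraction = 0.25) {
  stopifnot(maxGapFraction >= 0, maxGapFraction <= 1)
  keep <- .gapFraction(aln@seqs) <= maxGapFraction | aln@ids == aln@queryId
  if (!any(keep)) stop("sequence filtering removed every record")
  aln[which(keep)]
}

#' Remove gap-dominated columns, anchored on the query
#'
#' \code{mode = "query_anchored"} drops a column when the query holds a gap
#' there OR when the column's gap fraction exceeds \code{gapColumnThreshold}.
#' \code{mode = "strict"} is the same rule with a (typically lower) threshold
#' applied even where the query holds a residue, for harsher gap-column
#' removal. The returned column map records which original columns survived,
#' 0-based, and is the single source of coordinate truth for mapping external
#' sequences back to original MSA coordinates.
#'
#' @param aln a [ProteinMSA-class].
#' @param mode \code{"query_anchored"} or \code{"strict"}.
#' @param gapColumnThreshold maximum tolerated column gap fraction; defaults
#'   to 0.5 for query-anchored filtering and 0.2 for strict filtering.
#' @return list with elements \code{alignment} (filtered [ProteinMSA-class])
#'   and \code{columnMap} (0-based original indices of the kept columns,
#'   strictly increasing).
#' @export
filterColumns <- function(aln, mode = c("query_anchored", "strict"),
                          gapColumnThreshold = NULL) {
  mode <- match.arg(mode)
  if (is.null(gapColumnThreshold))
    gapColumnThreshold <- if (mode == "strict") 0.2 else 0.5
  stopifnot(gapColumnThreshold >= 0, gapColumnThreshold <= 1)
  m <- seqToInts(aln@seqs)
  gapFrac <- colMeans(m == GAP_INDEX)
  qrow <- m[match(aln@queryId, aln@ids), ]
  keep <- (qrow != GAP_INDEX) & (gapFrac <= gapColumnThreshold)
  # strict mode keeps the same query-anchored rule; the lower threshold is
  # what removes frequent-gap columns even where the query has a residue
  if (!any(keep)) stop("column filtering removed every column")
  m2 <- m[, keep, drop = FALSE]
  out <- proteinMSA(aln@ids, intsToSeq(m2), aln@queryId)
  list(alignment = out, columnMap = which(keep) - 1L)
}

#' Write / read a column map as TSV
#'
#' Two-column TSV \code{(new_index, original_index)}, both 0-based.
#' @param columnMap integer vector of kept 0-based original column indices.
#' @param path file path.
#' @export
writeColumnMap <- function(columnMap, path) {
  utils::write.table(
    data.frame(new_index = seq_along(columnMap) - 1L,
               original_index = as.integer(columnMap)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeColumnMap
#' @export
readColumnMap <- function(path) {
  df <- utils::read.delim(path)
  as.integer(df$original_index)
}

#' Pairwise identity of two equal-width integer-encoded sequence matrices
#' @keywords internal
.identityMatrix <- function(m) {
  n <- nrow(m)
  out <- matrix(1, n, n)
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) {
    hits <- colMeans(t(m[(i + 1L):n, , drop = FALSE]) == m[i, ])
    out[i, (i + 1L):n] <- hits
    out[(i + 1L):n, i] <- hits
  }
  out
}

#' Reduce redundancy by greedy representative selection
#'
#' Greedy single-linkage representative picking: records are visited in a
#' seed-shuffled order with the query first, and a record is kept iff its
#' identity to every already-kept record is below \code{identityThreshold}.
#' The query is always kept. Output preserves the original record order.
#'
#' @param aln a [ProteinMSA-class].
#' @param identityThreshold fraction in (0, 1]; pairs at or above it are
#'   considered redundant.
#' @param seed integer seed for the visiting order.
#' @return the reduced [ProteinMSA-class].
#' @export
clusterReduce <- function(aln, identityThreshold = 0.9, seed = 1L) {
  stopifnot(identityThreshold > 0, identityThreshold <= 1)
  n <- length(aln@ids)
  m <- seqToInts(aln@seqs)
  idm <- .identityMatrix(m)
  qi <- match(aln@queryId, aln@ids)
  order_idx <- local({
    set.seed(as.integer(seed))
    c(qi, sample(setdiff(seq_len(n), qi)))
  })
  kept <- integer(0)
  for (i in order_idx) {
    if (!length(kept) || all(idm[i, kept] < identityThreshold))
      kept <- c(kept, i)
  }
  aln[sort(kept)]
}

#' One-hot encode an alignment
#'
#' Produces a binary array indexed (sequence, column, symbol) with the fixed
#' symbol order of [AA_ALPHABET] (20 amino acids alphabetical, gap last).
#' Invertible via [decodeOneHot()].
#'
#' @param aln a [ProteinMSA-class].
#' @return 3-d array \code{n x width x 21} with dimnames; exactly one 1 per
#'   (sequence, column).
#' @export
encodeOneHot <- function(aln) {
  m <- seqToInts(aln@seqs)
  n <- nrow(m); w <- ncol(m)
  arr <- array(0L, dim = c(n, w, 21L),
               dimnames = list(aln@ids, NULL, AA_ALPHABET))
  arr[cbind(rep(seq_len(n), w), rep(seq_len(w), each = n), as.vector(m))] <- 1L
  arr
}

#' @rdname encodeOneHot
#' @param onehot array as returned by \code{encodeOneHot} (ties broken toward
#'   the lowest symbol index, matching the decoder's argmax rule).
#' @return \code{decodeOneHot}: character vector of sequences.
#' @export
decodeOneHot <- function(onehot) {
  n <- dim(onehot)[1L]; w <- dim(onehot)[2L]
  idx <- apply(onehot, c(1L, 2L), which.max)
  out <- intsToSeq(matrix(idx, nrow = n))
  stats::setNames(out, dimnames(onehot)[[1L]])
}

#' Flatten a one-hot array for the dense networks
#'
#' Layout: column-major blocks of 21 symbols, i.e. flat index
#' \code{(col-1)*21 + symbol}.
#' @keywords internal
.flattenOneHot <- function(onehot) {
  n <- dim(onehot)[1L]; w <- dim(onehot)[2L]
  out <- matrix(aperm(onehot, c(1L, 3L, 2L)), nrow = n)
  rownames(out) <- dimnames(onehot)[[1L]]
  out
}

#' One-hot matrix (n x width*21) straight from sequences
#' @keywords internal
.seqsToX <- function(seqs) {
  m <- seqToInts(seqs)
  n <- nrow(m); w <- ncol(m)
  x <- matrix(0, n, w * 21L)
  x[cbind(rep(seq_len(n), w),
          (rep(seq_len(w), each = n) - 1L) * 21L + as.vector(m))] <- 1
  rownames(x) <- names(seqs)
  x
}

#' Split off a held-out positive-control set
#'
#' Uniformly samples \code{round(fraction * n)} sequences (never the query)
#' into a positive control set excluded from training; the remainder is the
#' training alignment. The two parts are disjoint and their union is the
#' input.
#'
#' @param aln a [ProteinMSA-class].
#' @param fraction held-out fraction, default 0.05 (5 percent).
#' @param seed integer seed.
#' @return list with [ProteinMSA-class] elements \code{train} and
#'   \code{positive}.
#' @export
holdoutSplit <- function(aln, fraction = 0.05, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  n <- length(aln@ids)
  k <- round(fraction * n)
  if (k < 1L || k >= n)
    stop("alignment too small for a non-empty ", fraction, " hold-out split")
  qi <- match(aln@queryId, aln@ids)
  set.seed(as.integer(seed))
  pos <- sample(setdiff(seq_len(n), qi), k)
  pos <- sort(pos)
  positive <- new("ProteinMSA", ids = aln@ids[pos], seqs = aln@seqs[pos],
                  queryId = aln@ids[pos][1L])   # no anchor in the hold-out
  list(train = aln[sort(setdiff(seq_len(n), pos))], positive = positive)
}

#' Write split membership as TSV (id, set)
#' @param split list as returned by [holdoutSplit()].
#' @param path file path.
#' @export
writeSplit <- function(split, path) {
  df <- rbind(data.frame(id = split$train@ids, set = "train"),
              data.frame(id = split$positive@ids, set = "positive"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
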