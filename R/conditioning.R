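SOLUBILITY_TAGS <- c("LOW", "MEDIUM", "HIGH")

#' Read a per-sequence solubility score table
#'
#' Two-column TSV (id, score). Scores are externally predicted (e.g. by a
#' solubility predictor); this package treats them purely as an input
#' attribute to discretize.
#'
#' @param path TSV file with a header line \code{id<TAB>score}.
#' @return named numeric vector of scores.
#' @export
readScores <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "character"))
  if (ncol(df) < 2L) stop("expected a two-column (id, score) TSV")
  sc <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(sc))
    stop("non-numeric score(s) for id(s): ",
         paste(df[[1L]][is.na(sc)], collapse = ", "))
  if (anyDuplicated(df[[1L]]))
    stop("duplicate id(s): ",
         paste(unique(df[[1L]][duplicated(df[[1L]])]), collapse = ", "))
  stats::setNames(sc, df[[1L]])
}

#' Discretize scores into balanced LOW/MEDIUM/HIGH tags
#'
#' Equal-mass (quantile) binning: ids are sorted by score (ties broken by
#' identifier for determinism) and split into \code{nBins} contiguous groups
#' whose sizes differ by at most one (the remainder goes to the lowest bins
#' first). The lowest group is LOW, the highest HIGH. Balanced bins ensure
#' balanced sample extraction during conditional training.
#'
#' @param scores named numeric vector (id -> score).
#' @param nBins number of bins; default (and the supported conditioning
#'   arity) is 3.
#' @return object of class \code{"solubilityTags"}: list with \code{tags}
#'   (named character vector), \code{binEdges} (boundary scores between
#'   consecutive bins), and \code{scores}.
#' @export
binScores <- function(scores, nBins = 3L) {
  if (length(scores) < nBins)
    stop("need at least ", nBins, " scored ids to form ", nBins, " bins")
  ord <- order(scores, names(scores))
  ids <- names(scores)[ord]
  n <- length(ids)
  base <- n %/% nBins
  extra <- n %% nBins
  sizes <- rep(base, nBins) + c(rep(1L, extra), rep(0L, nBins - extra))
  labs <- if (nBins == 3L) SOLUBILITY_TAGS else paste0("BIN", seq_len(nBins))
  tags <- stats::setNames(rep(labs, times = sizes), ids)
  cuts <- cumsum(sizes)[-nBins]
  edges <- (scores[ids][cuts] + scores[ids][cuts + 1L]) / 2
  structure(list(tags = tags[names(scores)], binEdges = unname(edges),
                 scores = scores),
            class = "solubilityTags")
}

#' @export
print.solubilityTags <- function(x, ...) {
  cat("solubilityTags:", length(x$tags), "ids;",
      paste(names(table(x$tags)), table(x$tags), collapse = ", "), "\n")
  invisible(x)
}

#' Tag indices aligned to an alignment's record order
#'
#' @param tags a \code{"solubilityTags"} object (or named character vector of
#'   tag names).
#' @param aln a [ProteinMSA-class]; every record must be tagged.
#' @return integer vector of 0-based tag indices (LOW = 0, MEDIUM = 1,
#'   HIGH = 2) in alignment row order.
#' @export
tagsForTraining <- function(tags, aln) {
  tg <- if (inherits(tags, "solubilityTags")) tags$tags else tags
  missing <- setdiff(aln@ids, names(tg))
  if (length(missing))
    stop("untagged alignment id(s): ", paste(missing, collapse = ", "))
  idx <- match(tg[aln@ids], SOLUBILITY_TAGS) - 1L
  if (anyNA(idx)) stop("unknown tag name(s)")
  stats::setNames(idx, aln@ids)
}

#' Write tags as TSV (id, tag, score, bin index)
#' @param tags a \code{"solubilityTags"}.
#' @param path output TSV.
#' @export
writeTags <- function(tags, path) {
  df <- data.frame(id = names(tags$tags), tag = unname(tags$tags),
                   score = unname(tags$scores[names(tags$tags)]),
                   bin = match(unname(tags$tags), SOLUBILITY_TAGS) - 1L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
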