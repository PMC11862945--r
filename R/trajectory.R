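#' Equally spaced points on the query-to-origin line
#'
#' Point \eqn{k = (1 - k/n) \cdot query\_mean} for \eqn{k = 0..n}: the first
#' point is exactly the query's latent mean, the last is exactly the origin,
#' and the spacing is exactly uniform.
#'
#' @param queryMean latent mean vector of the query sequence.
#' @param nIntervals number of equal intervals (default 100, yielding 101
#'   boundary points).
#' @return matrix \code{(nIntervals + 1) x latentDim}; row \code{k+1} is
#'   point \code{k}.
#' @export
linePoints <- function(queryMean, nIntervals = 100L) {
  stopifnot(nIntervals >= 1L)
  queryMean <- as.numeric(queryMean)
  k <- 0:nIntervals
  outer(1 - k / nIntervals, queryMean)
}

#' Generate designs along the straight-line evolutionary trajectory
#'
#' Encodes the query, divides the straight line from its latent mean to the
#' latent-space origin into \code{nIntervals} equal intervals, and
#' argmax-decodes every boundary point. Index 0 is the reconstruction of the
#' query's own embedding; indices 1..\code{nIntervals} are the ancestor-like
#' designs, increasingly divergent as they approach the origin. Decoding is
#' deterministic (argmax, ties to the lowest symbol index): designs are
#' selectable artifacts, unlike the categorical sampling used for
#' generative statistics.
#'
#' @param model a trained [SequenceVAE-class].
#' @param query aligned query sequence (string or one-hot row).
#' @param nIntervals number of intervals (default 100).
#' @param tag single 0-based tag for conditional models (e.g. the HIGH
#'   solubility bin); must be absent for unconditional models.
#' @return object of class \code{"trajectoryDesigns"}: list with
#'   \code{index} (0..nIntervals), \code{coordinates} (matrix),
#'   \code{sequences} (aligned strings), and \code{profile} (NULL until
#'   [profileDesigns()]).
#' @export
generateTrajectory <- function(model, query, nIntervals = 100L, tag = NULL) {
  if (!model@trained) stop("model is untrained: train before generating")
  x <- .asInputMatrix(model, query)
  g <- encodeSequences(model, x, tags = tag)
  pts <- linePoints(g$mean[1L, ], nIntervals)
  seqs <- decodeToSequences(model, pts,
                            tags = if (is.null(tag)) NULL
                                   else rep(tag, nrow(pts)))
  names(seqs) <- c("query_reconstruction",
                   paste0("anc", seq_len(nIntervals)))
  structure(list(index = 0:nIntervals, coordinates = pts, sequences = seqs,
                 query = .probsToSeqs(x, model@config$msaWidth),
                 tag = tag, profile = NULL),
            class = "trajectoryDesigns")
}

#' @export
print.trajectoryDesigns <- function(x, ...) {
  cat("trajectoryDesigns:", length(x$index) - 1L, "ancestor designs",
      "plus the query reconstruction (index 0)\n")
  if (!is.null(x$profile)) {
    cat("profiled; identity to query ranges ",
        sprintf("%.2f-%.2f\n", min(x$profile$identity_to_query),
                max(x$profile$identity_to_query)), sep = "")
  }
  invisible(x)
}

#' Count insertions and deletions of a design relative to the query
#'
#' In shared MSA coordinates: a deletion is a column where the query has a
#' residue and the design a gap; an insertion the reverse. Gap-gap and
#' residue-residue columns contribute nothing.
#'
#' @param query,design aligned strings of equal length.
#' @return named integer vector \code{c(insertions =, deletions =)}.
#' @export
countIndels <- function(query, design) {
  if (nchar(query) != nchar(design))
    stop("aligned strings differ in length")
  q <- strsplit(query, "")[[1L]] == "-"
  d <- strsplit(design, "")[[1L]] == "-"
  c(insertions = sum(q & !d), deletions = sum(!q & d))
}

#' Fill the statistical design profile of a trajectory
#'
#' Per design: the average reconstruction probability (mean over columns of
#' the probability the decoder assigns, at the design's own latent point, to
#' the design's decoded symbol), the identity to the query, the identity to
#' (and identifier of) the closest training sequence (maximum identity, ties
#' broken by first occurrence in alignment order), and the insertion /
#' deletion counts relative to the query.
#'
#' @param designs a \code{"trajectoryDesigns"} object.
#' @param training the training [ProteinMSA-class].
#' @param model the trained [SequenceVAE-class] that generated the designs.
#' @return the \code{"trajectoryDesigns"} with \code{profile} set to a
#'   data.frame.
#' @export
profileDesigns <- function(designs, training, model) {
  stopifnot(inherits(designs, "trajectoryDesigns"), length(training) >= 1L)
  probs <- decodeLatent(model, designs$coordinates,
                        tags = if (is.null(designs$tag)) NULL
                               else rep(designs$tag, nrow(designs$coordinates)))
  w <- model@config$msaWidth
  decIdx <- seqToInts(designs$sequences)
  flat <- (col(decIdx) - 1L) * 21L + decIdx
  pSel <- matrix(probs[cbind(rep(seq_len(nrow(probs)), w), as.vector(flat))],
                 nrow(probs), w)
  recProb <- rowMeans(pSel)

  q <- designs$query
  trSeqs <- sequences(training)
  trMat <- seqToInts(trSeqs)
  identQ <- vapply(designs$sequences, sequenceIdentity, 0, b = q,
                   USE.NAMES = FALSE)
  closest <- t(vapply(seq_along(designs$sequences), function(i) {
    hits <- colMeans(t(trMat) == decIdx[i, ])
    j <- which.max(hits)
    c(id = j, identity = hits[j])
  }, c(id = 0, identity = 0)))
  indels <- t(vapply(designs$sequences, countIndels,
                     c(insertions = 0L, deletions = 0L), query = q))
  designs$profile <- data.frame(
    index = designs$index,
    reconstruction_probability = recProb,
    identity_to_query = identQ,
    identity_to_closest_training = unname(closest[, "identity"]),
    closest_training_id = names(trSeqs)[closest[, "id"]],
    insertions = unname(indels[, "insertions"]),
    deletions = unname(indels[, "deletions"]),
    row.names = NULL)
  designs
}

#' Write trajectory designs and their profile to files
#'
#' Writes \code{<prefix>.aligned.fasta} (MSA coordinates),
#' \code{<prefix>.ungapped.fasta} (gaps stripped, ready for synthesis),
#' \code{<prefix>.profile.tsv} and \code{<prefix>.profile.json}.
#'
#' @param designs a profiled \code{"trajectoryDesigns"}.
#' @param prefix output path prefix.
#' @param maxIndels optional filter: drop designs with more than this many
#'   total indels from the FASTA outputs (profile always covers all).
#' @param minIdentity optional filter on identity to the query.
#' @return invisible character vector of the written paths.
#' @export
writeDesigns <- function(designs, prefix, maxIndels = NULL,
                         minIdentity = NULL) {
  if (is.null(designs$profile))
    stop("designs must be profiled first (profileDesigns)")
  pr <- designs$profile
  keep <- rep(TRUE, nrow(pr))
  if (!is.null(maxIndels))
    keep <- keep & (pr$insertions + pr$deletions) <= maxIndels
  if (!is.null(minIdentity)) keep <- keep & pr$identity_to_query >= minIdentity
  paths <- paste0(prefix, c(".aligned.fasta", ".ungapped.fasta",
                            ".profile.tsv", ".profile.json"))
  writeAlignment(designs$sequences[keep], paths[1L])
  ungapped <- gsub("-", "", designs$sequences[keep], fixed = TRUE)
  Biostrings::writeXStringSet(Biostrings::BStringSet(ungapped), paths[2L])
  coord <- designs$coordinates
  colnames(coord) <- paste0("z", seq_len(ncol(coord)))
  utils::write.table(cbind(pr, coord), paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(cbind(pr, coord), paths[4L], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
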