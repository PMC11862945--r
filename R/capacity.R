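#' Sample sequences from a trained model
#'
#' Draws latent points from the standard-normal prior and decodes them.
#' \code{mode = "categorical"} (the default, used for statistical
#' comparisons) samples each column from its decoded distribution;
#' \code{mode = "argmax"} takes the per-column mode (which collapses
#' diversity and is reserved for deterministic artifacts).
#'
#' @param model a trained [SequenceVAE-class].
#' @param n number of sequences (default 3000, the size used for the first-
#'   and second-order statistical comparison).
#' @param seed integer seed.
#' @param mode \code{"categorical"} or \code{"argmax"}.
#' @param tag single 0-based tag for conditional models.
#' @return character vector of \code{n} aligned sequences.
#' @export
sampleGenerated <- function(model, n = 3000L, seed = 1L,
                            mode = c("categorical", "argmax"), tag = NULL) {
  mode <- match.arg(mode)
  if (!model@trained) stop("model is untrained: train before sampling")
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(n * model@config$latentDim), n,
              model@config$latentDim)
  probs <- decodeLatent(model, z, tags = if (is.null(tag)) NULL else tag)
  .probsToSeqs(probs, model@config$msaWidth, sample = (mode == "categorical"))
}

#' First- and second-order site statistics of a sequence set
#'
#' First order: empirical per-(column, symbol) frequencies. Second order:
#' pairwise covariances \eqn{cov(i,j,a,b) = f_{ij}(a,b) - f_i(a) f_j(b)} over
#' all column pairs \eqn{i < j} and all 21x21 symbol pairs (gap included;
#' zero-frequency entries are retained — they carry signal about what a model
#' never generates).
#'
#' @param seqs character vector of equal-length aligned sequences.
#' @return object of class \code{"siteStats"}: list with \code{freq}
#'   (width x 21 matrix), \code{cov} (symmetric \code{(width*21)^2} matrix in
#'   the flattened one-hot layout), \code{width}, and \code{n}.
#' @export
siteStats <- function(seqs) {
  if (!length(seqs)) stop("empty sequence set")
  if (length(unique(nchar(seqs))) != 1L)
    stop("ragged input: sequences must share one width")
  X <- .seqsToX(seqs)
  n <- nrow(X); w <- ncol(X) / 21L
  f <- colMeans(X)
  cv <- crossprod(X) / n - tcrossprod(f)
  structure(list(freq = matrix(f, w, 21L, byrow = TRUE,
                               dimnames = list(NULL, AA_ALPHABET)),
                 cov = cv, width = w, n = n),
            class = "siteStats")
}

#' @export
print.siteStats <- function(x, ...) {
  cat("siteStats:", x$n, "sequences,", x$width, "columns\n")
  invisible(x)
}

.upperPairMask <- function(width) {
  colIdx <- rep(seq_len(width), each = 21L)
  outer(colIdx, colIdx, "<")
}

#' Agreement between two sets of site statistics
#'
#' Pearson correlation of the paired entries: first order over all
#' (column, symbol) frequencies, second order over all pairwise covariance
#' entries with \eqn{i < j}. This is the generative-capacity score comparing
#' an input MSA with model-generated sequences.
#'
#' @param a,b \code{"siteStats"} objects of equal width.
#' @return named numeric vector \code{c(firstOrderR =, secondOrderR =)}.
#' @export
statsAgreement <- function(a, b) {
  stopifnot(inherits(a, "siteStats"), inherits(b, "siteStats"))
  if (a$width != b$width) stop("site statistics have different widths")
  f1 <- as.vector(a$freq); f2 <- as.vector(b$freq)
  if (stats::sd(f1) == 0 || stats::sd(f2) == 0)
    stop("degenerate (zero-variance) first-order statistics")
  mask <- .upperPairMask(a$width)
  c1 <- a$cov[mask]; c2 <- b$cov[mask]
  if (stats::sd(c1) == 0 || stats::sd(c2) == 0)
    stop("degenerate (zero-variance) second-order statistics")
  c(firstOrderR = stats::cor(f1, f2),
    secondOrderR = stats::cor(c1, c2))
}

#' Identity between two aligned strings in fixed MSA coordinates
#'
#' Matching columns divided by total columns; gap-gap columns count as
#' matches because both sequences live in the same coordinate system and the
#' gap is a bona fide model symbol.
#'
#' @param a,b aligned strings of equal length.
#' @return fraction in [0, 1].
#' @export
sequenceIdentity <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("aligned strings differ in length (", nchar(a), " vs ", nchar(b), ")")
  mean(strsplit(a, "")[[1L]] == strsplit(b, "")[[1L]])
}

#' Reconstruction of a sequence from its own mean embedding
#'
#' Identity between the sequence and the argmax decode of its posterior
#' mean; the headline "query reconstruction" number of a trained model.
#'
#' @param model a trained [SequenceVAE-class].
#' @param seq aligned sequence (string) or one-hot row.
#' @param tag 0-based tag for conditional models.
#' @return identity fraction in [0, 1].
#' @export
queryReconstructionAccuracy <- function(model, seq, tag = NULL) {
  x <- .asInputMatrix(model, seq)
  g <- encodeSequences(model, x, tags = tag)
  dec <- decodeToSequences(model, g$mean, tags = tag)
  truth <- .probsToSeqs(x, model@config$msaWidth)
  sequenceIdentity(dec, truth)
}

#' Average reconstruction accuracy around a sequence's embedding
#'
#' Mean identity between the sequence and the argmax decodes of \code{n}
#' latent samples drawn from its posterior Gaussian (mean and variance
#' returned by the encoder).
#'
#' @param model a trained [SequenceVAE-class].
#' @param seq aligned sequence or one-hot row.
#' @param n number of latent samples (default 5000).
#' @param seed integer seed.
#' @param tag 0-based tag for conditional models.
#' @return mean identity fraction.
#' @export
avgReconstructionAccuracy <- function(model, seq, n = 5000L, seed = 1L,
                                      tag = NULL) {
  x <- .asInputMatrix(model, seq)
  g <- encodeSequences(model, x, tags = tag)
  z <- sampleLatent(g, n = n, seed = seed)
  probs <- decodeLatent(model, z,
                        tags = if (is.null(tag)) NULL else rep(tag, n))
  w <- model@config$msaWidth
  a <- matrix(t(probs), nrow = 21L)           # (seq i, col j), j fastest
  idx <- matrix(max.col(t(a), ties.method = "first"), w, n)
  truth <- max.col(matrix(x[1L, ], ncol = 21L, byrow = TRUE),
                   ties.method = "first")      # length w
  mean(idx == truth)
}

#' Profile-sampled negative control sequences
#'
#' Samples each column independently from the alignment's empirical symbol
#' frequencies (gap included), destroying all pairwise structure. The
#' default size is 5 percent of the alignment, matching the convention for
#' the control subsets.
#'
#' @param aln a [ProteinMSA-class].
#' @param n number of sequences; default \code{round(0.05 * length(aln))}.
#' @param seed integer seed.
#' @return character vector of aligned sequences.
#' @export
negativeControl <- function(aln, n = NULL, seed = 1L) {
  if (is.null(n)) n <- max(1L, round(0.05 * length(aln)))
  m <- seqToInts(aln@seqs)
  w <- ncol(m)
  set.seed(as.integer(seed))
  out <- matrix(0L, n, w)
  for (j in seq_len(w)) {
    tab <- tabulate(m[, j], nbins = 21L)
    out[, j] <- sample.int(21L, n, replace = TRUE, prob = tab / sum(tab))
  }
  stats::setNames(intsToSeq(out), paste0("negative_", seq_len(n)))
}

#' Reconstruction-accuracy control report
#'
#' Computes the per-sequence average reconstruction accuracy for the four
#' control sets (profile-sampled negatives, training sequences, held-out
#' positives, trajectory "ancestors") and counts, per set, how many fall
#' below / at-or-above the separation threshold (~50 percent by default, the
#' cutoff at which a trained model separates random from family sequences).
#'
#' @param model a trained [SequenceVAE-class].
#' @param sets named list of character vectors of aligned sequences; names
#'   among \code{negative}, \code{training}, \code{positive},
#'   \code{ancestral} (any may be omitted; empty sets are skipped).
#' @param threshold accuracy cutoff (default 0.5); "below" means strictly
#'   less than the threshold.
#' @param n number of latent samples per sequence (default 5000).
#' @param seed integer seed.
#' @param tags optional named list of per-set 0-based tag vectors for
#'   conditional models.
#' @return object of class \code{"controlReport"}: list with
#'   \code{accuracies} (named list of numeric vectors), \code{threshold},
#'   and \code{counts} (data.frame set/n/below/above/mean).
#' @export
controlReport <- function(model, sets, threshold = 0.5, n = 5000L,
                          seed = 1L, tags = NULL) {
  stopifnot(threshold >= 0, threshold <= 1)
  sets <- sets[vapply(sets, length, 0L) > 0L]
  acc <- vector("list", length(sets))
  names(acc) <- names(sets)
  for (k in seq_along(sets)) {
    ss <- sets[[k]]
    tg <- if (is.null(tags)) NULL else tags[[names(sets)[k]]]
    acc[[k]] <- vapply(seq_along(ss), function(i)
      avgReconstructionAccuracy(model, ss[i], n = n,
                                seed = seed + 7L * k + i,
                                tag = if (is.null(tg)) NULL else tg[i]), 0)
    names(acc[[k]]) <- if (is.null(names(ss)))
      paste0(names(sets)[k], "_", seq_along(ss)) else names(ss)
  }
  counts <- data.frame(
    set = names(acc),
    n = vapply(acc, length, 0L),
    below = vapply(acc, function(a) sum(a < threshold), 0L),
    above = vapply(acc, function(a) sum(a >= threshold), 0L),
    mean = vapply(acc, mean, 0),
    row.names = NULL)
  structure(list(accuracies = acc, threshold = threshold, counts = counts),
            class = "controlReport")
}

#' @export
print.controlReport <- function(x, ...) {
  cat("controlReport (threshold ", x$threshold, "):\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Write site statistics / control report as TSV
#'
#' \code{writeSiteStats} writes the long-format first-order table
#' (column, symbol, frequency); \code{writeControlReport} writes
#' (set, id, accuracy) plus a JSON summary next to it.
#'
#' @param stats a \code{"siteStats"} object.
#' @param path output TSV path.
#' @export
writeSiteStats <- function(stats, path) {
  df <- data.frame(column = rep(seq_len(stats$width) - 1L, times = 21L),
                   symbol = rep(AA_ALPHABET, each = stats$width),
                   frequency = as.vector(stats$freq))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSiteStats
#' @param report a \code{"controlReport"}.
#' @export
writeControlReport <- function(report, path) {
  df <- do.call(rbind, lapply(names(report$accuracies), function(s)
    data.frame(set = s, id = names(report$accuracies[[s]]),
               accuracy = unname(report$accuracies[[s]]))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(threshold = report$threshold,
         counts = report$counts),
    paste0(sub("\\.tsv$", "", path), ".summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
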