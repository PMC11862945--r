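#' @import methods
NULL

#' ProteinMSA: a query-anchored protein multiple sequence alignment
#'
#' An ordered set of equal-length sequences over the 21-symbol alphabet
#' (20 amino acids plus gap), with one record designated as the query — the
#' anchor whose coordinates define column filtering and whose latent embedding
#' anchors the design trajectory.
#'
#' @slot ids character vector of unique record identifiers (row order is
#'   meaningful and preserved by all operations).
#' @slot seqs character vector of aligned residue strings, parallel to
#'   \code{ids}; all of equal width.
#' @slot queryId identifier of the anchor sequence; must appear in \code{ids}.
#'
#' @aliases ProteinMSA-class
#' @exportClass ProteinMSA
setClass("ProteinMSA",
         representation(ids = "character", seqs = "character",
                        queryId = "character"))

setValidity("ProteinMSA", function(object) {
  msgs <- character(0)
  if (length(object@ids) != length(object@seqs))
    msgs <- c(msgs, "ids and seqs must have equal length")
  if (length(object@ids) == 0L)
    msgs <- c(msgs, "alignment is empty")
  if (anyDuplicated(object@ids))
    msgs <- c(msgs, "duplicate sequence identifiers")
  if (length(object@seqs) > 0L) {
    w <- nchar(object@seqs[1L])
    if (any(nchar(object@seqs) != w))
      msgs <- c(msgs, "all sequences must have the same width")
    bad <- grepl(sprintf("[^%s-]", paste(AA_ALPHABET[1:20], collapse = "")),
                 object@seqs)
    if (any(bad))
      msgs <- c(msgs, "sequences contain symbols outside the 21-letter alphabet")
  }
  if (length(object@queryId) != 1L || !(object@queryId %in% object@ids))
    msgs <- c(msgs, "queryId must name exactly one record of the alignment")
  if (length(msgs)) msgs else TRUE
})

#' SequenceVAE: a (conditional) variational autoencoder over aligned sequences
#'
#' Encoder: flattened one-hot input of size width x 21 (plus an optional
#' 3-way condition tag) -> one tanh hidden layer -> latent Gaussian
#' (mean, log-variance). Decoder: latent point (plus tag) -> one tanh hidden
#' layer -> per-column categorical distributions over the 21 symbols.
#'
#' @slot config list of architecture settings (see [modelConfig()]).
#' @slot params named list of weight matrices and bias vectors.
#' @slot trained logical; set by [trainVAE()].
#' @slot lossHistory numeric matrix with columns reconstruction, kl, total
#'   (one row per epoch; zero rows before training).
#'
#' @aliases SequenceVAE-class
#' @exportClass SequenceVAE
setClass("SequenceVAE",
         representation(config = "list", params = "list", trained = "logical",
                        lossHistory = "matrix"))

setValidity("SequenceVAE", function(object) {
  need <- c("W1", "b1", "Wmu", "bmu", "Wlv", "blv", "W4", "b4", "W5", "b5")
  if (!all(need %in% names(object@params)))
    return(paste("missing parameter tensors:",
                 paste(setdiff(need, names(object@params)), collapse = ", ")))
  cf <- object@config
  if (cf$latentDim < 1L) return("latentDim must be >= 1")
  if (!cf$conditionArity %in% c(0L, 3L))
    return("conditionArity must be 0 (plain VAE) or 3 (solubility tags)")
  TRUE
})

#' AnnotatedTree: a rooted phylogeny whose every node carries a sequence
#'
#' Stored as a parent-pointer node table so that ancestor-closed subsamples
#' (which contract unary paths) remain first-class trees. Depth is cumulative
#' branch length from the root (root depth 0).
#'
#' @slot ids character vector of node identifiers (root included).
#' @slot parent named character vector: parent id per node, \code{NA} for the
#'   root.
#' @slot depth named numeric vector of cumulative branch lengths from root.
#' @slot sequences named character vector of aligned sequences, one per node,
#'   all of width equal to the alignment width.
#'
#' @aliases AnnotatedTree-class
#' @exportClass AnnotatedTree
setClass("AnnotatedTree",
         representation(ids = "character", parent = "character",
                        depth = "numeric", sequences = "character"))

setValidity("AnnotatedTree", function(object) {
  msgs <- character(0)
  if (anyDuplicated(object@ids)) msgs <- c(msgs, "duplicate node ids")
  roots <- object@ids[is.na(object@parent[object@ids])]
  if (length(roots) != 1L) msgs <- c(msgs, "tree must have exactly one root")
  if (!setequal(names(object@sequences), object@ids))
    msgs <- c(msgs, "every node needs exactly one aligned sequence")
  w <- nchar(object@sequences[1L])
  if (any(nchar(object@sequences) != w))
    msgs <- c(msgs, "node sequences must share one width")
  par <- object@parent[object@ids]
  ok <- is.na(par) | par %in% object@ids
  if (!all(ok)) msgs <- c(msgs, "parent pointers must stay inside the node set")
  d <- object@depth[object@ids]
  dp <- object@depth[par]
  strictly <- is.na(par) | d >= dp - 1e-12
  if (!all(strictly)) msgs <- c(msgs, "child depth must not be below parent depth")
  if (length(msgs)) msgs else TRUE
})
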