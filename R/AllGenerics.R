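#' @describeIn ProteinMSA number of sequences
#' @param x,object a \code{ProteinMSA}
#' @export
setMethod("length", "ProteinMSA", function(x) length(x@ids))

#' Alignment width (number of columns)
#' @param x a \code{ProteinMSA} or \code{AnnotatedTree}
#' @export
setGeneric("alnWidth", function(x) standardGeneric("alnWidth"))

#' @rdname alnWidth
#' @export
setMethod("alnWidth", "ProteinMSA", function(x) nchar(x@seqs[1L]))

#' @rdname alnWidth
#' @export
setMethod("alnWidth", "AnnotatedTree", function(x) nchar(x@sequences[1L]))

#' Record identifiers
#' @param x a \code{ProteinMSA} or \code{AnnotatedTree}
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' @rdname seqIds
#' @export
setMethod("seqIds", "ProteinMSA", function(x) x@ids)

#' @rdname seqIds
#' @export
setMethod("seqIds", "AnnotatedTree", function(x) x@ids)

#' Aligned residue strings (named by identifier)
#' @param x a \code{ProteinMSA} or \code{AnnotatedTree}
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname sequences
#' @export
setMethod("sequences", "ProteinMSA",
          function(x) stats::setNames(x@seqs, x@ids))

#' @rdname sequences
#' @export
setMethod("sequences", "AnnotatedTree", function(x) x@sequences[x@ids])

#' Query (anchor) identifier and sequence
#' @param x a \code{ProteinMSA}
#' @export
setGeneric("queryId", function(x) standardGeneric("queryId"))

#' @rdname queryId
#' @export
setMethod("queryId", "ProteinMSA", function(x) x@queryId)

#' @rdname queryId
#' @export
setGeneric("querySeq", function(x) standardGeneric("querySeq"))

#' @rdname queryId
#' @export
setMethod("querySeq", "ProteinMSA",
          function(x) x@seqs[match(x@queryId, x@ids)])

#' @export
setMethod("show", "ProteinMSA", function(object) {
  cat("ProteinMSA:", length(object@ids), "sequences x",
      nchar(object@seqs[1L]), "columns; query:", object@queryId, "\n")
})

#' Subset a ProteinMSA by identifier or index (query must survive use sites
#' that need it; subsetting itself does not enforce it).
#' @param x a \code{ProteinMSA}
#' @param i integer or character index
#' @param j,...,drop ignored
#' @export
setMethod("[", "ProteinMSA", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  new("ProteinMSA", ids = x@ids[i], seqs = x@seqs[i], queryId = x@queryId)
})

#' @export
setMethod("show", "SequenceVAE", function(object) {
  cf <- object@config
  cat(sprintf(
    "SequenceVAE: width %d, hidden %d, latent %d, %s, %s\n",
    cf$msaWidth, cf$hiddenWidth, cf$latentDim,
    if (cf$conditionArity > 0L) "conditional (3 tags)" else "unconditional",
    if (object@trained) sprintf("trained (%d epochs)", nrow(object@lossHistory))
    else "untrained"))
})

#' @export
setMethod("show", "AnnotatedTree", function(object) {
  nl <- sum(!(object@ids %in% object@parent))
  cat("AnnotatedTree:", length(object@ids), "nodes (", nl, "leaves ), width",
      nchar(object@sequences[1L]), "\n")
})

#' Root identifier of an annotated tree
#' @param x an \code{AnnotatedTree}
#' @export
setGeneric("rootId", function(x) standardGeneric("rootId"))

#' @rdname rootId
#' @export
setMethod("rootId", "AnnotatedTree",
          function(x) x@ids[is.na(x@parent[x@ids])])

#' Node depths (cumulative branch length from the root)
#' @param x an \code{AnnotatedTree}
#' @export
setGeneric("nodeDepths", function(x) standardGeneric("nodeDepths"))

#' @rdname nodeDepths
#' @export
setMethod("nodeDepths", "AnnotatedTree", function(x) x@depth[x@ids])

#' Leaf identifiers (nodes with no children)
#' @param x an \code{AnnotatedTree}
#' @export
setGeneric("leafIds", function(x) standardGeneric("leafIds"))

#' @rdname leafIds
#' @export
setMethod("leafIds", "AnnotatedTree",
          function(x) x@ids[!(x@ids %in% x@parent)])
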