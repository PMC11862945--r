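#' Build an AnnotatedTree from parent pointers
#'
#' @param parent named character vector (parent id per node id, \code{NA}
#'   for the root).
#' @param branchLength named numeric vector of branch lengths to each node's
#'   parent (root entry ignored); if \code{NULL}, unit lengths are used.
#' @param sequences named character vector of aligned sequences covering all
#'   nodes.
#' @return an [AnnotatedTree-class].
#' @export
annotatedTree <- function(parent, sequences, branchLength = NULL) {
  ids <- names(parent)
  if (is.null(branchLength)) branchLength <- stats::setNames(rep(1, length(ids)), ids)
  depth <- stats::setNames(rep(NA_real_, length(ids)), ids)
  root <- ids[is.na(parent)]
  depth[root] <- 0
  # iterate until all depths resolved (tree is small; O(n^2) worst case fine)
  while (anyNA(depth)) {
    todo <- ids[is.na(depth)]
    ready <- todo[!is.na(depth[parent[todo]])]
    if (!length(ready)) stop("unresolvable parent pointers (cycle or orphan)")
    depth[ready] <- depth[parent[ready]] + branchLength[ready]
  }
  new("AnnotatedTree", ids = ids, parent = parent, depth = depth,
      sequences = sequences[ids])
}

#' Read a newick tree with node-wise aligned sequences
#'
#' Every labeled node (tips and internal nodes, e.g. pre-computed ancestral
#' reconstructions) must have a sequence in the FASTA. Depths are cumulative
#' branch lengths from the root; if the newick carries no branch lengths,
#' unit lengths are used so depth equals topological level.
#'
#' @param newickPath newick file; internal nodes must be labeled.
#' @param fastaPath aligned FASTA keyed by node labels (or a named character
#'   vector of sequences).
#' @return an [AnnotatedTree-class].
#' @export
readAnnotatedTree <- function(newickPath, fastaPath) {
  tr <- ape::read.tree(newickPath)
  seqs <- if (is.character(fastaPath) && length(fastaPath) == 1L &&
              file.exists(fastaPath)) {
    ss <- Biostrings::readBStringSet(fastaPath)
    stats::setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
  } else fastaPath
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  if (is.null(tr$node.label) || any(tr$node.label == ""))
    tr$node.label <- paste0("node", seq_len(nnode))
  labels <- c(tr$tip.label, tr$node.label)
  missing <- setdiff(labels, names(seqs))
  if (length(missing))
    stop("no sequence for node(s): ", paste(missing, collapse = ", "))
  w <- nchar(seqs[[labels[1L]]])
  if (any(nchar(seqs[labels]) != w))
    stop("node sequences do not share the alignment width")
  el <- if (is.null(tr$edge.length)) rep(1, nrow(tr$edge)) else tr$edge.length
  parent <- stats::setNames(rep(NA_character_, length(labels)), labels)
  blen <- stats::setNames(rep(0, length(labels)), labels)
  for (e in seq_len(nrow(tr$edge))) {
    parent[labels[tr$edge[e, 2L]]] <- labels[tr$edge[e, 1L]]
    blen[labels[tr$edge[e, 2L]]] <- el[e]
  }
  annotatedTree(parent, seqs[labels], blen)
}

#' Children lookup
#' @keywords internal
.childrenOf <- function(tree) {
  split(tree@ids[!is.na(tree@parent[tree@ids])],
        tree@parent[tree@ids][!is.na(tree@parent[tree@ids])])
}

#' Root-to-leaf paths of an annotated tree
#'
#' @param tree an [AnnotatedTree-class].
#' @return named list: for each leaf, the vector of node ids from the root
#'   down to that leaf.
#' @export
rootToLeafPaths <- function(tree) {
  lv <- leafIds(tree)
  out <- lapply(lv, function(l) {
    path <- l
    while (!is.na(tree@parent[path[1L]]))
      path <- c(tree@parent[[path[1L]]], path)
    path
  })
  stats::setNames(out, lv)
}

#' Ancestor-closed random node subsample
#'
#' Randomly accumulates nodes (always including each picked node's full
#' ancestor chain, so the subset is closed under the ancestor relation and
#' the root is always kept) until at least \code{nNodes} nodes are retained.
#' Parent pointers are contracted to the nearest kept ancestor.
#'
#' @param tree an [AnnotatedTree-class].
#' @param nNodes target node count (around 100 in a typical evaluation);
#'   values at or above the tree size return the tree unchanged.
#' @param seed integer seed.
#' @return an [AnnotatedTree-class] over the kept nodes.
#' @export
subsampleTree <- function(tree, nNodes = 100L, seed = 1L) {
  stopifnot(nNodes >= 3L)
  n <- length(tree@ids)
  if (nNodes >= n) {
    if (nNodes > n) warning("nNodes exceeds tree size; returning tree unchanged")
    return(tree)
  }
  set.seed(as.integer(seed))
  root <- rootId(tree)
  keep <- root
  pool <- sample(setdiff(tree@ids, root))
  i <- 1L
  while (length(keep) < nNodes && i <= length(pool)) {
    node <- pool[i]; i <- i + 1L
    chain <- node
    while (!is.na(tree@parent[chain[1L]]) &&
           !(tree@parent[[chain[1L]]] %in% keep))
      chain <- c(tree@parent[[chain[1L]]], chain)
    keep <- union(keep, chain)
  }
  keep <- tree@ids[tree@ids %in% keep]    # original order
  # contract parents to nearest kept ancestor
  parent <- stats::setNames(rep(NA_character_, length(keep)), keep)
  for (nd in keep) {
    p <- tree@parent[[nd]]
    while (!is.na(p) && !(p %in% keep)) p <- tree@parent[[p]]
    parent[nd] <- p
  }
  new("AnnotatedTree", ids = keep, parent = parent,
      depth = tree@depth[keep], sequences = tree@sequences[keep])
}

#' Embed every node of an annotated tree into the latent space
#'
#' Each node's aligned sequence is encoded and its posterior mean taken
#' (deterministic).
#'
#' @param model a trained [SequenceVAE-class].
#' @param tree an [AnnotatedTree-class] whose sequence width matches the
#'   model.
#' @param tag single 0-based tag for conditional models.
#' @return numeric matrix nodes x latentDim with node ids as row names.
#' @export
embedTree <- function(model, tree, tag = NULL) {
  seqs <- sequences(tree)
  g <- encodeSequences(model, seqs,
                       tags = if (is.null(tag)) NULL
                              else rep(tag, length(seqs)))
  rownames(g$mean) <- names(seqs)
  g$mean
}

.pathsForMetrics <- function(tree, embeddings, minNodes = 3L) {
  paths <- rootToLeafPaths(tree)
  paths[vapply(paths, length, 0L) >= minNodes]
}

#' Depth vs. distance-to-origin correlation per lineage
#'
#' For each root-to-leaf path with at least 3 nodes, the Pearson correlation
#' between node depth (cumulative branch length) and the Euclidean distance
#' of the node's embedding from the latent-space origin. A positive value
#' means the lineage moves away from the origin as it descends the tree —
#' the geometric signature of a latent space that captures phylogeny.
#' Paths with constant depth or constant distance are flagged undefined
#' (\code{NA}) and excluded from summaries.
#'
#' @param tree an [AnnotatedTree-class].
#' @param embeddings node embedding matrix from [embedTree()].
#' @return data.frame (leaf, n, r).
#' @export
depthOriginCorrelation <- function(tree, embeddings) {
  paths <- .pathsForMetrics(tree, embeddings)
  res <- lapply(names(paths), function(l) {
    p <- paths[[l]]
    d <- tree@depth[p]
    dist <- sqrt(rowSums(embeddings[p, , drop = FALSE]^2))
    r <- if (stats::sd(d) == 0 || stats::sd(dist) == 0) NA_real_
         else stats::cor(d, dist)
    data.frame(leaf = l, n = length(p), r = r)
  })
  do.call(rbind, res)
}

#' Branch directionality in the latent space
#'
#' Per root-to-leaf path: the first principal axis of the path's node
#' embeddings is oriented from the leaf end toward the root end (by the
#' order of node projections along the axis), and the signed cosine between
#' this oriented axis and the unit vector pointing from the leaf embedding
#' toward the origin is returned. +1 means the lineage runs straight toward
#' the latent-space origin as one moves from leaf to root; -1 the opposite.
#' Degenerate paths (all embeddings identical, or leaf at the origin) are
#' \code{NA}.
#'
#' @param tree an [AnnotatedTree-class].
#' @param embeddings node embedding matrix from [embedTree()].
#' @return data.frame (leaf, n, cosine).
#' @export
branchDirectionality <- function(tree, embeddings) {
  paths <- .pathsForMetrics(tree, embeddings)
  res <- lapply(names(paths), function(l) {
    p <- paths[[l]]
    E <- embeddings[p, , drop = FALSE]
    leaf <- E[nrow(E), ]
    ctr <- sweep(E, 2L, colMeans(E))
    cv <- crossprod(ctr) / nrow(E)
    if (sum(cv^2) < 1e-24 || sqrt(sum(leaf^2)) < 1e-12)
      return(data.frame(leaf = l, n = length(p), cosine = NA_real_))
    ax <- eigen(cv, symmetric = TRUE)$vectors[, 1L]
    proj <- as.vector(ctr %*% ax)
    # orient the axis from the leaf end toward the root end of the path
    if (proj[1L] < proj[length(proj)]) ax <- -ax
    toOrigin <- -leaf / sqrt(sum(leaf^2))
    data.frame(leaf = l, n = length(p),
               cosine = sum(ax * toOrigin))
  })
  do.call(rbind, res)
}

#' Summarize signed geometry values
#'
#' @param values numeric vector (e.g. directionality cosines or per-path
#'   correlations); \code{NA}s are excluded.
#' @return list with \code{fractionPositive}, \code{mean}, and a fixed
#'   20-bin histogram over [-1, 1] (\code{breaks}, \code{counts}).
#' @export
geometrySummary <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("no defined values to summarize")
  breaks <- seq(-1, 1, length.out = 21L)
  h <- graphics::hist(pmin(pmax(v, -1), 1), breaks = breaks, plot = FALSE)
  list(fractionPositive = mean(v > 0), mean = mean(v),
       breaks = breaks, counts = h$counts)
}

#' Write per-path geometry metrics as TSV
#'
#' @param corr data.frame from [depthOriginCorrelation()].
#' @param dir data.frame from [branchDirectionality()].
#' @param path output TSV.
#' @param treeId identifier echoed in the first column.
#' @export
writePathMetrics <- function(corr, dir, path, treeId = "tree1") {
  df <- merge(corr, dir, by = c("leaf", "n"))
  names(df) <- c("leaf_id", "n_nodes", "depth_origin_r", "directionality")
  df <- cbind(tree_id = treeId, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
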