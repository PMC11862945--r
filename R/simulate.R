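#' Simulation configuration for the synthetic benchmark
#'
#' Describes a star-like phylogeny (several clades radiating from the root,
#' mirroring a multi-subfamily protein family), evolved by per-site
#' substitutions (uniform over the 19 alternatives), optional indels,
#' planted pairwise column covariation, and a planted solubility score that
#' is a sparse linear function of indicator features plus Gaussian noise.
#' The simulator is intentionally simple — no rate heterogeneity, no
#' selection — because its job is to create the statistical structure the
#' pipeline's metrics assume, with known truth.
#'
#' @param nClades number of clades ("spikes" of the star), at least 2.
#' @param leavesPerClade leaves per clade.
#' @param rootLength number of ancestral (core) columns.
#' @param substitutionRate expected substitutions per site per unit branch
#'   length.
#' @param indelRate expected indel events per site per unit branch length
#'   (half deletions, half insertions; insertions add new global columns).
#' @param branchLengthMean mean of the exponential within-clade branch
#'   lengths (clade ancestors sit at branch length 1 from the root).
#' @param coupledPairs list of \code{list(i =, j =, strength =)} giving
#'   0 < strength <= 1 co-substitution coupling between core columns i < j
#'   (1-based).
#' @param solubilityWeights \code{NULL} (auto-pick at planting time) or a
#'   data.frame (column, symbol, weight) defining the planted score.
#' @param noiseSd standard deviation of the Gaussian score noise.
#' @param seed integer master seed.
#' @return list of class \code{"simConfig"}.
#' @export
simConfig <- function(nClades = 4L, leavesPerClade = 25L, rootLength = 150L,
                      substitutionRate = 0.3, indelRate = 0,
                      branchLengthMean = 0.2, coupledPairs = list(),
                      solubilityWeights = NULL, noiseSd = 0.1, seed = 1L) {
  stopifnot(nClades >= 2L, leavesPerClade >= 1L, rootLength >= 2L,
            substitutionRate >= 0, indelRate >= 0, noiseSd >= 0)
  for (cp in coupledPairs)
    stopifnot(cp$i >= 1L, cp$j <= rootLength, cp$i != cp$j,
              cp$strength > 0, cp$strength <= 1)
  structure(list(nClades = as.integer(nClades),
                 leavesPerClade = as.integer(leavesPerClade),
                 rootLength = as.integer(rootLength),
                 substitutionRate = substitutionRate, indelRate = indelRate,
                 branchLengthMean = branchLengthMean,
                 coupledPairs = coupledPairs,
                 solubilityWeights = solubilityWeights,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "simConfig")
}

# random bifurcating topology over the given leaf ids; returns edges into env
.growClade <- function(leafNames, prefix, env, cfg) {
  counter <- 0L
  recurse <- function(leaves) {
    if (length(leaves) == 1L) return(leaves)
    counter <<- counter + 1L
    me <- paste0(prefix, "_n", counter)
    k <- length(leaves)
    nl <- if (k == 2L) 1L else sample.int(k - 1L, 1L)
    left <- recurse(leaves[seq_len(nl)])
    right <- recurse(leaves[(nl + 1L):k])
    for (ch in c(left, right)) {
      env$parent[ch] <- me
      env$blen[ch] <- stats::rexp(1L, rate = 1 / cfg$branchLengthMean)
    }
    me
  }
  recurse(leafNames)
}

#' Simulate a star-like phylogeny
#'
#' The root has \code{nClades} children (the clade ancestors) at branch
#' length 1; each clade is a random bifurcating tree over its leaves with
#' exponential branch lengths.
#'
#' @param cfg a [simConfig()].
#' @return list of class \code{"simTree"} with \code{parent} (named vector,
#'   NA at the root), \code{blen} (branch lengths), \code{ids} (topological
#'   order, root first), and \code{leaves}.
#' @export
simulateTree <- function(cfg) {
  set.seed(cfg$seed)
  env <- new.env()
  env$parent <- stats::setNames(NA_character_, "root")
  env$blen <- stats::setNames(0, "root")
  leaves <- character(0)
  for (cl in seq_len(cfg$nClades)) {
    lf <- paste0("c", cl, "_l", seq_len(cfg$leavesPerClade))
    leaves <- c(leaves, lf)
    top <- if (cfg$leavesPerClade == 1L) lf else
      .growClade(lf, paste0("c", cl), env, cfg)
    env$parent[top] <- "root"
    env$blen[top] <- 1
  }
  # topological order: parents before children
  ids <- "root"
  remaining <- setdiff(names(env$parent), "root")
  while (length(remaining)) {
    ready <- remaining[env$parent[remaining] %in% ids]
    ids <- c(ids, ready)
    remaining <- setdiff(remaining, ready)
  }
  structure(list(parent = env$parent, blen = env$blen, ids = ids,
                 leaves = leaves),
            class = "simTree")
}

#' Newick string of a simTree (internal nodes labeled)
#' @param tree a \code{"simTree"}.
#' @return single newick string.
#' @export
simTreeNewick <- function(tree) {
  kids <- split(names(tree$parent)[!is.na(tree$parent)],
                tree$parent[!is.na(tree$parent)])
  fmt <- function(node) {
    ch <- kids[[node]]
    lab <- if (is.null(ch)) node else
      paste0("(", paste(vapply(ch, fmt, ""), collapse = ","), ")", node)
    if (is.na(tree$parent[node])) paste0(lab, ";")
    else paste0(lab, ":", format(tree$blen[node], digits = 8))
  }
  fmt(names(tree$parent)[is.na(tree$parent)])
}

# fixed symbol pairing used by the coupling rule: symbol a at column i
# co-occurs with .pairedSymbol(a) at column j
.pairedSymbol <- function(s) (s %% 20L) + 1L

#' Evolve sequences down a simulated tree
#'
#' The root sequence is drawn uniformly over the 20 amino acids. Along each
#' branch every non-gap site substitutes with probability
#' \eqn{1 - e^{-rate \cdot length}} to a uniformly chosen different residue.
#' For each planted coupled pair, whenever column i changes on a branch,
#' column j co-substitutes to the paired symbol with probability equal to
#' the coupling strength, creating heritable pairwise covariation. Indel
#' events (Poisson, rate \code{indelRate} per site per unit length) either
#' delete a residue (gap in that lineage onward) or insert one (a new global
#' column, gap in all other lineages). Every node's sequence is stored, so
#' true ancestors are available downstream.
#'
#' @param tree a \code{"simTree"} from [simulateTree()].
#' @param cfg the same [simConfig()].
#' @return list of class \code{"simOutput"}: \code{alignment} (leaves as a
#'   [ProteinMSA-class], query = first leaf of clade 1), \code{tree} (an
#'   [AnnotatedTree-class] over all nodes with sequences), \code{solubility}
#'   (NULL until [plantSolubility()]), and \code{truth} (the config).
#' @export
evolveSequences <- function(tree, cfg) {
  set.seed(cfg$seed + 1L)
  W <- cfg$rootLength
  seqs <- list(root = sample.int(20L, W, replace = TRUE))
  insEvents <- list()   # each: list(id, pos (after core column), residue, node)
  insOf <- list(root = integer(0))   # event ids carried by each node
  cp <- cfg$coupledPairs
  for (nd in setdiff(tree$ids, "root")) {
    par <- tree$parent[[nd]]
    len <- tree$blen[[nd]]
    s <- seqs[[par]]
    alive <- which(s <= 20L)
    psub <- 1 - exp(-cfg$substitutionRate * len)
    mut <- alive[stats::runif(length(alive)) < psub]
    if (length(mut)) {
      shift <- sample.int(19L, length(mut), replace = TRUE)
      s[mut] <- ((s[mut] - 1L + shift) %% 20L) + 1L
    }
    # co-substitution: whenever either member of a coupled pair changed on
    # this branch, the dependent column re-syncs to the paired symbol with
    # probability = strength, so the pairing is planted and then maintained
    for (pair in cp) {
      if ((pair$i %in% mut || pair$j %in% mut) &&
          s[pair$i] <= 20L && s[pair$j] <= 20L &&
          stats::runif(1L) < pair$strength)
        s[pair$j] <- .pairedSymbol(s[pair$i])
    }
    ins <- insOf[[par]]
    if (cfg$indelRate > 0) {
      nEv <- stats::rpois(1L, cfg$indelRate * len * W)
      for (e in seq_len(nEv)) {
        if (stats::runif(1L) < 0.5) {
          al <- which(s <= 20L)
          if (length(al)) s[sample(al, 1L)] <- 21L
        } else {
          id <- length(insEvents) + 1L
          insEvents[[id]] <- list(id = id, pos = sample.int(W, 1L),
                                  residue = sample.int(20L, 1L), node = nd)
          ins <- c(ins, id)
        }
      }
    }
    seqs[[nd]] <- s
    insOf[[nd]] <- ins
  }
  # build the global coordinate system: core columns plus insertion columns
  # ordered by (core position, event id)
  if (length(insEvents)) {
    evPos <- vapply(insEvents, `[[`, 0L, "pos")
    evOrd <- order(evPos, vapply(insEvents, `[[`, 0L, "id"))
    build <- function(nd) {
      s <- seqs[[nd]]
      mine <- insOf[[nd]]
      out <- integer(0)
      k <- 1L
      for (j in seq_len(W)) {
        out <- c(out, s[j])
        while (k <= length(evOrd) && evPos[evOrd[k]] == j) {
          ev <- insEvents[[evOrd[k]]]
          out <- c(out, if (ev$id %in% mine) ev$residue else 21L)
          k <- k + 1L
        }
      }
      out
    }
    # insertion columns sort after their core column; events at pos j come in
    # id order. (evPos entries equal to j are consumed as column j is emitted)
    seqs <- stats::setNames(lapply(names(seqs), build), names(seqs))
  }
  allSeqs <- vapply(seqs[tree$ids], function(s) paste(AA_ALPHABET[s],
                                                      collapse = ""), "")
  atree <- annotatedTree(tree$parent[tree$ids], allSeqs, tree$blen[tree$ids])
  aln <- proteinMSA(tree$leaves, allSeqs[tree$leaves], queryId = "c1_l1")
  structure(list(alignment = aln, tree = atree, solubility = NULL,
                 truth = cfg),
            class = "simOutput")
}

#' @export
print.simOutput <- function(x, ...) {
  cat("simOutput:", length(x$alignment), "leaves x", alnWidth(x$alignment),
      "columns;", length(x$tree@ids), "tree nodes",
      if (!is.null(x$solubility)) "; solubility planted" else "", "\n")
  invisible(x)
}

#' Planted solubility score of aligned sequences
#'
#' \eqn{score = \sum_w weight_w \cdot 1[\mathrm{symbol}(column_w) =
#' symbol_w]} (no noise); the ground-truth scoring function used both to
#' plant scores on the simulated leaves and to evaluate conditional
#' generations.
#'
#' @param seqs character vector of aligned sequences.
#' @param weights data.frame (column, symbol, weight); columns 1-based in
#'   the current alignment coordinates.
#' @return numeric vector of scores.
#' @export
plantedScore <- function(seqs, weights) {
  m <- seqToInts(seqs)
  sc <- numeric(nrow(m))
  for (k in seq_len(nrow(weights))) {
    sym <- match(weights$symbol[k], AA_ALPHABET)
    sc <- sc + weights$weight[k] * (m[, weights$column[k]] == sym)
  }
  sc
}

#' Plant solubility scores on simulated leaves
#'
#' If the config carries no explicit weights, six core columns are chosen at
#' random and each contributes weight 1 when the leaf carries that column's
#' majority residue; Gaussian noise of sd \code{noiseSd} is added. The
#' resulting scores correlate with clade membership — high-scoring leaves
#' share identifiable sequence features a conditional model can learn.
#'
#' @param sim a \code{"simOutput"}.
#' @param cfg the [simConfig()] (defaults to \code{sim$truth}).
#' @return the \code{"simOutput"} with \code{solubility} (named scores) and
#'   \code{truth$solubilityWeights} filled.
#' @export
plantSolubility <- function(sim, cfg = sim$truth) {
  set.seed(cfg$seed + 2L)
  wts <- cfg$solubilityWeights
  if (is.null(wts)) {
    m <- seqToInts(sim$alignment@seqs)
    cols <- sort(sample.int(ncol(m), 6L))
    sym <- vapply(cols, function(j) {
      tb <- tabulate(m[, j], nbins = 20L)   # majority amino acid, gap excluded
      which.max(tb)
    }, 0L)
    wts <- data.frame(column = cols, symbol = AA_ALPHABET[sym], weight = 1)
  }
  base <- plantedScore(sim$alignment@seqs, wts)
  noise <- stats::rnorm(length(base), 0, cfg$noiseSd)
  sim$solubility <- stats::setNames(base + noise, sim$alignment@ids)
  sim$truth$solubilityWeights <- wts
  sim
}

#' Named deterministic simulation presets
#'
#' \describe{
#'   \item{tiny}{20 leaves x 30 columns, 4 clades — fast unit-test fixture.}
#'   \item{bench}{400 leaves x >= 120 columns, 4 clades, 3 planted coupled
#'     pairs, a few indels, planted solubility — the synthetic benchmark on
#'     which the pipeline's recovery properties are demonstrated.}
#'   \item{deep}{200 leaves x 120 columns, long branches — high divergence.}
#' }
#'
#' @param name one of \code{"tiny"}, \code{"bench"}, \code{"deep"}.
#' @return a \code{"simOutput"} with solubility planted.
#' @export
fixture <- function(name = c("tiny", "bench", "deep")) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = simConfig(nClades = 4L, leavesPerClade = 5L, rootLength = 30L,
                     substitutionRate = 0.3, indelRate = 0, seed = 101L),
    bench = simConfig(nClades = 4L, leavesPerClade = 100L, rootLength = 120L,
                      substitutionRate = 0.3, indelRate = 0.002,
                      coupledPairs = list(
                        list(i = 10L, j = 60L, strength = 0.95),
                        list(i = 25L, j = 90L, strength = 0.95),
                        list(i = 40L, j = 110L, strength = 0.95)),
                      noiseSd = 0.1, seed = 42L),
    deep = simConfig(nClades = 4L, leavesPerClade = 50L, rootLength = 120L,
                     substitutionRate = 0.3, indelRate = 0,
                     branchLengthMean = 0.6, seed = 7L))
  plantSolubility(evolveSequences(simulateTree(cfg), cfg))
}

#' Write all simulation outputs
#'
#' Leaves FASTA, ancestors FASTA, labeled newick, solubility TSV and a truth
#' JSON echoing the full configuration.
#'
#' @param sim a \code{"simOutput"}.
#' @param dir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
writeSimOutput <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, c("leaves.fasta", "ancestors.fasta", "tree.nwk",
                        "solubility.tsv", "truth.json"))
  writeAlignment(sim$alignment, p[1L])
  anc <- setdiff(sim$tree@ids, sim$alignment@ids)
  writeAlignment(sim$tree@sequences[anc], p[2L])
  # rebuild a simTree-shaped list for newick export
  ids <- sim$tree@ids
  par <- sim$tree@parent[ids]
  blen <- sim$tree@depth[ids] -
    ifelse(is.na(par), 0, sim$tree@depth[ifelse(is.na(par), ids, par)])
  names(blen) <- ids
  st <- structure(list(parent = par, blen = blen,
                       ids = ids,
                       leaves = sim$alignment@ids), class = "simTree")
  writeLines(simTreeNewick(st), p[3L])
  if (!is.null(sim$solubility))
    utils::write.table(data.frame(id = names(sim$solubility),
                                  score = unname(sim$solubility)),
                       p[4L], sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(truth, p[5L], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  invisible(p)
}
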