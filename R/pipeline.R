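# Pipeline commands: each run* function wires the lower-level operations
# into one stage of the workflow, writes its artifacts, and emits a
# machine-readable RunReport (JSON) echoing the fully resolved configuration
# and every seed, so any stage can be re-run bit-for-bit from its report.

.componentSeed <- function(seed, component) {
  # expand one global seed into stable per-component seeds
  (as.integer(seed) * 131L + sum(utf8ToInt(component))) %% 2000000000L
}

.runReport <- function(command, config, seeds, metrics, artifacts, path) {
  rep <- list(command = command, config_echo = config, seeds = seeds,
              metrics = metrics, artifact_paths = artifacts,
              version = list(tool = as.character(utils::packageVersion("SeqVAE")),
                             checkpoint_format = 1L),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  rep
}

#' Simulate a synthetic family (pipeline stage)
#'
#' @param outDir output directory.
#' @param preset fixture preset name, or \code{NULL} to use \code{config}.
#' @param config a [simConfig()] when no preset is given.
#' @return the RunReport list (invisibly the files are in \code{outDir}).
#' @export
runSimulate <- function(outDir, preset = "bench", config = NULL) {
  sim <- if (!is.null(preset)) fixture(preset) else
    plantSolubility(evolveSequences(simulateTree(config), config))
  paths <- writeSimOutput(sim, outDir)
  .runReport("simulate",
             config = if (!is.null(preset)) list(preset = preset)
                      else unclass(config),
             seeds = list(sim = sim$truth$seed),
             metrics = list(n_leaves = length(sim$alignment),
                            width = alnWidth(sim$alignment),
                            n_tree_nodes = length(sim$tree@ids)),
             artifacts = as.list(paths),
             file.path(outDir, "report.json"))
}

#' Preprocess an MSA (pipeline stage)
#'
#' read -> filter sequences -> filter columns -> cluster -> hold-out split,
#' in that fixed order, writing the train/positive FASTAs, the column map
#' and the split table.
#'
#' @param msaPath aligned FASTA.
#' @param queryId anchor sequence id.
#' @param outDir output directory.
#' @param maxGapFraction per-sequence gap threshold (default 0.25).
#' @param mode column filtering mode (default query_anchored).
#' @param gapColumnThreshold column gap threshold (NULL = mode default).
#' @param identityThreshold clustering threshold (default 0.9).
#' @param holdoutFraction positive-control fraction (default 0.05).
#' @param seed global seed.
#' @return the RunReport list.
#' @export
runPreprocess <- function(msaPath, queryId, outDir, maxGapFraction = 0.25,
                          mode = "query_anchored", gapColumnThreshold = NULL,
                          identityThreshold = 0.9, holdoutFraction = 0.05,
                          seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  aln <- readAlignment(msaPath, queryId)
  aln <- filterSequences(aln, maxGapFraction)
  fc <- filterColumns(aln, mode, gapColumnThreshold)
  aln2 <- clusterReduce(fc$alignment, identityThreshold,
                        seed = .componentSeed(seed, "cluster"))
  sp <- holdoutSplit(aln2, holdoutFraction,
                     seed = .componentSeed(seed, "holdout"))
  p <- file.path(outDir, c("train.fasta", "positive.fasta", "columns.tsv",
                           "split.tsv"))
  writeAlignment(sp$train, p[1L])
  writeAlignment(sp$positive, p[2L])
  writeColumnMap(fc$columnMap, p[3L])
  writeSplit(sp, p[4L])
  .runReport("preprocess",
             config = list(msaPath = msaPath, queryId = queryId,
                           maxGapFraction = maxGapFraction, mode = mode,
                           gapColumnThreshold = gapColumnThreshold,
                           identityThreshold = identityThreshold,
                           holdoutFraction = holdoutFraction, seed = seed),
             seeds = list(cluster = .componentSeed(seed, "cluster"),
                          holdout = .componentSeed(seed, "holdout")),
             metrics = list(n_input = length(readAlignment(msaPath, queryId)),
                            n_after_filter = length(aln),
                            n_after_cluster = length(aln2),
                            width = alnWidth(sp$train),
                            n_train = length(sp$train),
                            n_positive = length(sp$positive)),
             artifacts = as.list(p),
             file.path(outDir, "report.json"))
}

#' Train a model (pipeline stage)
#'
#' @param trainPath training FASTA (already preprocessed).
#' @param queryId anchor id.
#' @param checkpointPath output checkpoint file.
#' @param tagsPath optional tags TSV for a conditional model.
#' @param latentDim,hiddenWidth,klWeight architecture overrides.
#' @param learningRate,patience,maxEpochs,batchSize,weightDecay training
#'   overrides (see [trainConfig()]).
#' @param seed global seed.
#' @param columnMap optional 0-based column map to embed in the checkpoint.
#' @return the RunReport list.
#' @export
runTrain <- function(trainPath, queryId, checkpointPath, tagsPath = NULL,
                     latentDim = 2L, hiddenWidth = NULL, klWeight = 1,
                     learningRate = 0.001, patience = 3L, maxEpochs = 1000L,
                     batchSize = 128L, weightDecay = "none", seed = 1L,
                     columnMap = NULL) {
  aln <- readAlignment(trainPath, queryId)
  tags <- NULL
  arity <- 0L
  if (!is.null(tagsPath)) {
    df <- utils::read.delim(tagsPath)
    tg <- stats::setNames(df$tag, df$id)
    tags <- tagsForTraining(tg, aln)
    arity <- 3L
  }
  w <- alnWidth(aln)
  cfg <- modelConfig(msaWidth = w,
                     hiddenWidth = if (is.null(hiddenWidth)) w else hiddenWidth,
                     latentDim = latentDim, conditionArity = arity,
                     klWeight = klWeight,
                     seed = .componentSeed(seed, "init"))
  tc <- trainConfig(learningRate = learningRate, patience = patience,
                    maxEpochs = maxEpochs, batchSize = batchSize,
                    weightDecay = weightDecay)
  model <- trainVAE(initModel(cfg), sequences(aln), tags = tags, config = tc,
                    seed = .componentSeed(seed, "train"))
  saveCheckpoint(model, checkpointPath, columnMap = columnMap)
  logPath <- paste0(sub("\\.json$", "", checkpointPath), ".trainlog.tsv")
  utils::write.table(
    data.frame(epoch = seq_len(nrow(model@lossHistory)), model@lossHistory),
    logPath, sep = "\t", quote = FALSE, row.names = FALSE)
  .runReport("train",
             config = list(trainPath = trainPath, queryId = queryId,
                           tagsPath = tagsPath,
                           model = model@config, train = unclass(tc),
                           seed = seed),
             seeds = list(init = cfg$seed,
                          train = .componentSeed(seed, "train")),
             metrics = list(
               epochs = nrow(model@lossHistory),
               final_loss = unname(model@lossHistory[nrow(model@lossHistory),
                                                     "total"]),
               query_reconstruction =
                 queryReconstructionAccuracy(model, querySeq(aln),
                                             tag = if (arity)
                                               tags[[queryId]] else NULL)),
             artifacts = list(checkpointPath, logPath),
             paste0(sub("\\.json$", "", checkpointPath), ".report.json"))
}

#' Evaluate generative capacity and control separation (pipeline stage)
#'
#' @param checkpointPath trained checkpoint.
#' @param trainPath training FASTA.
#' @param positivePath held-out positive FASTA.
#' @param queryId anchor id.
#' @param outDir output directory.
#' @param nGenerated generated-set size for the statistics (default 3000).
#' @param nAccuracySamples latent samples per sequence for reconstruction
#'   accuracy (default 5000).
#' @param threshold control separation cutoff (default 0.5).
#' @param ancestral optional character vector of trajectory designs for the
#'   ancestral control set.
#' @param seed global seed.
#' @param tag 0-based tag for conditional checkpoints.
#' @return the RunReport list.
#' @export
runEvaluate <- function(checkpointPath, trainPath, positivePath, queryId,
                        outDir, nGenerated = 3000L, nAccuracySamples = 5000L,
                        threshold = 0.5, ancestral = character(0), seed = 1L,
                        tag = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  model <- readCheckpoint(checkpointPath)$model
  train <- readAlignment(trainPath, queryId)
  positive <- readAlignment(positivePath)
  gen <- sampleGenerated(model, n = nGenerated,
                         seed = .componentSeed(seed, "generate"),
                         tag = tag)
  inputStats <- siteStats(sequences(train))
  genStats <- siteStats(gen)
  agree <- statsAgreement(inputStats, genStats)
  nControl <- max(1L, round(0.05 * length(train)))
  neg <- negativeControl(train, n = nControl,
                         seed = .componentSeed(seed, "negative"))
  set.seed(.componentSeed(seed, "trainsub"))
  trSub <- sequences(train)[sample.int(length(train), nControl)]
  rep_ <- controlReport(model,
                        sets = list(negative = neg, training = trSub,
                                    positive = sequences(positive),
                                    ancestral = ancestral),
                        threshold = threshold, n = nAccuracySamples,
                        seed = .componentSeed(seed, "accuracy"),
                        tags = if (is.null(tag)) NULL else
                          list(negative = rep(tag, length(neg)),
                               training = rep(tag, length(trSub)),
                               positive = rep(tag, length(positive)),
                               ancestral = rep(tag, length(ancestral))))
  p <- file.path(outDir, c("first_order.tsv", "controls.tsv"))
  writeSiteStats(genStats, p[1L])
  writeControlReport(rep_, p[2L])
  .runReport("evaluate",
             config = list(checkpointPath = checkpointPath,
                           trainPath = trainPath, positivePath = positivePath,
                           nGenerated = nGenerated,
                           nAccuracySamples = nAccuracySamples,
                           threshold = threshold, seed = seed),
             seeds = list(generate = .componentSeed(seed, "generate"),
                          negative = .componentSeed(seed, "negative"),
                          accuracy = .componentSeed(seed, "accuracy")),
             metrics = list(first_order_r = unname(agree["firstOrderR"]),
                            second_order_r = unname(agree["secondOrderR"]),
                            control_means = as.list(stats::setNames(
                              rep_$counts$mean, rep_$counts$set))),
             artifacts = as.list(p),
             file.path(outDir, "report.json"))
}

#' Phylogeny-to-latent-space geometry (pipeline stage)
#'
#' @param checkpointPath trained checkpoint.
#' @param newickPath labeled newick tree.
#' @param nodeFastaPath aligned FASTA covering every node label.
#' @param outDir output directory.
#' @param nTrees number of subsampled replicate trees (default 1 uses the
#'   full tree only).
#' @param subsample nodes per replicate (default 100).
#' @param seed global seed.
#' @param tag 0-based tag for conditional checkpoints.
#' @return the RunReport list.
#' @export
runPhylo <- function(checkpointPath, newickPath, nodeFastaPath, outDir,
                     nTrees = 1L, subsample = 100L, seed = 1L, tag = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  model <- readCheckpoint(checkpointPath)$model
  tree <- readAnnotatedTree(newickPath, nodeFastaPath)
  emb <- embedTree(model, tree, tag = tag)
  corr <- depthOriginCorrelation(tree, emb)
  dir_ <- branchDirectionality(tree, emb)
  writePathMetrics(corr, dir_, file.path(outDir, "paths_full.tsv"), "full")
  fracs <- numeric(0)
  for (k in seq_len(nTrees)) {
    st <- subsampleTree(tree, subsample, seed = .componentSeed(seed, paste0("sub", k)))
    sc <- depthOriginCorrelation(st, emb[st@ids, , drop = FALSE])
    fracs <- c(fracs, mean(sc$r[!is.na(sc$r)] > 0))
  }
  cs <- geometrySummary(corr$r)
  ds <- geometrySummary(dir_$cosine)
  .runReport("phylo",
             config = list(checkpointPath = checkpointPath,
                           newickPath = newickPath, nTrees = nTrees,
                           subsample = subsample, seed = seed),
             seeds = lapply(stats::setNames(seq_len(nTrees),
                                            paste0("sub", seq_len(nTrees))),
                            function(k) .componentSeed(seed, paste0("sub", k))),
             metrics = list(
               fraction_positive_correlation = cs$fractionPositive,
               directionality_mean = ds$mean,
               directionality_fraction_positive = ds$fractionPositive,
               n_paths = sum(!is.na(corr$r)),
               n_undefined = sum(is.na(corr$r)),
               subsample_fraction_positive = as.list(fracs)),
             artifacts = list(file.path(outDir, "paths_full.tsv")),
             file.path(outDir, "report.json"))
}

#' Generate trajectory designs (pipeline stage)
#'
#' @param checkpointPath trained checkpoint.
#' @param trainPath training FASTA (for the closest-training profile).
#' @param queryId anchor id.
#' @param outPrefix output path prefix.
#' @param nIntervals number of line intervals (default 100).
#' @param tag tag name (\code{"LOW"/"MEDIUM"/"HIGH"}) or 0-based index for
#'   conditional checkpoints.
#' @param maxIndels optional FASTA filter.
#' @return the RunReport list.
#' @export
runGenerate <- function(checkpointPath, trainPath, queryId, outPrefix,
                        nIntervals = 100L, tag = NULL, maxIndels = NULL) {
  model <- readCheckpoint(checkpointPath)$model
  train <- readAlignment(trainPath, queryId)
  if (is.character(tag)) tag <- match(tag, SOLUBILITY_TAGS) - 1L
  designs <- generateTrajectory(model, querySeq(train),
                                nIntervals = nIntervals, tag = tag)
  designs <- profileDesigns(designs, train, model)
  paths <- writeDesigns(designs, outPrefix, maxIndels = maxIndels)
  pr <- designs$profile
  .runReport("generate",
             config = list(checkpointPath = checkpointPath,
                           trainPath = trainPath, queryId = queryId,
                           nIntervals = nIntervals, tag = tag,
                           maxIndels = maxIndels),
             seeds = list(),
             metrics = list(
               n_designs = nrow(pr) - 1L,
               query_reconstruction_identity = pr$identity_to_query[1L],
               min_identity_to_query = min(pr$identity_to_query),
               mean_reconstruction_probability =
                 mean(pr$reconstruction_probability)),
             artifacts = as.list(paths),
             paste0(outPrefix, ".report.json"))
}
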