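# Shared fixtures, computed lazily and cached for the whole test run.
# The benchmark model is expensive (a few minutes of training), so every
# test that needs a well-trained model shares one instance.

.fixture_cache <- new.env(parent = emptyenv())

# 400-leaf / ~140-column benchmark family with a trained default VAE
benchFixture <- function() {
  if (is.null(.fixture_cache$bench)) {
    sim <- fixture("bench")
    sp <- holdoutSplit(sim$alignment, 0.05, seed = 11L)
    cfg <- modelConfig(msaWidth = alnWidth(sim$alignment), seed = 3L)
    model <- trainVAE(initModel(cfg), sequences(sp$train),
                      config = trainConfig(maxEpochs = 800L))
    .fixture_cache$bench <- list(sim = sim, split = sp, model = model)
  }
  .fixture_cache$bench
}

# 20-leaf / 30-column family with a lightly trained model: enough for
# shape/determinism/contract tests, cheap to build
tinyFixture <- function() {
  if (is.null(.fixture_cache$tiny)) {
    sim <- fixture("tiny")
    cfg <- modelConfig(msaWidth = alnWidth(sim$alignment), seed = 5L)
    model <- trainVAE(initModel(cfg), sequences(sim$alignment),
                      config = trainConfig(maxEpochs = 60L, batchSize = 20L))
    .fixture_cache$tiny <- list(sim = sim, model = model)
  }
  .fixture_cache$tiny
}

# trained conditional models for the planted-solubility direction check
cvaeFixture <- function(seed) {
  key <- paste0("cvae", seed)
  if (is.null(.fixture_cache[[key]])) {
    b <- benchFixture()
    tags <- binScores(b$sim$solubility)
    ti <- tagsForTraining(tags, b$split$train)
    cfg <- modelConfig(msaWidth = alnWidth(b$split$train),
                       conditionArity = 3L, seed = seed)
    model <- trainVAE(initModel(cfg), sequences(b$split$train), tags = ti,
                      config = trainConfig(maxEpochs = 300L))
    .fixture_cache[[key]] <- list(model = model, tags = tags, tagIdx = ti)
  }
  .fixture_cache[[key]]
}

# deterministic random aligned sequences for oracle tests
randomAlignedSeqs <- function(n, width, seed, gapProb = 0.1) {
  set.seed(seed)
  m <- matrix(sample.int(20L, n * width, replace = TRUE), n, width)
  m[matrix(runif(n * width) < gapProb, n, width)] <- 21L
  vapply(seq_len(n), function(i) paste(AA_ALPHABET[m[i, ]], collapse = ""), "")
}

randomMSA <- function(n, width, seed, gapProb = 0.1) {
  seqs <- randomAlignedSeqs(n, width, seed, gapProb)
  proteinMSA(paste0("s", seq_len(n)), seqs, "s1")
}
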