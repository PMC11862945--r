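test_that("star phylogenies have the configured shape and are seeded", {
  cfg <- simConfig(nClades = 4L, leavesPerClade = 25L, rootLength = 50L,
                   seed = 5L)
  tr <- simulateTree(cfg)
  expect_length(tr$leaves, 100L)
  expect_equal(sum(is.na(tr$parent)), 1L)
  expect_equal(sum(tr$parent == "root", na.rm = TRUE), 4L)
  expect_true(all(tr$blen[names(tr$parent)[which(tr$parent == "root")]] == 1))
  expect_equal(vapply(1:4, function(cl)
    sum(startsWith(tr$leaves, paste0("c", cl, "_l"))), 0L), rep(25L, 4L))

  expect_identical(simTreeNewick(simulateTree(cfg)), simTreeNewick(tr))
})

test_that("zero rates copy the root everywhere; identity decays with rate", {
  cfg0 <- simConfig(nClades = 2L, leavesPerClade = 5L, rootLength = 40L,
                    substitutionRate = 0, indelRate = 0, seed = 3L)
  sim0 <- evolveSequences(simulateTree(cfg0), cfg0)
  seqs <- sequences(sim0$tree)
  expect_true(all(seqs == seqs[["root"]]))

  meanIdent <- function(rate) {
    cfg <- simConfig(nClades = 2L, leavesPerClade = 10L, rootLength = 60L,
                     substitutionRate = rate, indelRate = 0, seed = 3L)
    sim <- evolveSequences(simulateTree(cfg), cfg)
    root <- sequences(sim$tree)[["root"]]
    mean(vapply(sequences(sim$alignment), sequenceIdentity, 0, b = root))
  }
  idents <- vapply(c(0.05, 0.2, 0.5), meanIdent, 0)
  expect_true(all(diff(idents) < 0))
})

test_that("leaf-root identity matches the closed-form per-site expectation", {
  cfg <- simConfig(nClades = 3L, leavesPerClade = 8L, rootLength = 300L,
                   substitutionRate = 0.25, indelRate = 0, seed = 9L)
  sim <- evolveSequences(simulateTree(cfg), cfg)
  root <- sequences(sim$tree)[["root"]]
  d <- nodeDepths(sim$tree)
  for (leaf in sample(sim$alignment@ids, 6L)) {
    pSame <- exp(-0.25 * d[[leaf]]) + (1 - exp(-0.25 * d[[leaf]])) / 19
    # per-site substitute-and-land-back walk; 3 SE binomial bound at 300 sites
    se <- sqrt(pSame * (1 - pSame) / 300)
    obs <- sequenceIdentity(sequences(sim$alignment)[[leaf]], root)
    expect_lt(abs(obs - pSame), max(3 * se, 0.06))
  }
})

test_that("planted couplings dominate the leaf-set covariances", {
  # a high substitution rate saturates ancestry-driven covariances while the
  # strength-1 coupling keeps the planted pair in perfect sync
  cfg <- simConfig(nClades = 4L, leavesPerClade = 50L, rootLength = 90L,
                   substitutionRate = 1.0, indelRate = 0,
                   coupledPairs = list(list(i = 5L, j = 80L, strength = 1)),
                   seed = 13L)
  sim <- evolveSequences(simulateTree(cfg), cfg)
  st <- siteStats(unname(sequences(sim$alignment)))
  mask <- SeqVAE:::.upperPairMask(90L)
  colIdx <- rep(seq_len(90L), each = 21L)
  inPair <- outer(colIdx == 5L, colIdx == 80L, "&")
  maxPair <- max(abs(st$cov[inPair & mask]))
  maxOther <- max(abs(st$cov[mask & !inPair]))
  expect_gt(maxPair, maxOther)
})

test_that("indel events add gap-bearing lineages and global insertion columns", {
  cfg <- simConfig(nClades = 3L, leavesPerClade = 10L, rootLength = 60L,
                   substitutionRate = 0.2, indelRate = 0.01, seed = 21L)
  sim <- evolveSequences(simulateTree(cfg), cfg)
  w <- alnWidth(sim$alignment)
  expect_gte(w, 60L)
  # all node sequences share the widened coordinate system
  expect_true(all(nchar(sequences(sim$tree)) == w))
  # insertion columns are gap-majority (only one lineage carries them)
  if (w > 60L) {
    m <- do.call(rbind, strsplit(unname(sequences(sim$alignment)), ""))
    gapFrac <- colMeans(m == "-")
    expect_gt(max(gapFrac), 0.5)
  }
})

test_that("planted solubility is a reproducible indicator sum plus noise", {
  sim <- fixture("tiny")
  wts <- sim$truth$solubilityWeights
  expect_s3_class(wts, "data.frame")
  # noiseless recomputation by an independent indicator-sum pass
  base <- plantedScore(unname(sequences(sim$alignment)), wts)
  chars <- do.call(rbind, strsplit(unname(sequences(sim$alignment)), ""))
  oracle <- rowSums(vapply(seq_len(nrow(wts)), function(k)
    wts$weight[k] * (chars[, wts$column[k]] == wts$symbol[k]),
    numeric(nrow(chars))))
  expect_equal(base, oracle)
  # the stored scores differ from the noiseless sum only by bounded noise
  resid <- unname(sim$solubility) - base
  expect_lt(max(abs(resid)), 6 * sim$truth$noiseSd)

  # zero weights, zero noise -> all scores zero
  expect_equal(plantedScore(c("AC", "CD"),
                            data.frame(column = integer(0),
                                       symbol = character(0),
                                       weight = numeric(0))),
               c(0, 0))
  expect_equal(plantedScore(c("AKC", "AAC"),
                            data.frame(column = 2L, symbol = "K", weight = 1)),
               c(1, 0))
})

test_that("fixtures are pinned presets with consistent tree/alignment truth", {
  tiny <- fixture("tiny")
  expect_equal(length(tiny$alignment), 20L)
  expect_equal(alnWidth(tiny$alignment), 30L)

  tiny2 <- fixture("tiny")
  expect_identical(sequences(tiny2$alignment), sequences(tiny$alignment))
  expect_identical(tiny2$solubility, tiny$solubility)

  # every leaf appears exactly once; every internal node has a sequence
  expect_setequal(leafIds(tiny$tree), seqIds(tiny$alignment))
  expect_true(all(seqIds(tiny$tree) %in% names(sequences(tiny$tree))))
  expect_equal(queryId(tiny$alignment), "c1_l1")

  expect_error(fixture("nope"))

  deep <- fixture("deep")
  expect_equal(length(deep$alignment), 200L)
  expect_gte(alnWidth(deep$alignment), 120L)
  # longer branches make the deep preset more divergent than the tiny one
  root <- sequences(deep$tree)[["root"]]
  meanDeep <- mean(vapply(sequences(deep$alignment), sequenceIdentity, 0,
                          b = root))
  expect_lt(meanDeep, 0.6)
})

test_that("simulation outputs round-trip through their files", {
  sim <- fixture("tiny")
  dir <- file.path(tempdir(), "simout")
  paths <- writeSimOutput(sim, dir)
  expect_true(all(file.exists(paths)))
  leaves <- readAlignment(paths[1L], "c1_l1")
  expect_equal(sequences(leaves), sequences(sim$alignment))
  tr <- readAnnotatedTree(paths[3L], c(sequences(leaves),
                                       sequences(readAlignment(paths[2L]))))
  expect_setequal(tr@ids, sim$tree@ids)
  expect_equal(nodeDepths(tr)[sim$tree@ids], nodeDepths(sim$tree),
               tolerance = 1e-6)
  sol <- readScores(paths[4L])
  expect_equal(sol, sim$solubility, tolerance = 1e-6)
})
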