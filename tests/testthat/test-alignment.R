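test_that("aligned FASTA parsing enforces the alignment contract", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">q", "ACDEF", ">a", "ACDE-", ">b", "AC-EF"), fa)
  aln <- readAlignment(fa, "q")
  expect_s4_class(aln, "ProteinMSA")
  expect_equal(length(aln), 3L)
  expect_equal(alnWidth(aln), 5L)
  expect_equal(queryId(aln), "q")

  writeLines(c(">q", "ACDEF", ">a", "ACDEFA"), fa)
  expect_error(readAlignment(fa, "q"), "ragged")

  writeLines(c(">a", "ACDEF", ">b", "ACDE-"), fa)
  expect_error(readAlignment(fa, "zzz"), "not found")

  writeLines(c(">q", "ACXEF", ">a", "ACDE-"), fa)
  expect_warning(aln <- readAlignment(fa, "q"), "mapped to gap")
  expect_equal(unname(sequences(aln)[["q"]]), "AC-EF")
})

test_that("sequence filtering drops gappy records but never the query", {
  aln <- proteinMSA(c("q", "a", "b"), c("AAAAA", "AAAAA", "AA---"), "q")
  out <- filterSequences(aln, 0.4)
  expect_equal(seqIds(out), c("q", "a"))

  # threshold 1 is the identity
  expect_equal(seqIds(filterSequences(aln, 1)), seqIds(aln))

  # a query gappier than the threshold survives
  aln2 <- proteinMSA(c("q", "a"), c("A----", "AAAAA"), "q")
  expect_true("q" %in% seqIds(filterSequences(aln2, 0.2)))

  # brute-force oracle on a random fixture, and idempotence
  msa <- randomMSA(50L, 20L, seed = 91L, gapProb = 0.15)
  out <- filterSequences(msa, 0.2)
  expect_equal(sequences(filterSequences(out, 0.2)), sequences(out))
  keptOracle <- vapply(seqIds(msa), function(id) {
    s <- strsplit(sequences(msa)[[id]], "")[[1L]]
    sum(s == "-") / length(s) <= 0.2 || id == "s1"
  }, TRUE)
  expect_equal(seqIds(out), seqIds(msa)[keptOracle])
})

test_that("column filtering is query-anchored and traceable", {
  aln <- proteinMSA(c("q", "a"), c("A-A", "AAA"), "q")
  fc <- filterColumns(aln, "query_anchored", 1.0)
  expect_equal(alnWidth(fc$alignment), 2L)
  expect_equal(fc$columnMap, c(0L, 2L))

  # gapless alignments are untouched in either mode
  aln2 <- proteinMSA(c("q", "a"), c("ACD", "ACD"), "q")
  for (mode in c("query_anchored", "strict")) {
    fc2 <- filterColumns(aln2, mode, 0.1)
    expect_equal(sequences(fc2$alignment), sequences(aln2))
    expect_equal(fc2$columnMap, 0:2)
  }

  # brute-force per-column oracle on a gappy fixture
  msa <- randomMSA(20L, 10L, seed = 7L, gapProb = 0.25)
  fc3 <- filterColumns(msa, "strict", 0.3)
  m <- do.call(rbind, strsplit(unname(sequences(msa)), ""))
  qrow <- m[1L, ]
  keep <- which(qrow != "-" & colMeans(m == "-") <= 0.3)
  expect_equal(fc3$columnMap, keep - 1L)

  # strict output columns are a subset of query-anchored at the same threshold
  a1 <- filterColumns(msa, "query_anchored", 0.3)$columnMap
  a2 <- filterColumns(msa, "strict", 0.3)$columnMap
  expect_true(all(a2 %in% a1))

  # idempotence
  once <- filterColumns(msa, "query_anchored", 0.4)
  twice <- filterColumns(once$alignment, "query_anchored", 0.4)
  expect_equal(sequences(twice$alignment), sequences(once$alignment))
  expect_equal(twice$columnMap, seq_along(once$columnMap) - 1L)

  expect_error(filterColumns(proteinMSA("q", "---", "q"), "strict", 0.5),
               "every column")
})

test_that("greedy clustering collapses redundancy, keeps the query, and is monotone", {
  aln <- proteinMSA(c("q", "a", "b"), c("ACDEF", "AAAAA", "AAAAA"), "q")
  out <- clusterReduce(aln, 0.99, seed = 1L)
  expect_equal(length(out), 2L)
  expect_true("q" %in% seqIds(out))

  # all-distinct sequences at threshold 1.0 stay
  msa <- randomMSA(10L, 30L, seed = 3L, gapProb = 0)
  expect_equal(length(clusterReduce(msa, 1.0, seed = 2L)), 10L)

  # independent scripted greedy pass at a fixed seed
  msa2 <- randomMSA(30L, 15L, seed = 12L, gapProb = 0.05)
  thr <- 0.8
  got <- clusterReduce(msa2, thr, seed = 99L)
  m <- do.call(rbind, strsplit(unname(sequences(msa2)), ""))
  idm <- outer(seq_len(30L), seq_len(30L),
               Vectorize(function(i, j) mean(m[i, ] == m[j, ])))
  set.seed(99L)
  ord <- c(1L, sample(2:30))
  kept <- integer(0)
  for (i in ord) if (!length(kept) || all(idm[i, kept] < thr))
    kept <- c(kept, i)
  expect_equal(seqIds(got), paste0("s", sort(kept)))

  # representative count is non-decreasing in the threshold
  sizes <- vapply(c(0.5, 0.7, 0.9, 1.0),
                  function(th) length(clusterReduce(msa2, th, seed = 99L)), 0L)
  expect_true(all(diff(sizes) >= 0))
})

test_that("one-hot encoding uses the fixed symbol order and round-trips", {
  aln <- proteinMSA("s", "AC-", "s")
  oh <- encodeOneHot(aln)
  expect_equal(dim(oh), c(1L, 3L, 21L))
  expect_equal(which(oh[1, 1, ] == 1L), c(A = 1L))
  expect_equal(which(oh[1, 2, ] == 1L), c(C = 2L))
  expect_equal(which(oh[1, 3, ] == 1L), c(`-` = 21L))
  expect_equal(sum(oh), 3L)

  msa <- randomMSA(100L, 25L, seed = 10L, gapProb = 0.2)
  oh2 <- encodeOneHot(msa)
  expect_equal(sum(oh2), 100L * 25L)
  expect_equal(decodeOneHot(oh2), sequences(msa))
})

test_that("hold-out split is a seeded partition that spares the query", {
  msa <- randomMSA(100L, 10L, seed = 21L)
  sp <- holdoutSplit(msa, 0.05, seed = 4L)
  expect_equal(length(sp$positive), 5L)
  expect_equal(length(sp$train), 95L)
  expect_true("s1" %in% seqIds(sp$train))

  sp2 <- holdoutSplit(msa, 0.05, seed = 4L)
  expect_identical(seqIds(sp2$positive), seqIds(sp$positive))

  msa2 <- randomMSA(200L, 10L, seed = 22L)
  sp3 <- holdoutSplit(msa2, 0.05, seed = 9L)
  expect_length(intersect(seqIds(sp3$train), seqIds(sp3$positive)), 0L)
  expect_setequal(c(seqIds(sp3$train), seqIds(sp3$positive)), seqIds(msa2))

  expect_error(holdoutSplit(randomMSA(5L, 10L, seed = 1L), 0.05, 1L),
               "too small")
})

test_that("profile alignment reproduces query gap placement and an exhaustive oracle", {
  # a family with a fixed gap column: self-alignment recovers the gapped row
  ids <- paste0("s", 1:6)
  seqs <- c("AC-DEF", "AC-DEF", "AC-DEF", "AC-DEY", "AC-DEF", "AC-DEF")
  msa <- proteinMSA(ids, seqs, "s1")
  expect_equal(alignToProfile(msa, "ACDEF"), "AC-DEF")

  # one substitution keeps the same gap placement
  expect_equal(alignToProfile(msa, "ACDKF"), "AC-DKF")

  # exhaustive oracle: every gap placement enumerated on a 5-column profile
  msa2 <- proteinMSA(paste0("t", 1:4),
                     c("AWCDE", "AWCDE", "AWC-E", "AWCDE"), "t1")
  seq <- "WCE"
  prof <- columnProfile(msa2)
  res <- match(strsplit(seq, "")[[1L]], AA_ALPHABET)
  best <- -Inf; bestAln <- NULL
  for (cols in combn(5L, 3L, simplify = FALSE)) {
    sc <- sum(log(prof[cbind(cols, res)])) + (-2) * (5 - 3)
    if (sc > best) {
      best <- sc
      a <- rep("-", 5L); a[cols] <- strsplit(seq, "")[[1L]]
      bestAln <- paste(a, collapse = "")
    }
  }
  expect_equal(alignToProfile(msa2, seq), bestAln)
  expect_equal(nchar(alignToProfile(msa2, seq)), 5L)
})
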