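test_that("pairwise SH hits its bounds and the hand-derived value", {
  same <- makeProfile(c(0.5, 0.5, rep(0, 18)))
  expect_equal(sequenceHarmonyPair(same, same), 1)

  allA <- makeProfile(c(1, rep(0, 19)))
  allC <- makeProfile(c(0, 1, rep(0, 18)))
  expect_equal(sequenceHarmonyPair(allA, allC), 0)

  mixAC <- makeProfile(c(0.5, 0.5, rep(0, 18)))
  expect_equal(sequenceHarmonyPair(allA, mixAC),
               0.5 * (log2(1.5) + 0.5 * log2(3)), tolerance = 1e-12)

  degen <- columnProfile(ProteinAlignment(c(a = "-", b = "-")), 1)
  expect_true(is.na(sequenceHarmonyPair(allA, degen)))
})

test_that("SH is symmetric and bounded on random profile pairs", {
  set.seed(5)
  for (i in 1:200) {
    p <- stats::runif(20); p[sample.int(20, sample(0:15, 1))] <- 0
    q <- stats::runif(20); q[sample.int(20, sample(0:15, 1))] <- 0
    if (sum(p) == 0) p[1] <- 1
    if (sum(q) == 0) q[2] <- 1
    a <- makeProfile(p); b <- makeProfile(q)
    sh <- sequenceHarmonyPair(a, b)
    expect_identical(sh, sequenceHarmonyPair(b, a))
    expect_gte(sh, 0)
    expect_lte(sh, 1)
  }
})

test_that("SH increases monotonically as compositions mix", {
  pA <- c(stats::runif(10) + 0.1, rep(0, 10)); pA <- pA / sum(pA)
  q <- c(rep(0, 10), stats::runif(10) + 0.1); q <- q / sum(q)
  ts <- seq(0, 1, by = 0.05)
  sh <- vapply(ts, function(t)
    sequenceHarmonyPair(makeProfile(pA), makeProfile((1 - t) * q + t * pA)),
    numeric(1))
  expect_equal(sh[1], 0)
  expect_equal(sh[length(sh)], 1)
  expect_true(all(diff(sh) > 0))
})

test_that("one-vs-rest with two groups degenerates to the pairwise score", {
  set.seed(9)
  aln <- randomAlignment(20, 30, gapRate = 0)
  part <- GroupPartition(stats::setNames(rep(c("g1", "g2"), each = 10),
                                         seqIDs(aln)))
  df <- scoreFrame(shScan(aln, part))
  ids <- seqIDs(aln)
  pairwise <- vapply(seq_len(30), function(j)
    sequenceHarmonyPair(columnProfile(aln, j, rows = ids[1:10]),
                        columnProfile(aln, j, rows = ids[11:20])),
    numeric(1))
  expect_equal(df$SH_combined, pairwise, tolerance = 1e-12)
  expect_equal(df$SH_g1, df$SH_g2, tolerance = 1e-12)
})

test_that("a group-private residue drives the combined SH minimum", {
  sim <- generateAlignment(syntheticConfig(
    nGroups = 8, seqsPerGroup = 10, length = 40, nFoldColumns = 0,
    nFunctionColumns = 0, gapRate = 0, seed = 21))
  m <- as.matrix(sim$alignment)
  ## column 13: group G01 fixed to W, everyone else fixed to L
  m[, 13] <- "L"
  m[grepl("^G01_", rownames(m)), 13] <- "W"
  aln <- ProteinAlignment(apply(m, 1, paste0, collapse = ""),
                          ids = rownames(m))
  df <- scoreFrame(shScan(aln, sim$partition))
  expect_equal(which.min(df$SH_combined), 13L)
  expect_equal(df$SH_combined[13], 0)
})

test_that("a column invariant across groups scores SH = 1 everywhere", {
  aln <- ProteinAlignment(c(a = "W", b = "W", c = "W", d = "W"))
  part <- GroupPartition(c(a = "g1", b = "g1", c = "g2", d = "g2"))
  df <- scoreFrame(shScan(aln, part))
  expect_equal(df$SH_g1, 1)
  expect_equal(df$SH_g2, 1)
  expect_equal(df$SH_combined, 1)
})

test_that("groups with fewer than two residues at a column are skipped", {
  aln <- ProteinAlignment(c(a = "A-", b = "A-", c = "AC", d = "AC",
                            e = "AC", f = "AC"))
  part <- GroupPartition(c(a = "g1", b = "g1", c = "g2", d = "g2",
                           e = "g3", f = "g3"))
  df <- scoreFrame(shScan(aln, part, maxGapFraction = 0.5))
  ## column 2: g1 contributes nothing; combined uses g2 and g3
  expect_true(is.na(df$SH_g1[2]))
  expect_false(is.na(df$SH_combined[2]))
  expect_match(df$reason[2], "skipped:g1")
})

test_that("low-SH selection respects cutoff, order and cap", {
  tb <- scoreTableFromScores(1:3, c(0.9, 0.3, 0.5), "SH")
  expect_equal(siteColumns(selectLow(tb, cutoff = 0.4)), 2L)

  all1 <- scoreTableFromScores(1:4, rep(1, 4), "SH")
  expect_length(siteColumns(selectLow(all1, cutoff = 0.4)), 0L)

  many <- scoreTableFromScores(1:5, c(0.1, 0.3, 0.2, 0.05, 0.9), "SH")
  expect_equal(siteColumns(selectLow(many, cutoff = 0.4, n = 2)), c(4L, 1L))
  expect_equal(siteColumns(selectLow(many, cutoff = 0.4, n = NULL)),
               c(4L, 1L, 3L, 2L))
})

test_that("RELIEF weights behave at the analytic limits", {
  ## invariant column -> 0; one private residue per group -> +1
  m <- matrix("A", nrow = 8, ncol = 3)
  m[, 2] <- rep(c("W", "F", "K", "D"), each = 2)  # private per group
  set.seed(1); m[, 3] <- sample(AA, 8, replace = TRUE)
  aln <- ProteinAlignment(apply(m, 1, paste0, collapse = ""),
                          ids = sprintf("s%d", 1:8))
  part <- GroupPartition(stats::setNames(rep(c("g1", "g2", "g3", "g4"),
                                             each = 2), seqIDs(aln)))
  w <- multiRelief(aln, part, nClassPairs = 6, nSamplePairs = 50, seed = 4)
  expect_equal(w[1], 0)
  expect_equal(w[2], 1)
  expect_true(all(w >= -1 & w <= 1))
})

test_that("RELIEF weights are seed-reproducible and centred for null data", {
  set.seed(2)
  aln <- randomAlignment(40, 25, gapRate = 0)
  part <- GroupPartition(stats::setNames(rep(c("g1", "g2"), each = 20),
                                         seqIDs(aln)))
  w1 <- multiRelief(aln, part, nClassPairs = 1, nSamplePairs = 10000,
                    seed = 123)
  w2 <- multiRelief(aln, part, nClassPairs = 1, nSamplePairs = 10000,
                    seed = 123)
  expect_identical(w1, w2)
  ## no group structure: weights within sampling noise of 0
  expect_true(all(abs(w1) < 0.05))
  w3 <- multiRelief(aln, part, nClassPairs = 1, nSamplePairs = 10000,
                    seed = 456)
  expect_false(identical(w1, w3))
  expect_true(all(abs(w3) < 0.05))
  expect_warning(
    multiRelief(aln, part, nClassPairs = 5, nSamplePairs = 10, seed = 1),
    "capped")
})
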