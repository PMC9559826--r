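test_that("generation is fully deterministic given the seed", {
  cfg <- syntheticConfig(nGroups = 3, seqsPerGroup = 5, length = 50,
                         nFoldColumns = 5, nFunctionColumns = 5, seed = 99)
  a <- generateAlignment(cfg)
  b <- generateAlignment(cfg)
  expect_identical(as.matrix(a$alignment), as.matrix(b$alignment))
  expect_identical(foldColumns(a$truth), foldColumns(b$truth))
  expect_identical(a$truth@functionResidues, b$truth@functionResidues)
  c <- generateAlignment(syntheticConfig(nGroups = 3, seqsPerGroup = 5,
                                         length = 50, nFoldColumns = 5,
                                         nFunctionColumns = 5, seed = 100))
  expect_false(identical(as.matrix(a$alignment), as.matrix(c$alignment)))
})

test_that("planted classes are disjoint and sized per the config", {
  sim <- generateAlignment(syntheticConfig(seed = 8))
  expect_length(foldColumns(sim$truth), 30L)
  expect_length(functionColumns(sim$truth), 30L)
  expect_length(intersect(foldColumns(sim$truth),
                          functionColumns(sim$truth)), 0L)
  expect_equal(nSequences(sim$alignment), 160L)
  expect_equal(alignmentLength(sim$alignment), 200L)
  expect_equal(length(groupNames(sim$partition)), 8L)
})

test_that("full conservation without gaps realizes the RE closed form", {
  bg <- swissprotBackground()
  cfg <- syntheticConfig(nGroups = 2, seqsPerGroup = 10, length = 40,
                         nFoldColumns = 6, nFunctionColumns = 0,
                         conservationStrength = 1, gapRate = 0,
                         background = bg, seed = 5)
  sim <- generateAlignment(cfg)
  df <- scoreFrame(reScan(sim$alignment, bg))
  fc <- foldColumns(sim$truth)
  res <- sim$truth@foldResidues[as.character(fc)]
  expect_equal(df$RE[fc], unname(log(1 / backgroundProbs(bg)[res])),
               tolerance = 1e-12)
})

test_that("fully conserved disjoint function columns reach SH = 0", {
  cfg <- syntheticConfig(nGroups = 2, seqsPerGroup = 10, length = 40,
                         nFoldColumns = 0, nFunctionColumns = 6,
                         conservationStrength = 1, gapRate = 0, seed = 6)
  sim <- generateAlignment(cfg)
  df <- scoreFrame(shScan(sim$alignment, sim$partition))
  expect_equal(df$SH_combined[functionColumns(sim$truth)], rep(0, 6))
})

test_that("recovery metrics follow set arithmetic", {
  expect_equal(unname(evaluateRecovery(c(3, 4, 5, 6), c(3, 4, 5, 6))),
               c(1, 1, 1))
  expect_equal(evaluateRecovery(integer(0), c(1, 2))[["recall"]], 0)
  expect_equal(evaluateRecovery(integer(0), c(1, 2))[["precision"]], 0)
  expect_equal(unname(evaluateRecovery(c(1, 2, 3, 4), c(3, 4, 5, 6))),
               c(0.5, 0.5, 0.5))
})

test_that("background-column RE shrinks as group depth grows", {
  meanBgRE <- function(n) {
    cfg <- syntheticConfig(nGroups = 2, seqsPerGroup = n, length = 80,
                           nFoldColumns = 0, nFunctionColumns = 0,
                           gapRate = 0, seed = 31)
    sim <- generateAlignment(cfg)
    mean(scoreFrame(reScan(sim$alignment, cfg@background))$RE)
  }
  res <- vapply(c(20, 80, 320), meanBgRE, numeric(1))
  expect_true(all(diff(res) < 0))
})

test_that("planted classes do not cross-talk between the two selections", {
  sim <- generateAlignment(syntheticConfig(seed = 1))
  re <- reScan(sim$alignment, swissprotBackground())
  sh <- shScan(sim$alignment, sim$partition)
  top <- siteColumns(selectTop(re, n = 30))
  low <- siteColumns(selectLow(sh, cutoff = 0.4, n = 30))
  expect_lte(length(intersect(top, functionColumns(sim$truth))), 2L)
  expect_lte(length(intersect(low, foldColumns(sim$truth))), 2L)
})

test_that("invalid configurations are rejected", {
  expect_error(syntheticConfig(nGroups = 21, seed = 1), "nGroups <= 20")
  expect_error(syntheticConfig(length = 10, nFoldColumns = 8,
                               nFunctionColumns = 8, seed = 1),
               "exceed")
  expect_error(syntheticConfig(conservationStrength = 0, seed = 1),
               "conservationStrength")
})

test_that("truth tables serialize with per-group designated residues", {
  sim <- generateAlignment(syntheticConfig(nGroups = 2, seqsPerGroup = 4,
                                           length = 20, nFoldColumns = 2,
                                           nFunctionColumns = 2, seed = 3))
  f <- tempfile()
  writeTruth(sim$truth, f)
  df <- read.delim(f)
  expect_equal(nrow(df), 4L)
  expect_setequal(df$class, c("fold", "function"))
  expect_true(all(grepl("/", df$designated_residues[df$class == "function"])))
})
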