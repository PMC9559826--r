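test_that("column profiles exclude gaps and 'X' from frequencies", {
  aln <- ProteinAlignment(c(a = "AAAA", b = "AAA-", c = "AC--", d = "C-X-"))
  p1 <- columnProfile(aln, 1)  # A A A C
  expect_equal(profileProbs(p1)[["A"]], 0.75)
  expect_equal(profileProbs(p1)[["C"]], 0.25)
  expect_equal(gapFraction(p1), 0)

  p4 <- columnProfile(aln, 4)  # A - - -
  expect_equal(profileProbs(p4)[["A"]], 1)
  expect_equal(gapFraction(p4), 0.75)

  p3 <- columnProfile(aln, 3)  # A A - X : 'X' counted as gap
  expect_equal(gapFraction(p3), 0.5)
  expect_equal(p3@nEffective, 2L)

  degen <- columnProfile(ProteinAlignment(c(a = "-", b = "-", c = "X")), 1)
  expect_false(isUsable(degen))
  expect_length(profileProbs(degen), 0)

  expect_error(columnProfile(aln, 9), "out of range")
  sub <- columnProfile(aln, 1, rows = c("a", "c"))
  expect_equal(sub@nEffective, 2L)
})

test_that("relative entropy matches closed forms and conventions", {
  unif <- uniformBackground()
  conserved <- makeProfile(c(1, rep(0, 19)))
  expect_equal(relativeEntropy(conserved, unif), log(20), tolerance = 1e-12)
  expect_equal(relativeEntropy(conserved, unif, logBase = "2"),
               log2(20), tolerance = 1e-12)

  mixed <- makeProfile(c(0.75, 0.25, rep(0, 18)))
  expect_equal(relativeEntropy(mixed, unif),
               0.75 * log(15) + 0.25 * log(5), tolerance = 1e-12)

  ## profile equal to background -> 0
  bg <- randomBackground()
  same <- makeProfile(backgroundProbs(bg))
  expect_equal(relativeEntropy(same, bg), 0)

  ## unusable profile -> NA sentinel, never 0
  degen <- columnProfile(ProteinAlignment(c(a = "-", b = "-")), 1)
  expect_true(is.na(relativeEntropy(degen, unif)))
})

test_that("RE is invariant under consistent amino-acid relabeling", {
  set.seed(7)
  for (i in 1:20) {
    p <- stats::runif(20)
    p[sample.int(20, 5)] <- 0
    q <- stats::rexp(20) + 1e-3
    perm <- sample.int(20)
    re1 <- relativeEntropy(makeProfile(p),
                           BackgroundDistribution(stats::setNames(q, AA)))
    re2 <- relativeEntropy(makeProfile(p[perm]),
                           BackgroundDistribution(stats::setNames(q[perm], AA)))
    expect_equal(re1, re2, tolerance = 1e-12)
  }
})

test_that("base-2 scores equal natural-log scores divided by ln 2", {
  set.seed(11)
  aln <- randomAlignment(30, 50)
  bg <- swissprotBackground()
  reE <- scoreFrame(reScan(aln, bg, logBase = "e"))$RE
  re2 <- scoreFrame(reScan(aln, bg, logBase = "2"))$RE
  expect_equal(re2, reE / log(2), tolerance = 1e-12)
})

test_that("the scan applies the gap policy and flags excluded columns", {
  aln <- ProteinAlignment(c(a = "AA-", b = "AC-", c = "A--", d = "A--",
                            e = "A--"))
  tb <- reScan(aln, uniformBackground(), maxGapFraction = 0.5)
  df <- scoreFrame(tb)
  expect_equal(nrow(df), 3L)
  expect_true(df$usable[1])
  expect_false(df$usable[2])  # 60% gaps
  expect_equal(df$reason[2], "gap_fraction_exceeds_max")
  expect_true(is.na(df$RE[2]))
  expect_equal(df$reason[3], "no_residues")
  expect_true(is.na(df$RE[3]))
})

test_that("a planted invariant column attains the maximum RE", {
  set.seed(3)
  aln <- randomAlignment(40, 60, gapRate = 0.02)
  m <- as.matrix(aln)
  m[, 17] <- "W"
  planted <- ProteinAlignment(apply(m, 1, paste0, collapse = ""),
                              ids = rownames(m))
  df <- scoreFrame(reScan(planted, swissprotBackground()))
  expect_equal(which.max(df$RE), 17L)
})

test_that("top-N selection ranks scores with index tie-breaks", {
  tb <- scoreTableFromScores(1:3, c(1, 3, 2), "RE")
  expect_equal(siteColumns(selectTop(tb, n = 2)), c(2L, 3L))

  ties <- scoreTableFromScores(1:3, c(2, 2, 1), "RE")
  expect_equal(siteColumns(selectTop(ties, n = 1)), 1L)

  expect_error(selectTop(tb, n = 4), "selection-size")
  cr <- siteCriterion(selectTop(tb, n = 2))
  expect_equal(cr$statistic, "RE")
  expect_equal(cr$n, 2L)
})
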