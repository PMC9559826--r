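test_that("FASTA parsing validates shape, ids and alphabet", {
  f <- writeFastaTmp(c(s1 = "ACD-", s2 = "AC-E"))
  aln <- readAlignment(f)
  expect_s4_class(aln, "ProteinAlignment")
  expect_equal(alignmentLength(aln), 4L)
  expect_equal(nSequences(aln), 2L)
  expect_equal(seqIDs(aln), c("s1", "s2"))

  ragged <- writeFastaTmp(c(a = "ACDE", b = "ACDEF"))
  expect_error(readAlignment(ragged), "not rectangular.*'b'")

  dup <- writeFastaTmp(c(a = "ACDE", a = "ACDE"))
  expect_error(readAlignment(dup), "duplicate sequence identifier")

  badchar <- writeFastaTmp(c(a = "ACDB", b = "ACDE"))
  expect_error(readAlignment(badchar), "illegal character 'B'.*column 4")
})

test_that("input is normalized to uppercase with '-' gaps", {
  f <- writeFastaTmp(c(a = "acd.", b = "AC-e"))
  aln <- readAlignment(f)
  expect_equal(unname(alignedSequences(aln)), c("ACD-", "AC-E"))
})

test_that("Stockholm files parse with '.' gaps rewritten", {
  f <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0",
               "#=GF ID test",
               "s1 ACD.",
               "s2 AC-E",
               "",
               "s1 GH",
               "s2 GH",
               "//"), f)
  aln <- readAlignment(f)  # format sniffed from the header line
  expect_equal(unname(alignedSequences(aln)), c("ACD-GH", "AC-EGH"))
  expect_false(any(as.matrix(aln) == "."))
})

test_that("alignment round-trips through FASTA exactly", {
  set.seed(42)
  aln <- randomAlignment(12, 40)
  f <- tempfile(fileext = ".fasta")
  writeAlignment(aln, f)
  back <- readAlignment(f)
  expect_identical(seqIDs(back), seqIDs(aln))
  expect_identical(alignedSequences(back), alignedSequences(aln))
})

test_that("group tables form complete partitions over the alignment", {
  aln <- ProteinAlignment(c(a = "AC", b = "AC", c = "AC", d = "AC"))
  f <- tempfile()
  writeLines(c("id\tgroup", "a\tTHR", "b\tTHR", "c\tRAR", "d\tRAR"), f)
  part <- readGroups(f, aln)
  expect_equal(groupNames(part), c("THR", "RAR"))
  expect_equal(unname(groupOf(part)), c("THR", "THR", "RAR", "RAR"))

  incomplete <- tempfile()
  writeLines(c("a\tTHR", "b\tTHR", "c\tRAR"), incomplete)
  expect_error(readGroups(incomplete, aln), "incomplete partition.*d")

  extra <- tempfile()
  writeLines(c("a\tTHR", "b\tTHR", "c\tRAR", "d\tRAR", "zz\tVDR"), extra)
  expect_warning(part2 <- readGroups(extra, aln), "ignoring 1")
  expect_equal(groupNames(part2), c("THR", "RAR"))
})

test_that("the eight THR-like subfamily labels are carried through", {
  labs <- c("THR", "RAR", "VDR", "LXR", "PPAR", "Rev", "ROR", "E78c")
  ids <- sprintf("s%02d", 1:16)
  aln <- ProteinAlignment(stats::setNames(rep("ACDE", 16), ids))
  f <- tempfile()
  writeLines(paste(ids, rep(labs, each = 2), sep = "\t"), f)
  part <- readGroups(f, aln)
  expect_equal(groupNames(part), labs)
  expect_equal(length(groupNames(part)), 8L)
})

test_that("group round-trip preserves the partition", {
  part <- GroupPartition(c(a = "X1", b = "X1", c = "X2"))
  f <- tempfile()
  writeGroups(part, f)
  aln <- ProteinAlignment(c(a = "AA", b = "AA", c = "AA"))
  back <- readGroups(f, aln)
  expect_identical(groupOf(back), groupOf(part))
})
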