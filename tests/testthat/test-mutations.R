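test_that("mutation tokens parse per the clinical grammar", {
  p <- parseMutation("R429Q/W")
  expect_equal(p$wild_type, "R")
  expect_equal(p$position, 429L)
  expect_equal(p$alternates, c("Q", "W"))
  expect_false(p$is_deletion)

  d <- parseMutation("Del337T")
  expect_true(d$is_deletion)
  expect_equal(d$wild_type, "T")
  expect_equal(d$position, 337L)
  expect_length(d$alternates, 0L)

  s <- parseMutation("A263S")
  expect_equal(s[c("wild_type", "position")], list(wild_type = "A",
                                                   position = 263L))
  expect_equal(s$alternates, "S")

  expect_error(parseMutation(""), "non-empty")
  expect_error(parseMutation("not a mutation"), "unparseable")
  expect_error(parseMutation("429Q"), "unparseable")
})

test_that("formatting a parsed token reproduces it (fixture-wide)", {
  toks <- thrMutations()$mutation
  expect_identical(vapply(toks, function(t) formatMutation(parseMutation(t)),
                          character(1), USE.NAMES = FALSE), toks)
})

test_that("classification follows site-set membership", {
  fold <- SpecSites:::SiteSet(c(363L, 506L))
  fun <- SpecSites:::SiteSet(c(363L, 484L))
  rec <- data.frame(receptor = c("THRB", "THRA", "VDR", "RORA"),
                    mutation = c("L346F", "N359Y", "R391C", "Q999X"),
                    position = c(346L, 359L, 391L, 999L),
                    alignment_position = c(363L, 484L, 506L, 9999L),
                    stringsAsFactors = FALSE)
  out <- classifyMutations(rec, fold, fun)
  expect_equal(out$classification,
               c("Fold/Function", "Function", "Fold", "Unclassified"))
})

test_that("positions resolve through a residue map when absent", {
  aln <- ProteinAlignment(c(ref = "AC-DF", x = "ACQDF"))
  map <- mapColumnsToResidues(aln, "ref", 100)
  rec <- data.frame(receptor = "X", mutation = "A100C", position = 100L,
                    alignment_position = NA_integer_,
                    stringsAsFactors = FALSE)
  out <- classifyMutations(rec, SpecSites:::SiteSet(1L),
                           SpecSites:::SiteSet(integer(0)), map = map)
  expect_equal(out$alignment_position, 1L)
  expect_equal(out$classification, "Fold")

  bad <- data.frame(receptor = "X", mutation = "A9C", position = 9L,
                    alignment_position = NA_integer_,
                    stringsAsFactors = FALSE)
  expect_warning(out2 <- classifyMutations(bad, SpecSites:::SiteSet(1L),
                                           SpecSites:::SiteSet(integer(0)),
                                           map = map),
                 "resolvable")
  expect_equal(out2$classification, "Unresolved")
})

test_that("classification partitions the resolvable records", {
  rec <- thrMutations()
  ## site sets reconstructed from the curated labels: the rule should
  ## reproduce the labels exactly (round trip)
  foldSet <- SpecSites:::SiteSet(sort(unique(rec$alignment_position[
    rec$reported_classification %in% c("Fold", "Fold/Function")])))
  funSet <- SpecSites:::SiteSet(sort(unique(rec$alignment_position[
    rec$reported_classification %in% c("Function", "Fold/Function")])))
  out <- classifyMutations(rec, foldSet, funSet)
  expect_identical(out$classification, rec$reported_classification)
  tal <- tallyMutations(out, "classification")
  expect_equal(sum(tal$n_records), nrow(rec))
  expect_true(all(out$classification %in%
                    c("Fold", "Function", "Fold/Function")))
})

test_that("tallies count receptors, positions and motifs", {
  rec <- thrMutations()
  expect_equal(nrow(rec), 47L)

  byPos <- tallyMutations(rec, "alignment_position")
  expect_equal(byPos$n_receptors[byPos$alignment_position == 363], 3L)
  expect_equal(byPos$n_records[byPos$alignment_position == 523], 2L)
  expect_equal(byPos$n_receptors[byPos$alignment_position == 523], 1L)

  byRec <- tallyMutations(rec, "receptor")
  expect_equal(byRec$n_records[byRec$receptor == "THRB"], 27L)
  expect_equal(sum(byRec$n_records), 47L)

  byMotif <- tallyMutations(rec, "motif")
  expect_true("Motif A" %in% byMotif$motif)  # positions 207-216 occur
  expect_true("none" %in% byMotif$motif)

  empty <- tallyMutations(rec[0, ], "receptor")
  expect_equal(nrow(empty), 0L)
})
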