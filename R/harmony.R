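## Sequence Harmony (function-specificity) and RELIEF-style weighting.
##
## Sequence Harmony compares the amino-acid composition of two sequence
## groups at one column. We use the symmetrized, base-2, sign-corrected
## form
##
##     SH(A,B) = 1/2 * ( H(A|B) + H(B|A) ),
##     H(A|B)  = - sum_x p^A(x) * log2( p^A(x) / (p^A(x) + p^B(x)) ),
##
## which lies in [0, 1]: 1 when the two compositions are identical, 0
## when their residue supports are disjoint. Low combined SH marks a
## column that is differentially conserved between subfamilies, i.e. a
## candidate specificity-determining position.

#' Sequence Harmony between two column profiles
#'
#' Symmetric in its arguments; zero-probability terms contribute 0. An
#' unusable profile on either side yields \code{NA}.
#'
#' @param profileA,profileB [ColumnProfile-class] objects for the same
#'   column in two sequence groups.
#' @return SH score in [0, 1], or \code{NA}.
#' @examples
#' aln <- ProteinAlignment(c(a = "A", b = "A", c = "A", d = "C"))
#' pA <- columnProfile(aln, 1, rows = c("a", "b"))
#' pB <- columnProfile(aln, 1, rows = c("c", "d"))
#' sequenceHarmonyPair(pA, pB)
#' @export
sequenceHarmonyPair <- function(profileA, profileB) {
  stopifnot(methods::is(profileA, "ColumnProfile"),
            methods::is(profileB, "ColumnProfile"))
  if (!isUsable(profileA) || !isUsable(profileB)) return(NA_real_)
  pA <- profileA@probs
  pB <- profileB@probs
  h <- function(p, q) {
    i <- p > 0
    -sum(p[i] * log2(p[i] / (p[i] + q[i])))
  }
  sh <- 0.5 * (h(pA, pB) + h(pB, pA))
  min(max(sh, 0), 1)
}

## Vectorized SH over all columns from two 20 x L count matrices.
## Returns NA where either side has fewer than minPerGroup residues.
.shFromCounts <- function(cntA, nA, cntB, nB, minPerGroup = 2L) {
  PA <- sweep(cntA, 2L, pmax(nA, 1), "/")
  PB <- sweep(cntB, 2L, pmax(nB, 1), "/")
  MA <- PA / (PA + PB)
  MA[PA == 0] <- 1                    # 0 * log2(1) = 0 by convention
  MB <- PB / (PA + PB)
  MB[PB == 0] <- 1
  sh <- -0.5 * (colSums(PA * log2(MA)) + colSums(PB * log2(MB)))
  sh <- pmin(pmax(sh, 0), 1)
  sh[nA < minPerGroup | nB < minPerGroup] <- NA_real_
  sh
}

#' Scan all columns for multi-group Sequence Harmony
#'
#' For the default \code{one_vs_rest} scheme, each group's column
#' composition is compared with the pooled composition of all other rows,
#' giving one SH value per group per column; the combined score is the
#' minimum over groups (the most subfamily-specific signal). The
#' \code{pairwise_min} alternative takes the minimum over all group
#' pairs. A group contributing fewer than two residues at a column is
#' skipped there (noted in the reason field); the combined score then
#' uses the remaining groups. Columns failing the gap policy are
#' excluded with \code{NA} scores.
#'
#' @param alignment a [ProteinAlignment-class].
#' @param partition a [GroupPartition-class] with at least two groups.
#' @param scheme \code{"one_vs_rest"} (default) or \code{"pairwise_min"}.
#' @param maxGapFraction exclusion threshold on the per-column gap/'X'
#'   fraction (default 0.5).
#' @return A [ScoreTable-class] with per-group \code{SH_<group>} columns
#'   (or per-pair columns for \code{pairwise_min}) and
#'   \code{SH_combined}.
#' @export
shScan <- function(alignment, partition,
                   scheme = c("one_vs_rest", "pairwise_min"),
                   maxGapFraction = 0.5) {
  stopifnot(methods::is(alignment, "ProteinAlignment"),
            methods::is(partition, "GroupPartition"))
  scheme <- match.arg(scheme)
  groups <- groupNames(partition)
  if (length(groups) < 2L)
    stop("Sequence Harmony requires at least two groups")
  ids <- seqIDs(alignment)
  missing <- setdiff(ids, seqIDs(partition))
  if (length(missing))
    stop("partition lacks label(s) for: ", paste(missing, collapse = ", "))
  m <- alignment@mat
  L <- ncol(m)
  lab <- groupOf(partition)[ids]

  cnt <- lapply(groups, function(g)
    .columnCounts(m[lab == g, , drop = FALSE]))
  names(cnt) <- groups
  nEff <- lapply(cnt, colSums)
  total <- Reduce(`+`, cnt)
  nTot <- colSums(total)

  gapm <- m == GAP_CHAR | m == UNKNOWN_CHAR
  gapFrac <- colMeans(gapm)
  colOK <- gapFrac <= maxGapFraction & nTot > 0

  shCols <- list()
  if (scheme == "one_vs_rest") {
    for (g in groups) {
      rest <- total - cnt[[g]]
      shCols[[paste0("SH_", g)]] <-
        .shFromCounts(cnt[[g]], nEff[[g]], rest, colSums(rest))
    }
  } else {
    pairs <- utils::combn(groups, 2L, simplify = FALSE)
    for (p in pairs) {
      shCols[[paste0("SH_", p[1L], "_vs_", p[2L])]] <-
        .shFromCounts(cnt[[p[1L]]], nEff[[p[1L]]],
                      cnt[[p[2L]]], nEff[[p[2L]]])
    }
  }
  shMat <- do.call(cbind, shCols)
  shMat[!colOK, ] <- NA_real_
  allNA <- rowSums(!is.na(shMat)) == 0L
  combined <- rep(NA_real_, L)
  combined[!allNA] <- apply(shMat[!allNA, , drop = FALSE], 1L, min,
                            na.rm = TRUE)
  usable <- colOK & !is.na(combined)

  reason <- rep("", L)
  reason[gapFrac > maxGapFraction] <- "gap_fraction_exceeds_max"
  reason[nTot == 0] <- "no_residues"
  partial <- colOK & !allNA & rowSums(is.na(shMat)) > 0L
  if (any(partial)) {
    skipped <- apply(is.na(shMat[partial, , drop = FALSE]), 1L, function(z)
      paste(sub("^SH_", "", colnames(shMat))[z], collapse = ","))
    reason[partial] <- paste0("skipped:", skipped)
  }
  reason[colOK & allNA & nTot > 0] <- "insufficient_group_coverage"

  df <- data.frame(column = seq_len(L), gap_fraction = gapFrac,
                   stringsAsFactors = FALSE)
  for (cn in colnames(shMat)) df[[cn]] <- shMat[, cn]
  df$SH_combined <- combined
  df$usable <- usable
  df$reason <- reason
  ScoreTable(df, metadata = list(statistic = "SH", scheme = scheme,
                                 max_gap_fraction = maxGapFraction,
                                 groups = paste(groups, collapse = ",")))
}

#' Select low-SH (function-specific) columns
#'
#' Returns the usable columns whose combined SH falls strictly below the
#' cutoff, sorted ascending by score (most specific first), ties broken
#' by ascending column index, optionally capped at the \code{n} lowest.
#' An empty selection is permitted.
#'
#' @param table a [ScoreTable-class] with \code{SH_combined} filled.
#' @param cutoff SH cutoff (default 0.4).
#' @param n optional cap on the number of selected columns (default 30;
#'   use \code{NULL} for no cap).
#' @return A [SiteSet-class].
#' @examples
#' tb <- scoreTableFromScores(1:3, c(0.9, 0.3, 0.5), "SH")
#' siteColumns(selectLow(tb))
#' @export
selectLow <- function(table, cutoff = 0.4, n = 30) {
  stopifnot(methods::is(table, "ScoreTable"))
  df <- table@scores
  if (!"SH_combined" %in% colnames(df))
    stop("score table has no SH_combined column; run shScan() first")
  ok <- df$usable & !is.na(df$SH_combined) & df$SH_combined < cutoff
  sub <- df[ok, c("column", "SH_combined")]
  ord <- order(sub$SH_combined, sub$column)
  cols <- sub$column[ord]
  if (!is.null(n)) cols <- utils::head(cols, as.integer(n))
  SiteSet(cols, criterion = list(statistic = "SH_combined", type = "low",
                                 cutoff = cutoff,
                                 n = if (is.null(n)) NA_integer_
                                     else as.integer(n)))
}

#' RELIEF-style per-column feature weights
#'
#' A sampling-based weight for how well each column separates the groups,
#' in the spirit of the RELIEF family of feature-weighting methods. For
#' each of \code{nClassPairs} sampled group pairs, \code{nSamplePairs}
#' within-group sequence pairs ("hits") and \code{nSamplePairs}
#' between-group pairs ("misses") are drawn; a column's round weight is
#' the fraction of miss pairs with differing characters minus the
#' fraction of hit pairs with differing characters (identity metric;
#' gaps compare as an ordinary character). The final weight is the mean
#' over rounds, in [-1, 1]: an invariant column scores 0, a column with a
#' private residue per group approaches +1. Fully deterministic given
#' \code{seed}; the caller's RNG state is untouched.
#'
#' @param alignment a [ProteinAlignment-class].
#' @param partition a [GroupPartition-class] (>= 2 groups, each of size
#'   >= 2).
#' @param nClassPairs number of group-pair rounds (capped, with a
#'   warning, at the number of available pairs; default 10).
#' @param nSamplePairs hit and miss pairs sampled per round (default 200).
#' @param seed RNG seed (required).
#' @return Numeric vector of per-column weights in [-1, 1].
#' @export
multiRelief <- function(alignment, partition, nClassPairs = 10,
                        nSamplePairs = 200, seed) {
  stopifnot(methods::is(alignment, "ProteinAlignment"),
            methods::is(partition, "GroupPartition"))
  if (missing(seed)) stop("multiRelief() requires an explicit seed")
  groups <- groupNames(partition)
  if (length(groups) < 2L) stop("RELIEF weighting requires >= 2 groups")
  ids <- seqIDs(alignment)
  lab <- groupOf(partition)[ids]
  rowsByGroup <- split(seq_along(ids), factor(lab, levels = groups))
  sizes <- lengths(rowsByGroup)
  if (any(sizes < 2L))
    stop("every group needs >= 2 sequences for hit sampling: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  m <- alignment@mat
  L <- ncol(m)
  allPairs <- utils::combn(length(groups), 2L, simplify = FALSE)
  nClassPairs <- as.integer(nClassPairs)
  if (nClassPairs > length(allPairs)) {
    warning(sprintf("nClassPairs capped at %d available group pairs",
                    length(allPairs)))
    nClassPairs <- length(allPairs)
  }
  nSamplePairs <- as.integer(nSamplePairs)

  ## uniform distinct pair within a set of k indices
  distinctPairs <- function(rows, n) {
    k <- length(rows)
    a <- sample.int(k, n, replace = TRUE)
    b <- sample.int(k - 1L, n, replace = TRUE)
    b <- b + (b >= a)
    cbind(rows[a], rows[b])
  }

  .withSeed(seed, {
    pick <- sample.int(length(allPairs), nClassPairs, replace = FALSE)
    wsum <- numeric(L)
    for (r in pick) {
      g1 <- rowsByGroup[[allPairs[[r]][1L]]]
      g2 <- rowsByGroup[[allPairs[[r]][2L]]]
      ## hits: within-group pairs, group drawn at random per sample
      fromG1 <- sample(c(TRUE, FALSE), nSamplePairs, replace = TRUE)
      h1 <- distinctPairs(g1, sum(fromG1))
      h2 <- distinctPairs(g2, sum(!fromG1))
      hits <- rbind(h1, h2)
      ## misses: one sequence from each group
      miss <- cbind(g1[sample.int(length(g1), nSamplePairs, replace = TRUE)],
                    g2[sample.int(length(g2), nSamplePairs, replace = TRUE)])
      hitDiff <- colSums(m[hits[, 1L], , drop = FALSE] !=
                           m[hits[, 2L], , drop = FALSE])
      missDiff <- colSums(m[miss[, 1L], , drop = FALSE] !=
                            m[miss[, 2L], , drop = FALSE])
      wsum <- wsum + (missDiff - hitDiff) / nSamplePairs
    }
    wsum / nClassPairs
  })
}

#' Merge RE, SH and RELIEF results into one score table
#'
#' Combines score tables computed on the same alignment into a single
#' table keyed by column, keeping each statistic's exclusion flags
#' (scores excluded by one statistic's policy stay \code{NA} there).
#'
#' @param reTable [ScoreTable-class] from [reScan()] (or \code{NULL}).
#' @param shTable [ScoreTable-class] from [shScan()] (or \code{NULL}).
#' @param mrWeights optional numeric vector from [multiRelief()].
#' @return A merged [ScoreTable-class].
#' @export
combineScoreTables <- function(reTable = NULL, shTable = NULL,
                               mrWeights = NULL) {
  tabs <- Filter(Negate(is.null), list(reTable, shTable))
  if (!length(tabs)) stop("at least one score table is required")
  for (tb in tabs) stopifnot(methods::is(tb, "ScoreTable"))
  n <- unique(vapply(tabs, function(tb) nrow(tb@scores), integer(1)))
  if (length(n) != 1L)
    stop("score tables cover different numbers of columns")
  base <- tabs[[1L]]@scores
  df <- data.frame(column = base$column, gap_fraction = base$gap_fraction,
                   stringsAsFactors = FALSE)
  usable <- rep(FALSE, n)
  reasons <- rep("", n)
  for (tb in tabs) {
    sc <- tb@scores
    keep <- setdiff(colnames(sc),
                    c("column", "gap_fraction", "usable", "reason"))
    for (cn in keep) df[[cn]] <- sc[[cn]]
    usable <- usable | sc$usable
    reasons <- ifelse(nzchar(reasons) | !nzchar(sc$reason), reasons,
                      sc$reason)
  }
  if (!is.null(mrWeights)) {
    if (length(mrWeights) != n)
      stop("RELIEF weight vector length does not match the table")
    df$MR_weight <- mrWeights
  }
  df$usable <- usable
  df$reason <- reasons
  md <- do.call(c, lapply(tabs, function(tb) tb@metadata))
  md <- md[!duplicated(names(md))]
  ScoreTable(df, metadata = md)
}
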