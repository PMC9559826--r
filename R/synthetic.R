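## Synthetic benchmark alignments with planted column classes.
##
## The generator emulates the statistical structure the two column
## statistics are designed to detect in a subfamily-partitioned family
## alignment: "fold" columns conserved across all groups (one designated
## residue, emitted with the conservation strength everywhere), "function"
## columns with a distinct designated residue per group (conserved within
## each group, disjoint between groups), and i.i.d. background columns.
## Gaps are injected uniformly per cell. Columns are exchangeable given
## their class; no phylogenetic correlation is simulated.

#' Configure the synthetic alignment generator
#'
#' Defaults describe the benchmark conditions: 8 subfamilies of 20
#' sequences, 200 columns with 30 planted fold and 30 planted function
#' columns, conservation strength 0.95, gap rate 0.02, Swiss-Prot
#' background.
#'
#' @param nGroups number of subfamilies.
#' @param seqsPerGroup sequences per subfamily.
#' @param length alignment length.
#' @param nFoldColumns planted globally conserved columns.
#' @param nFunctionColumns planted subfamily-specific columns.
#' @param conservationStrength probability the designated residue is
#'   emitted at a planted column, in (0, 1].
#' @param gapRate i.i.d. per-cell gap probability, in [0, 1).
#' @param background [BackgroundDistribution-class] for background draws.
#' @param seed RNG seed.
#' @return A [SyntheticConfig-class].
#' @examples
#' syntheticConfig(seed = 1)
#' @export
syntheticConfig <- function(nGroups = 8, seqsPerGroup = 20, length = 200,
                            nFoldColumns = 30, nFunctionColumns = 30,
                            conservationStrength = 0.95, gapRate = 0.02,
                            background = swissprotBackground(), seed = 1) {
  methods::new("SyntheticConfig",
               nGroups = as.integer(nGroups),
               seqsPerGroup = as.integer(seqsPerGroup),
               length = as.integer(length),
               nFoldColumns = as.integer(nFoldColumns),
               nFunctionColumns = as.integer(nFunctionColumns),
               conservationStrength = as.numeric(conservationStrength),
               gapRate = as.numeric(gapRate),
               background = background,
               seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %d groups x %d seqs, length %d (%d fold + %d function planted)\n",
    object@nGroups, object@seqsPerGroup, object@length,
    object@nFoldColumns, object@nFunctionColumns))
  cat(sprintf("  conservation %.2f, gap rate %.3f, seed %d\n",
              object@conservationStrength, object@gapRate, object@seed))
})

#' Planted truth accessors
#'
#' @param x a \code{SyntheticTruth}.
#' @return Integer column indices of the planted fold-specific
#'   (\code{foldColumns}) or function-specific (\code{functionColumns})
#'   columns.
#' @export
setGeneric("foldColumns", function(x) standardGeneric("foldColumns"))

#' @rdname foldColumns
#' @export
setMethod("foldColumns", "SyntheticTruth", function(x) x@foldColumns)

#' @rdname foldColumns
#' @export
setGeneric("functionColumns", function(x) standardGeneric("functionColumns"))

#' @rdname foldColumns
#' @export
setMethod("functionColumns", "SyntheticTruth", function(x) x@functionColumns)

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d fold columns, %d function columns\n",
              length(object@foldColumns), length(object@functionColumns)))
})

#' Generate a labeled synthetic alignment with planted columns
#'
#' Fully deterministic given the config seed; the caller's RNG state is
#' untouched. Fold columns draw one designated residue per column from
#' the background and emit it with the conservation strength in every
#' sequence (background draw otherwise). Function columns assign each
#' group a distinct designated residue (sampled uniformly without
#' replacement) and emit it with the conservation strength within the
#' group. Remaining columns are i.i.d. background. Gaps are then
#' injected i.i.d. at the gap rate.
#'
#' @param config a [SyntheticConfig-class].
#' @return List with elements \code{alignment}
#'   ([ProteinAlignment-class]), \code{partition}
#'   ([GroupPartition-class]) and \code{truth}
#'   ([SyntheticTruth-class]).
#' @examples
#' sim <- generateAlignment(syntheticConfig(nGroups = 2, seqsPerGroup = 4,
#'                                          length = 20, nFoldColumns = 3,
#'                                          nFunctionColumns = 3, seed = 7))
#' sim$truth
#' @export
generateAlignment <- function(config) {
  stopifnot(methods::is(config, "SyntheticConfig"))
  methods::validObject(config)
  K <- config@nGroups
  S <- config@seqsPerGroup
  L <- config@length
  N <- K * S
  p <- config@background@probs
  strength <- config@conservationStrength

  groupLabels <- sprintf("G%02d", seq_len(K))
  ids <- as.vector(vapply(seq_len(K), function(g)
    sprintf("%s_S%03d", groupLabels[g], seq_len(S)), character(S)))
  rowGroup <- rep(groupLabels, each = S)

  .withSeed(config@seed, {
    cols <- sample.int(L, config@nFoldColumns + config@nFunctionColumns)
    foldCols <- sort(cols[seq_len(config@nFoldColumns)])
    funCols <- sort(cols[config@nFoldColumns + seq_len(config@nFunctionColumns)])

    drawBg <- function(n) sample(AA20, n, replace = TRUE, prob = p)
    m <- matrix(drawBg(N * L), nrow = N, ncol = L)

    foldRes <- character(0)
    if (length(foldCols)) {
      foldRes <- stats::setNames(drawBg(length(foldCols)),
                                 as.character(foldCols))
      for (i in seq_along(foldCols)) {
        emit <- stats::runif(N) < strength
        m[emit, foldCols[i]] <- foldRes[[i]]
      }
    }
    funRes <- list()
    for (j in seq_along(funCols)) {
      des <- stats::setNames(sample(AA20, K), groupLabels)
      funRes[[as.character(funCols[j])]] <- des
      emit <- stats::runif(N) < strength
      m[emit, funCols[j]] <- des[rowGroup[emit]]
    }
    if (config@gapRate > 0) {
      gap <- stats::runif(N * L) < config@gapRate
      m[matrix(gap, nrow = N)] <- GAP_CHAR
    }
    rownames(m) <- ids
    aln <- methods::new("ProteinAlignment", mat = m)
    part <- GroupPartition(stats::setNames(rowGroup, ids),
                           groups = groupLabels)
    truth <- methods::new("SyntheticTruth",
                          foldColumns = as.integer(foldCols),
                          functionColumns = as.integer(funCols),
                          foldResidues = foldRes,
                          functionResidues = funRes)
    list(alignment = aln, partition = part, truth = truth)
  })
}

#' Precision, recall and F1 of a site prediction against planted truth
#'
#' Standard set-overlap metrics. With an empty prediction, precision is
#' defined as 0 when the truth set is non-empty (1 when both are empty);
#' with an empty truth set, recall is 1.
#'
#' @param predicted a [SiteSet-class] or integer vector of columns.
#' @param truthColumns integer vector of planted columns.
#' @return Named numeric vector \code{c(precision, recall, f1)}.
#' @examples
#' evaluateRecovery(c(1, 2, 3, 4), c(3, 4, 5, 6))
#' @export
evaluateRecovery <- function(predicted, truthColumns) {
  if (methods::is(predicted, "SiteSet")) predicted <- siteColumns(predicted)
  predicted <- unique(as.integer(predicted))
  truthColumns <- unique(as.integer(truthColumns))
  tp <- length(intersect(predicted, truthColumns))
  precision <- if (length(predicted)) tp / length(predicted)
               else if (length(truthColumns)) 0 else 1
  recall <- if (length(truthColumns)) tp / length(truthColumns) else 1
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Write planted truth to TSV
#'
#' One row per planted column: index, class (\code{fold} or
#' \code{function}) and the designated residue(s) (for function columns,
#' '/'-joined per group in group order).
#'
#' @param truth a [SyntheticTruth-class].
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeTruth <- function(truth, path) {
  stopifnot(methods::is(truth, "SyntheticTruth"))
  rows <- c(
    sprintf("%d\tfold\t%s", truth@foldColumns,
            truth@foldResidues[as.character(truth@foldColumns)]),
    sprintf("%d\tfunction\t%s", truth@functionColumns,
            vapply(as.character(truth@functionColumns), function(k)
              paste(truth@functionResidues[[k]], collapse = "/"),
              character(1))))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("column\tclass\tdesignated_residues", con)
  writeLines(rows, con)
  invisible(path)
}
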