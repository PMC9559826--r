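## End-to-end drivers: scan, classify, simulate/evaluate.
## A thin command-line wrapper over these functions ships in
## inst/scripts/specsite.R.

#' Score an alignment and select fold- and function-specific sites
#'
#' Runs the full scoring stage: relative-entropy scan, Sequence Harmony
#' scan, optional RELIEF-style weighting, top-N / low-SH selection, and
#' (when \code{outDir} is given) writes \code{scores.tsv},
#' \code{fold_sites.tsv}, \code{function_sites.tsv} and
#' \code{run_metadata.txt}. The score and site files are byte-identical
#' across re-runs with identical inputs and parameters; only the
#' metadata file carries a timestamp. On any validation failure,
#' partially written outputs are removed.
#'
#' @param alignment a [ProteinAlignment-class] or path to an alignment
#'   file (read via [readAlignment()]).
#' @param groups a [GroupPartition-class] or path to a group-label TSV.
#' @param background a [BackgroundDistribution-class] (default packaged
#'   Swiss-Prot composition).
#' @param outDir output directory (created if needed), or \code{NULL} to
#'   skip writing.
#' @param logBase \code{"e"} or \code{"2"} for the RE scan.
#' @param maxGapFraction shared gap policy threshold (default 0.5).
#' @param topN fold-specific selection size (default 30).
#' @param shCutoff function-specific SH cutoff (default 0.4).
#' @param shN cap on function-specific sites (default 30; \code{NULL}
#'   for no cap).
#' @param scheme SH grouping scheme (default \code{"one_vs_rest"}).
#' @param computeMR also compute RELIEF-style weights (default
#'   \code{FALSE}; they never feed the selection).
#' @param seed seed for the RELIEF sampler (required when
#'   \code{computeMR}).
#' @param residueMap optional [ResidueMap-class] to attach reference
#'   numbering to the outputs.
#' @param motifs optional [MotifTable-class]; selected sites are
#'   annotated when given.
#' @return Invisibly, a list with \code{scores} ([ScoreTable-class]),
#'   \code{foldSites}, \code{functionSites} ([SiteSet-class]) and
#'   \code{files} (written paths, or \code{NULL}).
#' @export
runScan <- function(alignment, groups, background = swissprotBackground(),
                    outDir = NULL, logBase = "e", maxGapFraction = 0.5,
                    topN = 30, shCutoff = 0.4, shN = 30,
                    scheme = "one_vs_rest", computeMR = FALSE, seed = NULL,
                    residueMap = NULL, motifs = NULL) {
  if (is.character(alignment)) alignment <- readAlignment(alignment)
  stopifnot(methods::is(alignment, "ProteinAlignment"))
  if (is.character(groups)) groups <- readGroups(groups, alignment)
  stopifnot(methods::is(groups, "GroupPartition"))
  if (computeMR && is.null(seed))
    stop("computeMR = TRUE requires a seed")

  written <- character(0)
  cleanup <- function() if (length(written)) unlink(written)

  res <- tryCatch({
    reTab <- reScan(alignment, background, maxGapFraction, logBase)
    shTab <- shScan(alignment, groups, scheme, maxGapFraction)
    mr <- if (computeMR)
      multiRelief(alignment, groups, seed = seed) else NULL
    combined <- combineScoreTables(reTab, shTab, mr)
    foldSites <- selectTop(combined, "RE", topN)
    funSites <- selectLow(combined, cutoff = shCutoff, n = shN)

    df <- combined@scores
    df$selected_fold <- df$column %in% siteColumns(foldSites)
    df$selected_function <- df$column %in% siteColumns(funSites)
    md <- combined@metadata
    md$top_n <- topN
    md$sh_cutoff <- shCutoff
    if (!is.null(seed)) md$seed <- seed
    combined <- ScoreTable(df, metadata = md)
    if (!is.null(residueMap))
      combined <- attachResidueMap(combined, residueMap)

    files <- NULL
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      files <- list(
        scores = file.path(outDir, "scores.tsv"),
        fold = file.path(outDir, "fold_sites.tsv"),
        funct = file.path(outDir, "function_sites.tsv"),
        meta = file.path(outDir, "run_metadata.txt"))
      written <- unlist(files, use.names = FALSE)
      writeScoreTable(combined, files$scores)
      .writeSiteSet(foldSites, combined, files$fold, residueMap, motifs)
      .writeSiteSet(funSites, combined, files$funct, residueMap, motifs)
      .writeRunMetadata(files$meta, md,
                        nSeq = nSequences(alignment),
                        nCol = alignmentLength(alignment),
                        scoresFile = files$scores)
    }
    list(scores = combined, foldSites = foldSites,
         functionSites = funSites, files = files)
  }, error = function(e) {
    cleanup()
    stop(e)
  })
  invisible(res)
}

.writeSiteSet <- function(sites, table, path, residueMap = NULL,
                          motifs = NULL) {
  df <- table@scores
  cols <- siteColumns(sites)
  idx <- match(cols, df$column)
  stat <- siteCriterion(sites)$statistic
  out <- data.frame(rank = seq_along(cols), column = cols,
                    score = df[[stat]][idx], stringsAsFactors = FALSE)
  if (!is.null(residueMap)) {
    out$residue_number <- columnToResidue(residueMap, cols)
    rl <- residueMap@residueLetter[match(cols, residueMap@column)]
    out$residue_letter <- ifelse(is.na(rl), "", rl)
  }
  if (!is.null(motifs)) out$motifs <- annotateColumns(cols, motifs)$motifs
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  cr <- siteCriterion(sites)
  writeLines(sprintf("# criterion: %s",
                     paste(sprintf("%s=%s", names(cr),
                                   vapply(cr, function(v)
                                     paste(format(v), collapse = ","),
                                     character(1))), collapse = " ")), con)
  out$score <- .fmtNum(out$score)
  writeLines(paste(colnames(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

.writeRunMetadata <- function(path, md, nSeq, nCol, scoresFile) {
  lines <- c(
    sprintf("package_version: %s",
            as.character(utils::packageVersion("SpecSites"))),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("n_sequences: %d", nSeq),
    sprintf("n_columns: %d", nCol),
    sprintf("scores_md5: %s", unname(tools::md5sum(scoresFile))),
    vapply(sort(names(md)), function(k)
      sprintf("%s: %s", k, paste(format(md[[k]]), collapse = ",")),
      character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Classify a mutation list against selected site sets
#'
#' Parses the mutation table (unparseable tokens are reported and
#' skipped), classifies each record by site-set membership, annotates
#' positions with motifs, and tallies by receptor, classification,
#' motif and alignment position. With \code{outDir}, writes
#' \code{mutations_classified.tsv} and one tally TSV per grouping.
#'
#' @param mutations data.frame from [readMutations()] or a path to a
#'   mutation TSV.
#' @param foldSites,functionSites [SiteSet-class] objects.
#' @param motifs a [MotifTable-class] (default [defaultMotifs()]).
#' @param map optional [ResidueMap-class] for records lacking alignment
#'   positions.
#' @param outDir output directory or \code{NULL}.
#' @return Invisibly, list with \code{records} (classified data.frame,
#'   motif-annotated), \code{tallies} (named list of data.frames),
#'   \code{failures} (rejected token table) and \code{files}.
#' @export
runClassify <- function(mutations, foldSites, functionSites,
                        motifs = defaultMotifs(), map = NULL,
                        outDir = NULL) {
  if (is.character(mutations)) mutations <- readMutations(mutations)
  failures <- attr(mutations, "failures")
  if (is.null(failures))
    failures <- data.frame(row = integer(0), token = character(0))
  records <- classifyMutations(mutations, foldSites, functionSites, map)
  if (nrow(records)) {
    records$motifs <-
      annotateColumns(ifelse(is.na(records$alignment_position), 0L,
                             records$alignment_position), motifs)$motifs
  } else records$motifs <- character(0)
  tallies <- list(
    receptor = tallyMutations(records, "receptor"),
    classification = tallyMutations(records, "classification"),
    alignment_position = tallyMutations(records, "alignment_position"),
    motif = tallyMutations(records, "motif", motifs = motifs))
  files <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    files <- c(list(records = file.path(outDir, "mutations_classified.tsv")),
               stats::setNames(
                 lapply(names(tallies), function(k)
                   file.path(outDir, sprintf("tally_%s.tsv", k))),
                 names(tallies)))
    writeMutations(records, files$records)
    for (k in names(tallies))
      utils::write.table(tallies[[k]], files[[k]], sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  invisible(list(records = records, tallies = tallies,
                 failures = failures, files = files))
}

#' Simulate, scan and score recovery of planted sites
#'
#' Generates a synthetic alignment, scans it with the same background
#' the generator used, selects fold (top-N RE) and function (SH below
#' cutoff) sites at the given parameters, and scores both selections
#' against the planted truth.
#'
#' @param config a [SyntheticConfig-class] (default
#'   \code{syntheticConfig()}, the benchmark conditions).
#' @param topN fold selection size (default the number of planted fold
#'   columns).
#' @param shCutoff function-specific SH cutoff (default 0.4).
#' @param shN cap on function-specific sites (default the number of
#'   planted function columns).
#' @param verbose print the recovery report (default \code{TRUE}).
#' @return Invisibly, list with \code{report} (data.frame of precision/
#'   recall/F1 per task), \code{sim}, \code{scores}, \code{foldSites},
#'   \code{functionSites}.
#' @examples
#' cfg <- syntheticConfig(nGroups = 3, seqsPerGroup = 6, length = 60,
#'                        nFoldColumns = 5, nFunctionColumns = 5, seed = 2)
#' runSimulateEvaluate(cfg, verbose = FALSE)$report
#' @export
runSimulateEvaluate <- function(config = syntheticConfig(),
                                topN = NULL, shCutoff = 0.4, shN = NULL,
                                verbose = TRUE) {
  stopifnot(methods::is(config, "SyntheticConfig"))
  if (is.null(topN)) topN <- config@nFoldColumns
  if (is.null(shN)) shN <- config@nFunctionColumns
  sim <- generateAlignment(config)
  reTab <- reScan(sim$alignment, config@background)
  shTab <- shScan(sim$alignment, sim$partition)
  combined <- combineScoreTables(reTab, shTab)
  foldSites <- selectTop(combined, "RE", topN)
  funSites <- selectLow(combined, cutoff = shCutoff, n = shN)
  foldRec <- evaluateRecovery(foldSites, foldColumns(sim$truth))
  funRec <- evaluateRecovery(funSites, functionColumns(sim$truth))
  report <- data.frame(
    task = c("fold_top_RE", "function_low_SH"),
    n_selected = c(length(siteColumns(foldSites)),
                   length(siteColumns(funSites))),
    n_planted = c(length(foldColumns(sim$truth)),
                  length(functionColumns(sim$truth))),
    precision = c(foldRec[["precision"]], funRec[["precision"]]),
    recall = c(foldRec[["recall"]], funRec[["recall"]]),
    f1 = c(foldRec[["f1"]], funRec[["f1"]]),
    stringsAsFactors = FALSE)
  if (verbose) {
    message(sprintf(
      "fold:     precision %.3f recall %.3f F1 %.3f (%d selected / %d planted)",
      report$precision[1], report$recall[1], report$f1[1],
      report$n_selected[1], report$n_planted[1]))
    message(sprintf(
      "function: precision %.3f recall %.3f F1 %.3f (%d selected / %d planted)",
      report$precision[2], report$recall[2], report$f1[2],
      report$n_selected[2], report$n_planted[2]))
  }
  invisible(list(report = report, sim = sim, scores = combined,
                 foldSites = foldSites, functionSites = funSites))
}

#' Packaged reference score lists for the THR-like LBD analysis
#'
#' Loads the bundled per-residue score lists for the THR-like
#' ligand-binding domain family: the 30 highest relative-entropy
#' (fold-specific) residues and the 30 lowest Sequence Harmony
#' (function-specific) residues, identified by reference structure
#' residue number (thyroid hormone receptor alpha, PDB 1NAV chain A
#' numbering).
#'
#' @param statistic \code{"re"} (fold-specific list) or \code{"sh"}
#'   (function-specific list).
#' @return A [ScoreTable-class] keyed by residue number.
#' @examples
#' selectTop(thrReferenceScores("re"), n = 30)
#' @export
thrReferenceScores <- function(statistic = c("re", "sh")) {
  statistic <- match.arg(statistic)
  fn <- if (statistic == "re") "thr_lbd_re_top30.tsv"
        else "thr_lbd_sh_low30.tsv"
  df <- .readTSV(system.file("extdata", fn, package = "SpecSites",
                             mustWork = TRUE))
  scoreTableFromScores(df$residue_number, df$score,
                       statistic = toupper(statistic),
                       metadata = list(residue_letters =
                                         paste(df$residue, collapse = "")))
}
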