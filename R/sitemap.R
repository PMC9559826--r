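## Column <-> reference-residue mapping and motif annotation.

#' Map alignment columns to reference residue numbers
#'
#' Walks the reference row left to right and assigns consecutive residue
#' numbers, starting at \code{firstResidueNumber}, to its non-gap
#' columns ('X' counts as a residue position); gap columns of the
#' reference are unmapped. This reproduces e.g. PDB-chain author
#' numbering when the offset of the first modeled residue is supplied.
#'
#' @param alignment a [ProteinAlignment-class].
#' @param referenceId id of the alignment row to number along.
#' @param firstResidueNumber number given to the first non-gap residue
#'   (default 1).
#' @return A [ResidueMap-class].
#' @examples
#' aln <- ProteinAlignment(c(ref = "AC-D", other = "ACQD"))
#' residueMapFrame(mapColumnsToResidues(aln, "ref", 100))
#' @export
mapColumnsToResidues <- function(alignment, referenceId,
                                 firstResidueNumber = 1L) {
  stopifnot(methods::is(alignment, "ProteinAlignment"))
  ids <- seqIDs(alignment)
  if (!referenceId %in% ids)
    stop(sprintf("reference id '%s' not found in alignment", referenceId))
  chars <- alignment@mat[referenceId, ]
  cols <- which(chars != GAP_CHAR)
  if (!length(cols))
    stop(sprintf("reference row '%s' contains only gaps", referenceId))
  methods::new("ResidueMap",
               referenceId = referenceId,
               column = as.integer(cols),
               residueNumber = as.integer(firstResidueNumber) +
                 seq_along(cols) - 1L,
               residueLetter = unname(chars[cols]))
}

#' Residue map as a data.frame
#'
#' @param x a \code{ResidueMap}.
#' @return data.frame with columns \code{column}, \code{residue_number},
#'   \code{residue_letter}.
#' @export
setGeneric("residueMapFrame", function(x) standardGeneric("residueMapFrame"))

#' @rdname residueMapFrame
#' @export
setMethod("residueMapFrame", "ResidueMap", function(x) {
  data.frame(column = x@column, residue_number = x@residueNumber,
             residue_letter = x@residueLetter, stringsAsFactors = FALSE)
})

setMethod("show", "ResidueMap", function(object) {
  cat(sprintf("ResidueMap on '%s': %d residues, columns %d..%d -> %d..%d\n",
              object@referenceId, length(object@column),
              min(object@column), max(object@column),
              min(object@residueNumber), max(object@residueNumber)))
})

#' Convert between columns and residue numbers
#'
#' \code{columnToResidue} returns the residue number at an alignment
#' column (\code{NA} for unmapped/gap columns); \code{residueToColumn}
#' the inverse.
#'
#' @param map a [ResidueMap-class].
#' @param column,residue integer vectors.
#' @return Integer vector with \code{NA} where unmapped.
#' @export
columnToResidue <- function(map, column) {
  stopifnot(methods::is(map, "ResidueMap"))
  map@residueNumber[match(as.integer(column), map@column)]
}

#' @rdname columnToResidue
#' @export
residueToColumn <- function(map, residue) {
  stopifnot(methods::is(map, "ResidueMap"))
  map@column[match(as.integer(residue), map@residueNumber)]
}

#' Attach reference residue numbering to a score table
#'
#' Adds \code{residue_number} and \code{residue_letter} columns
#' (\code{NA} for columns where the reference row is gapped).
#'
#' @param table a [ScoreTable-class].
#' @param map a [ResidueMap-class].
#' @return The augmented [ScoreTable-class].
#' @export
attachResidueMap <- function(table, map) {
  stopifnot(methods::is(table, "ScoreTable"), methods::is(map, "ResidueMap"))
  df <- table@scores
  idx <- match(df$column, map@column)
  df$residue_number <- map@residueNumber[idx]
  df$residue_letter <- map@residueLetter[idx]
  md <- table@metadata
  md$reference_id <- map@referenceId
  ScoreTable(df, metadata = md)
}

#' Write a residue map to TSV
#'
#' @param map a [ResidueMap-class].
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeResidueMap <- function(map, path) {
  df <- residueMapFrame(map)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# reference_id: %s", map@referenceId), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  writeLines(paste(df$column, df$residue_number, df$residue_letter,
                   sep = "\t"), con)
  invisible(path)
}

#' Conserved-motif coordinates of the THR-like LBD consensus
#'
#' The seven conserved motifs of the thyroid hormone receptor-like
#' ligand-binding domain consensus alignment: Motif A 207-216 (inverse
#' NR-box LLxxL, a main ligand interaction site), Motif B 222-232,
#' Motif C 236-245 (LxxDDQ), Motif D 396-401 (ligand binding),
#' Motif E 455-459 (inverse NR-box), Motif F 498-504 and Motif G 540-548
#' (coactivator binding). Interaction-site ranges (INS1-INS5) have no
#' published coordinates and must be supplied by the user via
#' [readMotifs()].
#'
#' @return A [MotifTable-class].
#' @examples
#' defaultMotifs()
#' @export
defaultMotifs <- function() {
  readMotifs(system.file("extdata", "thr_lbd_motifs.tsv",
                         package = "SpecSites", mustWork = TRUE))
}

#' Read a motif coordinate table
#'
#' TSV with columns \code{name}, \code{start}, \code{end} and optional
#' \code{category} (\code{motif} or \code{interaction_site}); 1-based
#' inclusive alignment-column ranges.
#'
#' @param path TSV file.
#' @return A [MotifTable-class].
#' @export
readMotifs <- function(path) {
  if (!file.exists(path)) stop("motif file not found: ", path)
  df <- .readTSV(path)
  need <- c("name", "start", "end")
  if (!all(need %in% colnames(df)))
    stop("motif table needs columns: name, start, end")
  MotifTable(df)
}

#' Motif ranges as a data.frame
#'
#' @param x a \code{MotifTable}.
#' @return data.frame with columns name, start, end, category.
#' @export
setGeneric("motifFrame", function(x) standardGeneric("motifFrame"))

#' @rdname motifFrame
#' @export
setMethod("motifFrame", "MotifTable", function(x) x@ranges)

setMethod("show", "MotifTable", function(object) {
  r <- object@ranges
  cat(sprintf("MotifTable: %d range(s)\n", nrow(r)))
  if (nrow(r))
    cat(paste(sprintf("  %s [%d-%d] (%s)", r$name, r$start, r$end,
                      r$category), collapse = "\n"), "\n", sep = "")
})

#' Annotate columns with containing motifs
#'
#' Every queried column is labelled with all ranges containing it
#' (overlaps all reported, ';'-joined); columns outside every range get
#' an empty label.
#'
#' @param columns a [SiteSet-class] or integer vector of column indices.
#' @param motifs a [MotifTable-class] (default [defaultMotifs()]).
#' @return data.frame with columns \code{column} and \code{motifs}
#'   (empty string when none).
#' @examples
#' annotateColumns(c(210, 545, 600))
#' @export
annotateColumns <- function(columns, motifs = defaultMotifs()) {
  if (methods::is(columns, "SiteSet")) columns <- siteColumns(columns)
  columns <- as.integer(columns)
  stopifnot(methods::is(motifs, "MotifTable"))
  r <- motifs@ranges
  labels <- vapply(columns, function(cc) {
    hit <- r$name[r$start <= cc & cc <= r$end]
    paste(hit, collapse = ";")
  }, character(1))
  data.frame(column = columns, motifs = labels, stringsAsFactors = FALSE)
}
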