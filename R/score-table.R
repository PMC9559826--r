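## ScoreTable accessors and TSV serialization.

#' Per-column scores as a data.frame
#'
#' @param x a \code{ScoreTable}.
#' @return The underlying data.frame, one row per alignment column.
#' @export
setGeneric("scoreFrame", function(x) standardGeneric("scoreFrame"))

#' @rdname scoreFrame
#' @export
setMethod("scoreFrame", "ScoreTable", function(x) x@scores)

#' Run metadata of a score table
#'
#' @param x a \code{ScoreTable}.
#' @return Named list of provenance parameters (log base, gap policy,
#'   grouping scheme, seed, ...).
#' @export
setGeneric("scoreMetadata", function(x) standardGeneric("scoreMetadata"))

#' @rdname scoreMetadata
#' @export
setMethod("scoreMetadata", "ScoreTable", function(x) x@metadata)

setMethod("show", "ScoreTable", function(object) {
  df <- object@scores
  stats <- intersect(c("RE", "SH_combined", "MR_weight"), colnames(df))
  cat(sprintf("ScoreTable: %d columns; statistics: %s\n", nrow(df),
              if (length(stats)) paste(stats, collapse = ", ") else "none"))
  cat(sprintf("  usable columns: %d/%d\n", sum(df$usable), nrow(df)))
  if (length(object@metadata))
    cat("  metadata: ",
        paste(sprintf("%s=%s", names(object@metadata),
                      vapply(object@metadata, function(v)
                        paste(format(v), collapse = ","), character(1))),
              collapse = " "), "\n", sep = "")
})

#' Selected columns and selection criterion of a SiteSet
#'
#' @param x a \code{SiteSet}.
#' @return \code{siteColumns}: integer columns in rank order (most extreme
#'   score first); \code{siteCriterion}: list describing the selection.
#' @export
setGeneric("siteColumns", function(x) standardGeneric("siteColumns"))

#' @rdname siteColumns
#' @export
setMethod("siteColumns", "SiteSet", function(x) x@columns)

#' @rdname siteColumns
#' @export
setGeneric("siteCriterion", function(x) standardGeneric("siteCriterion"))

#' @rdname siteColumns
#' @export
setMethod("siteCriterion", "SiteSet", function(x) x@criterion)

setMethod("show", "SiteSet", function(object) {
  cr <- object@criterion
  cat(sprintf("SiteSet: %d columns (%s)\n", length(object@columns),
              paste(sprintf("%s=%s", names(cr),
                            vapply(cr, function(v)
                              paste(format(v), collapse = ","),
                              character(1))), collapse = ", ")))
  cat("  ", paste(utils::head(object@columns, 15L), collapse = " "),
      if (length(object@columns) > 15L) " ..." else "", "\n", sep = "")
})

#' @describeIn ScoreTable coerce to the underlying data.frame.
#' @param x a \code{ScoreTable}.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "ScoreTable",
          function(x, ...) x@scores)

#' Write a score table to TSV
#'
#' Deterministic layout: '#'-prefixed metadata lines (sorted by key), a
#' header row, then one row per column with floats printed to 6 decimals
#' and excluded scores as the literal \code{NA} sentinel.
#'
#' @param table a [ScoreTable-class].
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @seealso [readScoreTable()]
#' @export
writeScoreTable <- function(table, path) {
  stopifnot(methods::is(table, "ScoreTable"))
  df <- table@scores
  md <- table@metadata
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in sort(names(md)))
    writeLines(sprintf("# %s: %s", k,
                       paste(format(md[[k]], scientific = FALSE),
                             collapse = ",")), con)
  out <- df
  for (cn in colnames(out)) {
    v <- out[[cn]]
    if (is.double(v)) out[[cn]] <- .fmtNum(v)
    else if (is.logical(v)) out[[cn]] <- ifelse(v, "TRUE", "FALSE")
  }
  writeLines(paste(colnames(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' Read a score table written by [writeScoreTable()]
#'
#' @param path TSV file.
#' @return A [ScoreTable-class]; metadata recovered from the '#' header
#'   lines (as strings).
#' @export
readScoreTable <- function(path) {
  if (!file.exists(path)) stop("score table not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  mdLines <- grep("^# ", lines, value = TRUE)
  md <- list()
  for (ln in mdLines) {
    kv <- sub("^# ", "", ln)
    key <- sub(":.*$", "", kv)
    md[[key]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- utils::read.delim(text = paste(grep("^#", lines, invert = TRUE,
                                            value = TRUE), collapse = "\n"),
                          stringsAsFactors = FALSE)
  if ("reason" %in% colnames(df)) {
    df$reason <- as.character(df$reason)
    df$reason[is.na(df$reason)] <- ""
  }
  ScoreTable(df, metadata = md)
}

#' Build a ScoreTable from an external per-site score list
#'
#' Wraps a plain vector of scores (e.g. a published per-residue score
#' list) as a ScoreTable so the package's selection rules can be applied
#' to it. Site identifiers become the \code{column} key.
#'
#' @param sites integer site identifiers (alignment columns or residue
#'   numbers, as long as they are used consistently).
#' @param scores numeric scores, parallel to \code{sites}.
#' @param statistic \code{"RE"} or \code{"SH"} (stored as
#'   \code{SH_combined}).
#' @param metadata optional named list.
#' @return A [ScoreTable-class].
#' @export
scoreTableFromScores <- function(sites, scores,
                                 statistic = c("RE", "SH"),
                                 metadata = list()) {
  statistic <- match.arg(statistic)
  stopifnot(length(sites) == length(scores))
  df <- data.frame(column = as.integer(sites),
                   gap_fraction = 0,
                   stringsAsFactors = FALSE)
  if (statistic == "RE") df$RE <- as.numeric(scores)
  else df$SH_combined <- as.numeric(scores)
  df$usable <- !is.na(scores)
  df$reason <- ""
  ScoreTable(df, metadata = c(metadata, list(source = "external_scores")))
}
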