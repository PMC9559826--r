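## Natural-variant parsing, fold/function classification and tallies.
##
## Mutation tokens follow the compact clinical notation used in variant
## compilations: "A263S" (wild type, position, alternate), "R429Q/W"
## (several alternates), and the deletion form "Del337T" in which the
## affected residue FOLLOWS the position (deletion of T at 337) --
## inverting the usual wild-type-first order, so documented prominently.

#' Parse a mutation token
#'
#' Grammar: \code{[Del]? WT? POSITION ALT(/ALT)*}. Substitutions carry
#' one or more alternate residues separated by '/'; deletions
#' (\code{DelPOSRES}) carry the deleted residue after the position and
#' have no alternates.
#'
#' @param token mutation string, e.g. \code{"R429Q/W"} or
#'   \code{"Del337T"}.
#' @return List with elements \code{wild_type}, \code{position},
#'   \code{alternates} (character, empty for deletions) and
#'   \code{is_deletion}.
#' @examples
#' parseMutation("R429Q/W")
#' parseMutation("Del337T")
#' @export
parseMutation <- function(token) {
  if (is.null(token) || is.na(token) || !nzchar(token))
    stop("mutation token must be non-empty")
  token <- trimws(token)
  if (grepl("^[Dd]el", token)) {
    mm <- regmatches(token, regexec("^[Dd]el([0-9]+)([A-Z])$", token))[[1L]]
    if (length(mm) != 3L)
      stop(sprintf("unparseable mutation token: '%s'", token))
    return(list(wild_type = mm[3L], position = as.integer(mm[2L]),
                alternates = character(0), is_deletion = TRUE))
  }
  mm <- regmatches(token,
                   regexec("^([A-Z])([0-9]+)([A-Z](?:/[A-Z])*)$", token))[[1L]]
  if (length(mm) != 4L)
    stop(sprintf("unparseable mutation token: '%s'", token))
  pos <- as.integer(mm[3L])
  if (pos < 1L) stop(sprintf("mutation position must be >= 1: '%s'", token))
  list(wild_type = mm[2L], position = pos,
       alternates = strsplit(mm[4L], "/", fixed = TRUE)[[1L]],
       is_deletion = FALSE)
}

#' Format a parsed mutation back to its canonical token
#'
#' Inverse of [parseMutation()]: \code{formatMutation(parseMutation(x))}
#' reproduces \code{x} for canonical tokens.
#'
#' @param mutation list as returned by [parseMutation()].
#' @return Character token.
#' @export
formatMutation <- function(mutation) {
  if (isTRUE(mutation$is_deletion))
    return(sprintf("Del%d%s", mutation$position, mutation$wild_type))
  sprintf("%s%d%s", mutation$wild_type, mutation$position,
          paste(mutation$alternates, collapse = "/"))
}

#' Read a mutation table
#'
#' TSV with columns \code{receptor}, \code{mutation} and optionally
#' \code{alignment_position}, \code{disease} and
#' \code{reported_classification} (a curated fold/function label carried
#' through for comparison). Tokens are parsed into wild type, position
#' and alternates; unparseable tokens are reported (with row numbers)
#' and either dropped (\code{onError = "warn"}, default) or fatal
#' (\code{onError = "stop"}).
#'
#' @param path TSV file.
#' @param onError \code{"warn"} or \code{"stop"}.
#' @return data.frame, one row per record, with parsed fields
#'   \code{wild_type}, \code{position}, \code{alternates} ('/'-joined),
#'   \code{is_deletion}, plus an attribute \code{"failures"} holding the
#'   rejected row numbers and tokens.
#' @export
readMutations <- function(path, onError = c("warn", "stop")) {
  onError <- match.arg(onError)
  if (!file.exists(path)) stop("mutation file not found: ", path)
  df <- .readTSV(path)
  need <- c("receptor", "mutation")
  if (!all(need %in% colnames(df)))
    stop("mutation table needs columns: receptor, mutation")
  if (is.null(df$alignment_position)) df$alignment_position <- NA_integer_
  df$alignment_position <- as.integer(df$alignment_position)
  if (is.null(df$disease)) df$disease <- ""
  if (is.null(df$reported_classification))
    df$reported_classification <- NA_character_

  parsed <- lapply(df$mutation, function(tok)
    tryCatch(parseMutation(tok), error = function(e) NULL))
  bad <- vapply(parsed, is.null, logical(1))
  failures <- data.frame(row = which(bad),
                         token = df$mutation[bad],
                         stringsAsFactors = FALSE)
  if (nrow(failures)) {
    msg <- sprintf("%d unparseable mutation token(s) at row(s) %s: %s",
                   nrow(failures),
                   paste(failures$row, collapse = ", "),
                   paste(failures$token, collapse = ", "))
    if (onError == "stop") stop(msg)
    warning(msg)
  }
  keep <- !bad
  out <- df[keep, , drop = FALSE]
  pk <- parsed[keep]
  out$wild_type <- vapply(pk, `[[`, character(1), "wild_type")
  out$position <- vapply(pk, `[[`, integer(1), "position")
  out$alternates <- vapply(pk, function(p)
    paste(p$alternates, collapse = "/"), character(1))
  out$is_deletion <- vapply(pk, `[[`, logical(1), "is_deletion")
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}

#' The packaged THR-like LBD disease mutation compilation
#'
#' Natural ligand-binding-domain mutations of THR-like receptors (THRA,
#' THRB, RARB, VDR, PPARG, RORA) associated with human disease, compiled
#' from UniProtKB variant annotation, with curated fold/function labels
#' and alignment positions in the family consensus coordinate system.
#'
#' @return data.frame as returned by [readMutations()].
#' @examples
#' nrow(thrMutations())
#' @export
thrMutations <- function() {
  readMutations(system.file("extdata", "thr_lbd_mutations.tsv",
                            package = "SpecSites", mustWork = TRUE))
}

#' Classify mutations as fold- or function-specific
#'
#' A record's alignment position is looked up in the fold-specific site
#' set (top-N relative entropy) and the function-specific site set
#' (combined SH below cutoff): membership in only one yields
#' \code{Fold} or \code{Function}, in both \code{Fold/Function}, in
#' neither \code{Unclassified}. Records without a resolvable alignment
#' position (directly, or through \code{map} from receptor numbering)
#' are flagged \code{Unresolved} with a warning and excluded from
#' classification tallies.
#'
#' @param records data.frame from [readMutations()] (or with columns
#'   \code{position} and optionally \code{alignment_position}).
#' @param foldSet a [SiteSet-class] of fold-specific columns.
#' @param functionSet a [SiteSet-class] of function-specific columns.
#' @param map optional [ResidueMap-class] used to resolve
#'   \code{alignment_position} from \code{position} where absent.
#' @return The records with a \code{classification} column added.
#' @export
classifyMutations <- function(records, foldSet, functionSet, map = NULL) {
  stopifnot(methods::is(foldSet, "SiteSet"),
            methods::is(functionSet, "SiteSet"))
  if (is.null(records$alignment_position))
    records$alignment_position <- NA_integer_
  unresolved <- is.na(records$alignment_position)
  if (any(unresolved) && !is.null(map)) {
    records$alignment_position[unresolved] <-
      residueToColumn(map, records$position[unresolved])
    unresolved <- is.na(records$alignment_position)
  }
  if (any(unresolved))
    warning(sprintf("%d record(s) lack a resolvable alignment position",
                    sum(unresolved)))
  inFold <- records$alignment_position %in% siteColumns(foldSet)
  inFun <- records$alignment_position %in% siteColumns(functionSet)
  cls <- rep("Unclassified", nrow(records))
  cls[inFold & !inFun] <- "Fold"
  cls[!inFold & inFun] <- "Function"
  cls[inFold & inFun] <- "Fold/Function"
  cls[unresolved] <- "Unresolved"
  records$classification <- cls
  records
}

#' Tally mutation records
#'
#' Deterministic counts by receptor, classification, alignment position
#' or motif. Position tallies additionally report the number of distinct
#' receptors mutated at each position (convergent positions hit in
#' several receptors are of particular interest); motif tallies use
#' [annotateColumns()] on the alignment positions.
#'
#' @param records classified (or raw, for receptor/position tallies)
#'   mutation data.frame.
#' @param by one of \code{"receptor"}, \code{"classification"},
#'   \code{"alignment_position"}, \code{"motif"}.
#' @param motifs [MotifTable-class] for \code{by = "motif"} (default
#'   [defaultMotifs()]).
#' @return data.frame of counts, sorted by key.
#' @examples
#' tallyMutations(thrMutations(), by = "alignment_position")
#' @export
tallyMutations <- function(records,
                           by = c("receptor", "classification",
                                  "alignment_position", "motif"),
                           motifs = defaultMotifs()) {
  by <- match.arg(by)
  if (!nrow(records))
    return(data.frame(key = character(0), n_records = integer(0),
                      stringsAsFactors = FALSE))
  if (by == "receptor" || by == "classification") {
    key <- records[[by]]
    if (is.null(key)) stop("records lack a '", by, "' column")
    tab <- table(key)
    out <- data.frame(key = names(tab), n_records = as.integer(tab),
                      stringsAsFactors = FALSE)
    colnames(out)[1L] <- by
    return(out[order(out[[by]]), , drop = FALSE])
  }
  if (by == "alignment_position") {
    keep <- !is.na(records$alignment_position)
    rec <- records[keep, , drop = FALSE]
    pos <- sort(unique(rec$alignment_position))
    out <- data.frame(
      alignment_position = pos,
      n_records = vapply(pos, function(p)
        sum(rec$alignment_position == p), integer(1)),
      n_receptors = vapply(pos, function(p)
        length(unique(rec$receptor[rec$alignment_position == p])),
        integer(1)),
      stringsAsFactors = FALSE)
    return(out)
  }
  ## by motif
  keep <- !is.na(records$alignment_position)
  ann <- annotateColumns(records$alignment_position[keep], motifs)
  lab <- strsplit(ann$motifs, ";", fixed = TRUE)
  lab[!vapply(lab, length, integer(1))] <- "none"
  flat <- unlist(lab, use.names = FALSE)
  tab <- table(flat)
  data.frame(motif = names(tab), n_records = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Write classified mutations to TSV
#'
#' @param records classified mutation data.frame.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeMutations <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
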