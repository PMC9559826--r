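## Alignment and group-label I/O, plus accessors for the core classes.

#' Sequence identifiers of an alignment or partition
#'
#' @param x a \code{ProteinAlignment} or \code{GroupPartition}.
#' @return Character vector of sequence identifiers, in input order.
#' @export
setGeneric("seqIDs", function(x) standardGeneric("seqIDs"))

#' @rdname seqIDs
#' @export
setMethod("seqIDs", "ProteinAlignment", function(x) rownames(x@mat))

#' @rdname seqIDs
#' @export
setMethod("seqIDs", "GroupPartition", function(x) names(x@mapping))

#' Number of columns in an alignment
#'
#' @param x a \code{ProteinAlignment}.
#' @return Integer number of alignment columns.
#' @export
setGeneric("alignmentLength", function(x) standardGeneric("alignmentLength"))

#' @rdname alignmentLength
#' @export
setMethod("alignmentLength", "ProteinAlignment", function(x) ncol(x@mat))

#' Number of sequences in an alignment
#'
#' @param x a \code{ProteinAlignment}.
#' @return Integer number of sequences (rows).
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' @rdname nSequences
#' @export
setMethod("nSequences", "ProteinAlignment", function(x) nrow(x@mat))

#' @describeIn ProteinAlignment extract the character matrix (rows =
#'   sequences, columns = alignment positions).
#' @param x a \code{ProteinAlignment}.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "ProteinAlignment", function(x, ...) x@mat)

#' Aligned sequences as a named character vector
#'
#' @param x a \code{ProteinAlignment}.
#' @return Named character vector of gapped sequences.
#' @export
setGeneric("alignedSequences",
           function(x) standardGeneric("alignedSequences"))

#' @rdname alignedSequences
#' @export
setMethod("alignedSequences", "ProteinAlignment", function(x) {
  out <- apply(x@mat, 1L, paste0, collapse = "")
  names(out) <- rownames(x@mat)
  out
})

#' Group labels and membership of a partition
#'
#' \code{groupNames} returns the ordered distinct group labels;
#' \code{groupOf} the per-sequence label vector (named by sequence id).
#'
#' @param x a \code{GroupPartition}.
#' @return \code{groupNames}: character vector of labels; \code{groupOf}:
#'   named character vector mapping sequence id to label.
#' @export
setGeneric("groupNames", function(x) standardGeneric("groupNames"))

#' @rdname groupNames
#' @export
setMethod("groupNames", "GroupPartition", function(x) x@groups)

#' @rdname groupNames
#' @export
setGeneric("groupOf", function(x) standardGeneric("groupOf"))

#' @rdname groupNames
#' @export
setMethod("groupOf", "GroupPartition", function(x) x@mapping)

setMethod("show", "ProteinAlignment", function(object) {
  cat(sprintf("ProteinAlignment: %d sequences x %d columns\n",
              nrow(object@mat), ncol(object@mat)))
  ids <- rownames(object@mat)
  shown <- utils::head(ids, 3L)
  cat("  ids: ", paste(shown, collapse = ", "),
      if (length(ids) > 3L) ", ..." else "", "\n", sep = "")
})

setMethod("show", "GroupPartition", function(object) {
  tab <- table(factor(object@mapping, levels = object@groups))
  cat(sprintf("GroupPartition: %d sequences in %d groups\n",
              length(object@mapping), length(object@groups)))
  cat("  ", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "),
      "\n", sep = "")
})

.sniffStockholm <- function(path) {
  first <- readLines(path, n = 1L)
  length(first) == 1L && grepl("^#\\s*STOCKHOLM", first)
}

#' Read a gapped protein multiple sequence alignment
#'
#' Reads FASTA (via Biostrings) or Stockholm. Input is validated and
#' normalized: sequences must be equal length, identifiers unique, and
#' characters restricted to the 20 amino acids, 'X' and the gap symbols
#' '-' or '.' (the latter rewritten to '-'); lowercase is uppercased.
#' Sequence order is preserved.
#'
#' @param path input file.
#' @param format \code{"fasta"}, \code{"stockholm"}, or \code{"auto"}
#'   (sniffs the Stockholm header line, otherwise by extension).
#' @return A [ProteinAlignment-class] object.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACD-", ">s2", "AC-E"), f)
#' readAlignment(f)
#' @export
readAlignment <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(sto|stk|stockholm)$", path, ignore.case = TRUE) ||
                  .sniffStockholm(path)) "stockholm" else "fasta"
  }
  if (format == "fasta") {
    x <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(x))
    seqs <- as.character(x)
  } else {
    parsed <- .readStockholm(path)
    ids <- parsed$ids
    seqs <- parsed$seqs
  }
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sequence identifier: '%s'",
                 ids[duplicated(ids)][1L]))
  ProteinAlignment(seqs, ids = ids)
}

## Minimal Stockholm reader: '#' lines are markup, '//' terminates, data
## lines are "<name> <subsequence>" and may be split across blocks.
.readStockholm <- function(path) {
  lines <- readLines(path)
  seqs <- character(0)
  for (ln in lines) {
    if (grepl("^\\s*$", ln) || startsWith(ln, "#")) next
    if (grepl("^//", ln)) break
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) != 2L)
      stop("malformed Stockholm sequence line: ", ln)
    id <- parts[1L]
    if (id %in% names(seqs)) {
      seqs[[id]] <- paste0(seqs[[id]], parts[2L])
    } else {
      seqs[[id]] <- parts[2L]
    }
  }
  if (!length(seqs)) stop("no sequences found in Stockholm file: ", path)
  list(ids = names(seqs), seqs = unname(unlist(seqs)))
}

#' Write an alignment to FASTA
#'
#' @param x a [ProteinAlignment-class].
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeAlignment <- function(x, path) {
  stopifnot(methods::is(x, "ProteinAlignment"))
  set <- Biostrings::AAStringSet(alignedSequences(x))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read sequence-to-subfamily labels
#'
#' Reads a two-column TSV (sequence id, group label; optional header;
#' '#' comment lines allowed) and checks it forms a complete partition of
#' the alignment: every alignment id must be labelled exactly once. Ids
#' in the table that are absent from the alignment are dropped with a
#' warning.
#'
#' @param path two-column TSV file.
#' @param alignment the [ProteinAlignment-class] the labels refer to.
#' @return A [GroupPartition-class]; group order follows first appearance
#'   in the table.
#' @export
readGroups <- function(path, alignment) {
  stopifnot(methods::is(alignment, "ProteinAlignment"))
  if (!file.exists(path)) stop("group file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2L) stop("group table must have two columns (id, label)")
  df <- df[, 1:2]
  colnames(df) <- c("id", "label")
  ids <- seqIDs(alignment)
  ## optional header row: first cell is a column title, not a sequence id
  if (nrow(df) && !(df$id[1L] %in% ids) &&
      tolower(df$id[1L]) %in% c("id", "seq", "seqid", "seq_id", "sequence",
                                "sequence_id", "name"))
    df <- df[-1L, , drop = FALSE]
  unknown <- setdiff(df$id, ids)
  if (length(unknown)) {
    warning("ignoring ", length(unknown),
            " label row(s) for ids absent from the alignment: ",
            paste(utils::head(unknown, 5L), collapse = ", "),
            if (length(unknown) > 5L) ", ..." else "")
    df <- df[df$id %in% ids, , drop = FALSE]
  }
  df <- unique(df)
  if (anyDuplicated(df$id))
    stop("conflicting group labels for id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  missing <- setdiff(ids, df$id)
  if (length(missing))
    stop("incomplete partition; alignment id(s) without a group label: ",
         paste(missing, collapse = ", "))
  groups <- unique(df$label)
  mapping <- stats::setNames(df$label[match(ids, df$id)], ids)
  GroupPartition(mapping, groups = groups)
}

#' Write sequence-to-subfamily labels
#'
#' @param partition a [GroupPartition-class].
#' @param path output TSV file.
#' @return Invisibly, \code{path}.
#' @export
writeGroups <- function(partition, path) {
  stopifnot(methods::is(partition, "GroupPartition"))
  df <- data.frame(id = seqIDs(partition), label = unname(groupOf(partition)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
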