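## S4 class definitions: the data model shared by all analysis stages.

#' ProteinAlignment: a validated gapped protein multiple sequence alignment
#'
#' A rectangular character matrix over the alphabet of the 20 canonical
#' amino acids plus \code{'X'} (unknown residue) and \code{'-'} (gap).
#' Input is normalized at construction: lowercase is uppercased and the
#' \code{'.'} gap symbol is rewritten to \code{'-'}. Ambiguity codes
#' (B, Z, U, O) are rejected rather than silently remapped. All column
#' indices in the package interface are 1-based.
#'
#' @slot mat character matrix, one row per sequence (rownames are the
#'   unique sequence identifiers), one column per alignment position.
#'
#' @param seqs character vector of equal-length aligned sequences.
#' @param ids sequence identifiers; defaults to \code{names(seqs)}.
#'
#' @return A \code{ProteinAlignment} object.
#' @examples
#' aln <- ProteinAlignment(c(s1 = "ACD-", s2 = "AC-E"))
#' alignmentLength(aln)
#' @export ProteinAlignment
#' @exportClass ProteinAlignment
setClass("ProteinAlignment", representation(mat = "matrix"))

setValidity("ProteinAlignment", function(object) {
  m <- object@mat
  if (!is.character(m)) return("alignment matrix must be of character type")
  if (ncol(m) < 1L) return("alignment must have at least one column")
  ids <- rownames(m)
  if (is.null(ids) || any(!nzchar(ids)))
    return("all sequence identifiers must be non-empty")
  if (anyDuplicated(ids))
    return(sprintf("duplicate sequence identifier: '%s'",
                   ids[duplicated(ids)][1L]))
  bad <- !(m %in% ALN_ALPHABET)
  if (any(bad)) {
    idx <- arrayInd(which(bad)[1L], dim(m))[1L, ]
    return(sprintf(
      "illegal character '%s' in sequence '%s' at column %d (alphabet: 20 amino acids, 'X', '-')",
      m[idx[1L], idx[2L]], ids[idx[1L]], idx[2L]))
  }
  TRUE
})

ProteinAlignment <- function(seqs, ids = names(seqs)) {
  if (is.null(ids) || length(ids) != length(seqs))
    stop("sequence identifiers are required (one per sequence)")
  seqs <- toupper(chartr(".", "-", as.character(seqs)))
  w <- nchar(seqs)
  if (length(unique(w)) > 1L) {
    off <- ids[w != w[1L]][1L]
    stop(sprintf(
      "alignment is not rectangular: sequence '%s' has length %d, expected %d",
      off, w[ids == off][1L], w[1L]))
  }
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), ncol = w[1L], byrow = TRUE)
  rownames(m) <- as.character(ids)
  methods::new("ProteinAlignment", mat = m)
}

#' GroupPartition: assignment of every sequence to one subfamily
#'
#' Maps each alignment row to exactly one group label (for the bundled
#' THR-like LBD analysis these are the eight subfamilies THR, RAR, VDR,
#' LXR, PPAR, Rev, ROR and E78c). Sequence Harmony scanning requires at
#' least two groups; relative-entropy scanning accepts any partition.
#'
#' @slot mapping named character vector, sequence id -> group label.
#' @slot groups ordered character vector of distinct group labels.
#'
#' @param mapping named character vector (names are sequence ids).
#' @param groups label order; defaults to order of first appearance.
#'
#' @return A \code{GroupPartition} object.
#' @examples
#' GroupPartition(c(a = "THR", b = "THR", c = "RAR", d = "RAR"))
#' @export GroupPartition
#' @exportClass GroupPartition
setClass("GroupPartition",
         representation(mapping = "character", groups = "character"))

setValidity("GroupPartition", function(object) {
  ids <- names(object@mapping)
  if (is.null(ids) || any(!nzchar(ids)))
    return("mapping must be a named vector (sequence id -> group)")
  if (anyDuplicated(ids))
    return("each sequence id may appear only once in the mapping")
  if (any(is.na(object@mapping) | !nzchar(object@mapping)))
    return("group labels must be non-empty")
  if (length(object@groups) < 1L) return("at least one group is required")
  if (anyDuplicated(object@groups)) return("group labels must be distinct")
  if (!all(object@mapping %in% object@groups))
    return("every mapped label must occur in the group list")
  if (!all(object@groups %in% object@mapping))
    return("every group must contain at least one sequence")
  TRUE
})

GroupPartition <- function(mapping, groups = unique(unname(mapping))) {
  methods::new("GroupPartition", mapping = mapping,
               groups = as.character(groups))
}

#' BackgroundDistribution: amino-acid null frequencies
#'
#' The background (null) probability of each of the 20 canonical amino
#' acids, as estimated over a large sequence corpus. All probabilities
#' must be strictly positive (so that log-ratios stay finite); they are
#' renormalized to sum to one at construction.
#'
#' @slot probs named numeric vector of 20 probabilities in canonical
#'   amino-acid order.
#'
#' @param probs named numeric vector covering exactly the 20 amino acids.
#'
#' @return A \code{BackgroundDistribution} object.
#' @seealso [uniformBackground()], [swissprotBackground()], [readBackground()]
#' @export BackgroundDistribution
#' @exportClass BackgroundDistribution
setClass("BackgroundDistribution", representation(probs = "numeric"))

setValidity("BackgroundDistribution", function(object) {
  p <- object@probs
  if (!identical(names(p), AA20))
    return("background must cover exactly the 20 canonical amino acids")
  if (any(!is.finite(p)) || any(p <= 0))
    return("all 20 background probabilities must be strictly positive")
  if (abs(sum(p) - 1) > 1e-9)
    return("background probabilities must sum to 1 (within 1e-9)")
  TRUE
})

BackgroundDistribution <- function(probs) {
  if (is.null(names(probs)))
    stop("background probabilities must be named by amino acid")
  names(probs) <- toupper(names(probs))
  missing <- setdiff(AA20, names(probs))
  extra <- setdiff(names(probs), AA20)
  if (length(missing))
    stop("background is missing amino acid(s): ",
         paste(missing, collapse = ", "))
  if (length(extra))
    stop("background has unknown amino acid(s): ",
         paste(extra, collapse = ", "))
  p <- probs[AA20]
  if (any(!is.finite(p)) || any(p <= 0))
    stop("all background probabilities must be strictly positive")
  methods::new("BackgroundDistribution", probs = p / sum(p))
}

#' ColumnProfile: amino-acid composition of one alignment column
#'
#' Residue counts and frequencies for a single column (optionally over a
#' subset of rows). Gaps and \code{'X'} are excluded from the frequency
#' estimate and tracked through \code{gapFraction}; a column with no
#' contributing residues is unusable and carries an empty probability
#' vector.
#'
#' @slot column 1-based column index.
#' @slot counts named integer vector of residue counts (20 entries).
#' @slot probs named numeric vector of residue frequencies (20 entries,
#'   summing to 1), or \code{numeric(0)} when no residues contribute.
#' @slot gapFraction fraction of selected rows that are gap or 'X'.
#' @slot nEffective number of rows contributing residues.
#'
#' @seealso [columnProfile()]
#' @exportClass ColumnProfile
setClass("ColumnProfile",
         representation(column = "integer", counts = "numeric",
                        probs = "numeric", gapFraction = "numeric",
                        nEffective = "integer"))

setValidity("ColumnProfile", function(object) {
  if (object@nEffective > 0L) {
    if (!identical(names(object@probs), AA20))
      return("usable profile must carry 20 named probabilities")
    if (abs(sum(object@probs) - 1) > 1e-9)
      return("profile probabilities must sum to 1 (within 1e-9)")
  } else if (length(object@probs) != 0L) {
    return("unusable profile (nEffective = 0) must have empty probs")
  }
  if (object@gapFraction < 0 || object@gapFraction > 1)
    return("gapFraction must lie in [0, 1]")
  TRUE
})

#' ScoreTable: per-column scores with exclusion flags and metadata
#'
#' One row per alignment column, carrying whichever statistics have been
#' computed: relative entropy (\code{RE}), per-group Sequence Harmony
#' (\code{SH_<group>}), combined SH (\code{SH_combined}, the minimum over
#' groups), and the optional RELIEF-style weight (\code{MR_weight}).
#' Columns excluded by the gap policy carry \code{NA} scores (never 0) and
#' a reason string. Metadata records the provenance knobs: log base, gap
#' policy, grouping scheme, seed.
#'
#' @slot scores data.frame with at least \code{column}, \code{gap_fraction},
#'   \code{usable} and \code{reason} columns.
#' @slot metadata named list of run parameters.
#'
#' @param scores the per-column data.frame.
#' @param metadata named list.
#'
#' @return A \code{ScoreTable} object.
#' @export ScoreTable
#' @exportClass ScoreTable
setClass("ScoreTable",
         representation(scores = "data.frame", metadata = "list"))

setValidity("ScoreTable", function(object) {
  need <- c("column", "gap_fraction", "usable", "reason")
  miss <- setdiff(need, colnames(object@scores))
  if (length(miss))
    return(paste("score table lacks column(s):", paste(miss, collapse = ", ")))
  sh <- grep("^SH_", colnames(object@scores), value = TRUE)
  for (cn in sh) {
    v <- object@scores[[cn]]
    if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
      return(sprintf("%s values must lie in [0, 1]", cn))
  }
  if ("MR_weight" %in% colnames(object@scores)) {
    v <- object@scores$MR_weight
    if (any(v < -1 - 1e-9 | v > 1 + 1e-9, na.rm = TRUE))
      return("MR_weight values must lie in [-1, 1]")
  }
  TRUE
})

ScoreTable <- function(scores, metadata = list()) {
  methods::new("ScoreTable", scores = scores, metadata = metadata)
}

#' SiteSet: a selected set of alignment columns
#'
#' Columns selected by a recorded criterion (top-N relative entropy, or
#' combined Sequence Harmony below a cutoff). Columns are stored in rank
#' order, most extreme first (highest RE, or lowest SH), with ties broken
#' by ascending column index.
#'
#' @slot columns integer vector of 1-based column indices in rank order.
#' @slot criterion named list describing how the set was selected.
#'
#' @seealso [selectTop()], [selectLow()]
#' @exportClass SiteSet
setClass("SiteSet",
         representation(columns = "integer", criterion = "list"))

SiteSet <- function(columns, criterion = list()) {
  methods::new("SiteSet", columns = as.integer(columns),
               criterion = criterion)
}

#' ResidueMap: alignment columns vs reference residue numbering
#'
#' Bijection between the non-gap columns of one reference alignment row
#' and consecutive residue numbers (for the bundled analysis: human
#' thyroid hormone receptor alpha, PDB 1NAV chain A numbering). Gap
#' columns of the reference row are unmapped.
#'
#' @slot referenceId the alignment row used as reference.
#' @slot column mapped column indices (strictly increasing).
#' @slot residueNumber residue numbers (strictly increasing).
#' @slot residueLetter reference residue at each mapped column.
#'
#' @seealso [mapColumnsToResidues()]
#' @exportClass ResidueMap
setClass("ResidueMap",
         representation(referenceId = "character", column = "integer",
                        residueNumber = "integer",
                        residueLetter = "character"))

setValidity("ResidueMap", function(object) {
  n <- length(object@column)
  if (length(object@residueNumber) != n || length(object@residueLetter) != n)
    return("column, residueNumber and residueLetter must have equal length")
  if (n > 1L) {
    if (any(diff(object@column) <= 0L))
      return("mapped columns must be strictly increasing")
    if (any(diff(object@residueNumber) <= 0L))
      return("residue numbers must be strictly increasing")
  }
  TRUE
})

#' MotifTable: named column ranges (conserved motifs, interaction sites)
#'
#' Inclusive 1-based alignment-column ranges with unique names, used to
#' annotate selected sites and mutation positions. The packaged default
#' carries the seven conserved motifs of the THR-like LBD consensus
#' (Motif A 207-216 through Motif G 540-548); interaction-site ranges are
#' analysis-specific and must be supplied by the user.
#'
#' @slot ranges data.frame with columns name, start, end, category.
#'
#' @param ranges data.frame with columns \code{name}, \code{start},
#'   \code{end} and optionally \code{category}.
#'
#' @return A \code{MotifTable} object.
#' @seealso [defaultMotifs()], [annotateColumns()]
#' @export MotifTable
#' @exportClass MotifTable
setClass("MotifTable", representation(ranges = "data.frame"))

setValidity("MotifTable", function(object) {
  r <- object@ranges
  need <- c("name", "start", "end", "category")
  if (!all(need %in% colnames(r)))
    return(paste("motif table needs columns:", paste(need, collapse = ", ")))
  if (nrow(r)) {
    if (anyDuplicated(r$name)) return("motif names must be unique")
    if (any(r$start < 1L)) return("motif ranges are 1-based (start >= 1)")
    if (any(r$start > r$end)) return("motif start must not exceed end")
  }
  TRUE
})

MotifTable <- function(ranges) {
  if (is.null(ranges$category)) ranges$category <- "motif"
  ranges$start <- as.integer(ranges$start)
  ranges$end <- as.integer(ranges$end)
  methods::new("MotifTable",
               ranges = ranges[, c("name", "start", "end", "category")])
}

#' SyntheticConfig: parameters of the planted-column alignment generator
#'
#' @slot nGroups number of subfamilies (default 8).
#' @slot seqsPerGroup sequences per subfamily (default 20).
#' @slot length alignment length in columns (default 200).
#' @slot nFoldColumns planted globally conserved columns (default 30).
#' @slot nFunctionColumns planted subfamily-specific columns (default 30).
#' @slot conservationStrength probability that the designated residue is
#'   emitted at a planted column (default 0.95).
#' @slot gapRate i.i.d. per-cell gap probability (default 0.02).
#' @slot background BackgroundDistribution used for background draws.
#' @slot seed RNG seed; generation is fully deterministic given the seed.
#'
#' @seealso [syntheticConfig()], [generateAlignment()]
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
         representation(nGroups = "integer", seqsPerGroup = "integer",
                        length = "integer", nFoldColumns = "integer",
                        nFunctionColumns = "integer",
                        conservationStrength = "numeric",
                        gapRate = "numeric",
                        background = "BackgroundDistribution",
                        seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  if (object@nGroups < 1L) return("nGroups must be >= 1")
  if (object@seqsPerGroup < 1L) return("seqsPerGroup must be >= 1")
  if (object@length < 1L) return("length must be >= 1")
  if (object@nFoldColumns < 0L || object@nFunctionColumns < 0L)
    return("planted column counts must be non-negative")
  if (object@nFoldColumns + object@nFunctionColumns > object@length)
    return("planted columns cannot exceed the alignment length")
  if (object@nFunctionColumns > 0L && object@nGroups > 20L)
    return("function columns need distinct residues per group: nGroups <= 20")
  if (object@conservationStrength <= 0 || object@conservationStrength > 1)
    return("conservationStrength must lie in (0, 1]")
  if (object@gapRate < 0 || object@gapRate >= 1)
    return("gapRate must lie in [0, 1)")
  TRUE
})

#' SyntheticTruth: the planted column classes of a generated alignment
#'
#' @slot foldColumns indices of planted globally conserved columns.
#' @slot functionColumns indices of planted subfamily-specific columns.
#' @slot foldResidues named character, fold column -> designated residue.
#' @slot functionResidues list, function column -> named character vector
#'   (group label -> designated residue for that group).
#'
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
         representation(foldColumns = "integer", functionColumns = "integer",
                        foldResidues = "character",
                        functionResidues = "list"))

setValidity("SyntheticTruth", function(object) {
  if (length(intersect(object@foldColumns, object@functionColumns)))
    return("fold and function column sets must be disjoint")
  TRUE
})
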