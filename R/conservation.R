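## Column profiles and relative-entropy (fold-specificity) scoring.
##
## A column's relative entropy (Kullback-Leibler divergence) against the
## amino-acid background,
##
##     RE_i = sum_x p_i(x) * log( p_i(x) / p_null(x) ),
##
## measures how atypically conserved the column is: 0 when the column
## composition equals the background, log(1/p_null(a)) when the column is
## fixed at residue a. Gaps and 'X' never enter p_i; they are tracked as
## the column's gap fraction and gate exclusion instead. No pseudocounts
## are used: zero-probability terms contribute 0 (0*log 0 convention), and
## strict background positivity keeps every other term finite.

#' Amino-acid profile of one alignment column
#'
#' Counts and frequencies of the 20 amino acids in one column, optionally
#' restricted to a subset of sequences. Gap ('-') and unknown ('X')
#' characters are excluded from the frequency estimate and reported via
#' \code{gapFraction}; a column whose selected rows are all gap/'X' is
#' unusable (\code{nEffective = 0}, empty probabilities).
#'
#' @param alignment a [ProteinAlignment-class].
#' @param column 1-based column index.
#' @param rows optional character vector of sequence ids to restrict to.
#' @return A [ColumnProfile-class].
#' @examples
#' aln <- ProteinAlignment(c(a = "AA", b = "AA", c = "AC", d = "A-"))
#' columnProfile(aln, 2)
#' @export
columnProfile <- function(alignment, column, rows = NULL) {
  stopifnot(methods::is(alignment, "ProteinAlignment"))
  column <- as.integer(column)
  if (column < 1L || column > alignmentLength(alignment))
    stop(sprintf("column %d out of range [1, %d]", column,
                 alignmentLength(alignment)))
  m <- alignment@mat
  if (!is.null(rows)) {
    if (!length(rows)) stop("row subset must be non-empty")
    missing <- setdiff(rows, rownames(m))
    if (length(missing))
      stop("unknown sequence id(s): ", paste(missing, collapse = ", "))
    m <- m[rows, , drop = FALSE]
  }
  chars <- m[, column]
  .profileFromChars(chars, column)
}

.profileFromChars <- function(chars, column) {
  isGap <- chars == GAP_CHAR | chars == UNKNOWN_CHAR
  counts <- stats::setNames(
    as.numeric(table(factor(chars[!isGap], levels = AA20))), AA20)
  nEff <- as.integer(sum(!isGap))
  methods::new("ColumnProfile",
               column = as.integer(column),
               counts = counts,
               probs = if (nEff > 0L) counts / nEff else numeric(0),
               gapFraction = if (length(chars)) mean(isGap) else 0,
               nEffective = nEff)
}

#' Is a column profile usable?
#'
#' @param x a \code{ColumnProfile}.
#' @return \code{TRUE} when at least one row contributed a residue.
#' @export
setGeneric("isUsable", function(x) standardGeneric("isUsable"))

#' @rdname isUsable
#' @export
setMethod("isUsable", "ColumnProfile", function(x) x@nEffective > 0L)

#' Residue frequencies of a column profile
#'
#' @param x a \code{ColumnProfile}.
#' @return Named numeric vector of 20 frequencies (empty when unusable).
#' @export
setGeneric("profileProbs", function(x) standardGeneric("profileProbs"))

#' @rdname profileProbs
#' @export
setMethod("profileProbs", "ColumnProfile", function(x) x@probs)

#' Gap fraction of a column profile
#'
#' @param x a \code{ColumnProfile}.
#' @return Fraction of rows that are gap or 'X', in [0, 1].
#' @export
setGeneric("gapFraction", function(x) standardGeneric("gapFraction"))

#' @rdname gapFraction
#' @export
setMethod("gapFraction", "ColumnProfile", function(x) x@gapFraction)

setMethod("show", "ColumnProfile", function(object) {
  if (object@nEffective == 0L) {
    cat(sprintf("ColumnProfile [col %d]: unusable (no residues)\n",
                object@column))
  } else {
    p <- sort(object@probs[object@probs > 0], decreasing = TRUE)
    cat(sprintf("ColumnProfile [col %d]: n=%d, gap=%.2f | %s\n",
                object@column, object@nEffective, object@gapFraction,
                paste(sprintf("%s:%.2f", names(p), p), collapse = " ")))
  }
})

#' Relative entropy of a column profile against a background
#'
#' Computes \eqn{RE = \sum_x p(x) \log(p(x)/p_{null}(x))} term by term,
#' with zero-probability terms contributing 0. Natural log by default;
#' base 2 yields bits (\code{RE_bits = RE_nats / ln 2}). An unusable
#' profile yields \code{NA} (never a silent 0).
#'
#' @param profile a [ColumnProfile-class].
#' @param background a [BackgroundDistribution-class].
#' @param logBase \code{"e"} (nats, default) or \code{"2"} (bits).
#' @return Non-negative numeric score, or \code{NA} for an unusable
#'   profile.
#' @examples
#' aln <- ProteinAlignment(c(a = "A", b = "A", c = "A", d = "C"))
#' relativeEntropy(columnProfile(aln, 1), uniformBackground())
#' @export
relativeEntropy <- function(profile, background, logBase = c("e", "2")) {
  stopifnot(methods::is(profile, "ColumnProfile"),
            methods::is(background, "BackgroundDistribution"))
  logBase <- match.arg(as.character(logBase), c("e", "2"))
  if (!isUsable(profile)) return(NA_real_)
  p <- profile@probs
  q <- background@probs
  s <- 0
  for (x in AA20) {
    px <- p[[x]]
    if (px > 0) s <- s + px * log(px / q[[x]])
  }
  if (logBase == "2") s <- s / log(2)
  ## Gibbs' inequality guarantees RE >= 0; trim float noise at the bound
  if (s < 0 && s > -1e-9) s <- 0
  s
}

#' Scan all columns for relative entropy
#'
#' Computes RE for every column whose gap fraction does not exceed
#' \code{maxGapFraction}; other columns are flagged excluded with a
#' reason and carry \code{NA} scores, so they can never enter a top-N
#' selection. The scan is a vectorized matrix computation over the
#' per-column count matrix.
#'
#' @param alignment a [ProteinAlignment-class].
#' @param background a [BackgroundDistribution-class]; default the
#'   packaged Swiss-Prot composition.
#' @param maxGapFraction exclusion threshold on the per-column gap/'X'
#'   fraction (default 0.5).
#' @param logBase \code{"e"} (default) or \code{"2"}.
#' @param rows optional subset of sequence ids.
#' @return A [ScoreTable-class] with the \code{RE} column filled.
#' @export
reScan <- function(alignment, background = swissprotBackground(),
                   maxGapFraction = 0.5, logBase = c("e", "2"),
                   rows = NULL) {
  stopifnot(methods::is(alignment, "ProteinAlignment"),
            methods::is(background, "BackgroundDistribution"))
  logBase <- match.arg(as.character(logBase), c("e", "2"))
  m <- alignment@mat
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  L <- ncol(m)
  counts <- .columnCounts(m)                       # 20 x L
  gapm <- m == GAP_CHAR | m == UNKNOWN_CHAR
  nEff <- nrow(m) - colSums(gapm)
  gapFrac <- colMeans(gapm)
  P <- sweep(counts, 2L, pmax(nEff, 1L), "/")
  q <- background@probs
  ratio <- P / q                                   # recycles q down columns
  term <- P * log(ratio)
  term[P == 0] <- 0
  re <- colSums(term)
  if (logBase == "2") re <- re / log(2)
  re[re < 0 & re > -1e-9] <- 0
  usable <- nEff > 0 & gapFrac <= maxGapFraction
  reason <- rep("", L)
  reason[gapFrac > maxGapFraction] <- "gap_fraction_exceeds_max"
  reason[nEff == 0] <- "no_residues"
  re[!usable] <- NA_real_
  df <- data.frame(column = seq_len(L), gap_fraction = gapFrac,
                   n_effective = as.integer(nEff), RE = re,
                   usable = usable, reason = reason,
                   stringsAsFactors = FALSE)
  ScoreTable(df, metadata = list(statistic = "RE", log_base = logBase,
                                 max_gap_fraction = maxGapFraction))
}

## 20 x L residue count matrix of an alignment character matrix.
.columnCounts <- function(m) {
  out <- vapply(AA20, function(a) colSums(m == a), numeric(ncol(m)))
  ## vapply returns L x 20; transpose to 20 x L with AA rownames
  t(matrix(out, ncol = 20L, dimnames = list(NULL, AA20)))
}

#' Select the top-N columns by a score
#'
#' Returns the \code{n} highest-scoring usable columns (default statistic
#' \code{RE}), ties broken by ascending column index. The returned set
#' stores columns in rank order (highest score first) and records the
#' selection criterion.
#'
#' @param table a [ScoreTable-class].
#' @param statistic score column to rank by (default \code{"RE"}).
#' @param n number of columns to select.
#' @return A [SiteSet-class].
#' @examples
#' tb <- scoreTableFromScores(1:3, c(1, 3, 2), "RE")
#' siteColumns(selectTop(tb, n = 2))
#' @export
selectTop <- function(table, statistic = "RE", n) {
  stopifnot(methods::is(table, "ScoreTable"))
  df <- table@scores
  if (!statistic %in% colnames(df))
    stop(sprintf("statistic '%s' not present in score table", statistic))
  n <- as.integer(n)
  if (n < 1L) stop("n must be a positive integer")
  ok <- df$usable & !is.na(df[[statistic]])
  if (sum(ok) < n)
    stop(sprintf("selection-size error: only %d usable %s scores, need %d",
                 sum(ok), statistic, n))
  sub <- df[ok, c("column", statistic)]
  ord <- order(-sub[[statistic]], sub$column)
  SiteSet(sub$column[ord][seq_len(n)],
          criterion = list(statistic = statistic, type = "top", n = n))
}
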