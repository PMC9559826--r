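## Background (null) amino-acid distributions.

#' Uniform amino-acid background
#'
#' Every canonical amino acid at probability 1/20.
#'
#' @return A [BackgroundDistribution-class].
#' @examples
#' uniformBackground()
#' @export
uniformBackground <- function() {
  BackgroundDistribution(stats::setNames(rep(1 / 20, 20), AA20))
}

#' Swiss-Prot composition background
#'
#' The per-residue amino-acid composition of UniProtKB/Swiss-Prot
#' (release statistics; provenance header in the packaged file),
#' renormalized on load. This is the package default null model for
#' relative-entropy conservation scoring.
#'
#' @return A [BackgroundDistribution-class].
#' @examples
#' swissprotBackground()
#' @export
swissprotBackground <- function() {
  readBackground(system.file("extdata", "swissprot_background.tsv",
                             package = "SpecSites", mustWork = TRUE))
}

#' Read an amino-acid background table
#'
#' Two-column TSV: one-letter amino-acid code, probability (or relative
#' frequency; renormalized). Errors on missing, duplicated or unknown
#' amino acids and on non-positive values.
#'
#' @param path TSV file ('#' comment lines allowed, header optional).
#' @return A [BackgroundDistribution-class].
#' @export
readBackground <- function(path) {
  if (!file.exists(path)) stop("background file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2L)
    stop("background table must have two columns (amino acid, probability)")
  df <- df[, 1:2]
  colnames(df) <- c("aa", "prob")
  df$aa <- toupper(trimws(df$aa))
  if (nrow(df) && !(df$aa[1L] %in% AA20)) df <- df[-1L, , drop = FALSE]
  if (anyDuplicated(df$aa))
    stop("duplicated amino acid(s) in background table: ",
         paste(unique(df$aa[duplicated(df$aa)]), collapse = ", "))
  BackgroundDistribution(stats::setNames(as.numeric(df$prob), df$aa))
}

#' Background probabilities
#'
#' @param x a \code{BackgroundDistribution}.
#' @return Named numeric vector of 20 probabilities (canonical order).
#' @export
setGeneric("backgroundProbs", function(x) standardGeneric("backgroundProbs"))

#' @rdname backgroundProbs
#' @export
setMethod("backgroundProbs", "BackgroundDistribution", function(x) x@probs)

setMethod("show", "BackgroundDistribution", function(object) {
  cat("BackgroundDistribution over 20 amino acids\n")
  top <- sort(object@probs, decreasing = TRUE)[1:3]
  cat(sprintf("  most frequent: %s\n",
              paste(sprintf("%s=%.4f", names(top), top), collapse = " ")))
})
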