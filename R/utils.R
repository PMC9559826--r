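## Shared constants and small internal helpers.

## Canonical 20-amino-acid alphabet, in the fixed order used by every
## profile/background vector in the package.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHAR <- "-"
UNKNOWN_CHAR <- "X"

## Full alignment alphabet: residues + unknown + gap. Ambiguity codes
## (B/Z/U/O) and '*' are deliberately rejected at parse time.
ALN_ALPHABET <- c(AA20, UNKNOWN_CHAR, GAP_CHAR)

#' @importFrom utils read.delim write.table head
.readTSV <- function(path, header = TRUE, ...) {
  utils::read.delim(path, sep = "\t", header = header, comment.char = "#",
                    stringsAsFactors = FALSE, quote = "", ...)
}

## Evaluate `code` with the RNG seeded at `seed`, restoring the caller's
## RNG state afterwards so library calls never perturb user simulations.
.withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

## Format numerics with 6 decimals, NA as literal "NA" (the score-table
## sentinel for excluded columns; never written as 0).
.fmtNum <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))
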