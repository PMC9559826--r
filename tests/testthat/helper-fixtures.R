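## Shared helpers: in-code fixtures, no files on disk except via tempfile.

## canonical amino-acid order used by the package
AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## Wrap a bare probability vector (length 20, package order) as a usable
## ColumnProfile without going through an alignment.
makeProfile <- function(p, n = 100L, column = 1L) {
  p <- p / sum(p)
  methods::new("ColumnProfile", column = as.integer(column),
               counts = stats::setNames(p * n, AA),
               probs = stats::setNames(p, AA),
               gapFraction = 0, nEffective = as.integer(n))
}

## Random strictly positive background
randomBackground <- function() {
  BackgroundDistribution(stats::setNames(stats::rexp(20) + 1e-3, AA))
}

## Random gapped alignment as a ProteinAlignment
randomAlignment <- function(n, L, gapRate = 0.05) {
  chars <- sample(AA, n * L, replace = TRUE)
  gap <- stats::runif(n * L) < gapRate
  chars[gap] <- "-"
  m <- matrix(chars, nrow = n, ncol = L)
  ProteinAlignment(apply(m, 1L, paste0, collapse = ""),
                   ids = sprintf("s%03d", seq_len(n)))
}

writeFastaTmp <- function(seqs, ids = names(seqs)) {
  f <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), unname(seqs))), f)
  f
}

## naive per-term relative entropy, independent of the package path
naiveRE <- function(p, q, base = exp(1)) {
  s <- 0
  for (i in seq_along(p)) if (p[i] > 0) s <- s + p[i] * log(p[i] / q[i])
  s / log(base)
}
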