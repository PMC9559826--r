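---
title: "Detecting fold- and function-specific residues with SpecSites"
author: "SpecSites maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fold- and function-specific residues with SpecSites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpecSites)
```

## The two conservation signals

A protein family that shares one fold but has diverged into subfamilies
with different ligands or partners — the motivating case is the thyroid
hormone receptor-like (NR1) ligand-binding domain family, with its THR,
RAR, VDR, LXR, PPAR, Rev-ErbA, ROR and E78C subfamilies — superimposes
two conservation signals in its multiple sequence alignment:

1. columns conserved *family-wide*, which maintain the shared fold, and
2. columns conserved *within* subfamilies but *different between* them,
   which encode functional specificity (specificity-determining
   positions, SDPs).

SpecSites scores the first signal with per-column **relative entropy**
against an amino-acid background and the second with multi-group
**Sequence Harmony**, then supports the downstream steps of a typical
analysis: mapping selected columns onto a reference structure's residue
numbering, annotating them with conserved motifs, and classifying
natural disease mutations by which site set their alignment position
falls into.

## Relative entropy (fold-specific signal)

For column $i$ with residue frequencies $p_i(x)$ and background
$p_{\mathrm{null}}(x)$,

$$RE_i \;=\; \sum_{x=1}^{20} p_i(x)\,\log\frac{p_i(x)}{p_{\mathrm{null}}(x)},$$

with $0 \log 0 \equiv 0$. By Gibbs' inequality $RE_i \ge 0$, with
equality exactly when the column matches the background; a column fixed
at residue $a$ attains $\log(1/p_{\mathrm{null}}(a))$. Both bounds are
exercised by the test suite, and the vectorized scan (`reScan()`) is
tested for exact agreement (within $10^{-12}$) with naive term-by-term
summation.

**Numerical choices.**

* *No pseudocounts.* Zero-frequency terms contribute 0 by convention and
  the background is required to be strictly positive, so no smoothing is
  needed and the statistic matches its definition exactly.
* *Log base.* Natural log by default (scores in nats); base 2 is
  available and equals the natural-log score divided by $\ln 2$. The
  choice is recorded in the score-table metadata.
* *Background.* The default is the packaged Swiss-Prot composition
  (UniProtKB/Swiss-Prot release statistics, renormalized on load); a
  uniform $1/20$ background is built in. Backgrounds are validated to
  cover exactly the 20 canonical amino acids with positive mass.

## Sequence Harmony (function-specific signal)

The literature definition of SH is stated as a relative entropy of one
group against the pooled probabilities of both groups; written that way
the sum is non-positive, while the score is universally described as
lying in $[0,1]$. We therefore implement the negated, base-2,
symmetrized form — the one that actually realizes the stated range:

$$SH(A,B) = \tfrac12\bigl(H(A|B) + H(B|A)\bigr),\qquad
H(A|B) = -\sum_x p^A(x)\,\log_2\frac{p^A(x)}{p^A(x)+p^B(x)},$$

so that $SH = 1$ for identical compositions and $SH = 0$ for disjoint
residue usage. Symmetry is exact (the same terms are summed either way),
and the test suite checks the bounds on $10^4$ random profile pairs, a
hand-derived worked value, and monotone growth of SH as one composition
is mixed continuously into another.

**Multi-group combination.** With $K > 2$ subfamilies each group $g$ is
scored one-vs-rest: the group's column profile against the *pooled*
profile of all other rows (pooling, rather than averaging per-group
profiles, keeps the comparison at the sequence level and matches
one-vs-rest semantics). The combined per-column score is the **minimum**
over groups — the most subfamily-specific signal present — with all
per-group values retained in the table. A `pairwise_min` scheme
(minimum over all group pairs) is available as an alternative. With two
groups both schemes reduce to the single pairwise score, which the tests
verify.

**Selection.** Function-specific sites are the usable columns with
combined $SH$ strictly below a cutoff, default 0.4, reported ascending
by score and capped by default at the 30 lowest; fold-specific sites are
the top-30 columns by RE. Ties are broken by ascending column index so
selections are deterministic. The defaults mirror the reference
THR-like LBD analysis bundled with the package (`thrReferenceScores()`),
where the same rules return 30 sites each with extremes C392 (lowest
SH) and F239 (highest RE).

## Gap policy and exclusion flags

Gaps (`-`) and unknown residues (`X`) never enter a column's frequency
vector; they accumulate in the column's gap fraction. Columns whose gap
fraction exceeds `maxGapFraction` (default 0.5, shared by both scans)
are excluded: their scores are an `NA` sentinel — never 0, so an
excluded column can never sneak into a top-N selection — and the reason
is recorded per column. Within the SH scan a group contributing fewer
than two residues at a column is skipped there (noted in the reason
string) and the combined score uses the remaining groups; if no group
pair remains, the column is excluded. All-gap rows and columns are
rejected or flagged rather than silently handled.

The alphabet is deliberately strict: the 20 canonical amino acids plus
`X` and `-` (input `.` is normalized to `-`, lowercase to uppercase).
Ambiguity codes B/Z/U/O are rejected at parse time with the offending
row and column named, which keeps the statistical contract of every
downstream stage unambiguous.

## RELIEF-style weighting

`multiRelief()` provides an independent, sampling-based view of the same
between-group signal, in the spirit of the RELIEF family of
feature-weighting algorithms: over sampled group pairs, within-group
sequence pairs ("hits") and between-group pairs ("misses") are drawn,
and a column's weight is the miss-disagreement rate minus the
hit-disagreement rate (identity metric, gaps comparing as ordinary
characters), averaged over rounds. The weight lies in $[-1,1]$: 0 for
an invariant column, $+1$ in the limit of a residue private to each
group. It is deterministic given its seed (the caller's RNG state is
saved and restored) and is intentionally *not* part of the default
function-specific selection — it serves as a cross-check.

## Column-to-residue mapping and motifs

`mapColumnsToResidues()` numbers the non-gap columns of a chosen
reference row consecutively from a caller-supplied first residue number.
This reproduces a crystal structure's author numbering (e.g. thyroid
hormone receptor alpha, PDB 1NAV chain A) when the offset of the first
modeled residue is given; the package stays structure-file-free by
design, and a numbering derived from a PDB file can be fed through the
same interface. Insertions relative to the crystal construct are not
modeled — numbering is strictly consecutive.

`defaultMotifs()` ships the seven conserved motifs of the THR-like LBD
consensus (Motif A 207–216 … Motif G 540–548). The family's five
interaction sites have no published coordinates (published descriptions
of their locations are mutually inconsistent), so they are deliberately
not packaged; user-supplied ranges go through `readMotifs()`.
Annotation is total: every queried column yields all containing ranges,
possibly none.

## Mutation classification

The mutation stage parses compact clinical tokens (`R429Q/W`;
`Del337T`, where — inverting the usual order — the *deleted* residue
follows the position) and classifies each record by set membership of
its alignment position: in the fold set only → `Fold`, function set
only → `Function`, both → `Fold/Function`, neither → `Unclassified`;
records whose position cannot be resolved (directly or via a residue
map) are flagged and excluded from tallies. The published description
of this classification scheme does not spell out the rule; membership
in the top-N RE and SH-below-cutoff sets (defaults N = 30, cutoff 0.4)
is the natural reading and is what we implement. The packaged
47-record THR-like LBD disease compilation carries its curated labels,
and the test suite shows the rule reproduces them exactly when the site
sets are reconstructed from those labels.

## The synthetic benchmark

`generateAlignment()` plants three column classes in a
subfamily-partitioned alignment:

* **fold columns** — one designated residue drawn from the background,
  emitted with probability `conservationStrength` in *every* sequence;
* **function columns** — a distinct designated residue per group
  (sampled without replacement, hence at most 20 groups), emitted with
  `conservationStrength` *within* each group;
* **background columns** — i.i.d. background draws;

with gaps injected i.i.d. per cell afterwards. Defaults — 8 groups × 20
sequences, 200 columns, 30 + 30 planted columns, conservation 0.95, gap
rate 0.02, Swiss-Prot background — describe a family of moderate depth
with strong but imperfect site conservation, sized so the full
generate–scan–select–evaluate cycle runs in seconds. Generation is
fully deterministic given the seed.

What the generator does *not* emulate: phylogenetic correlation between
sequences (columns are exchangeable given their class), block-wise or
lineage-specific gapping, unequal subfamily sizes (an option exists but
is outside the benchmark), and partially shared specificity residues
between subfamily subsets (available via softer configurations, also
outside the benchmark). Passing the benchmark therefore demonstrates
that the statistics and selection rules recover exactly the signal they
define, with calibrated precision/recall bookkeeping
(`evaluateRecovery()`); it does not certify performance on real,
phylogenetically structured families.

Benchmark sizes used throughout the tests: the default 160 × 200
benchmark for recovery, 50 × 200 alignments for the vectorized-vs-naive
oracle, $10^4$ randomized profile pairs for the RE and SH property
suites, and group depths 20/80/320 for the background-RE shrinkage
check.

## Known limitations

* SH applies no correction for unequal subfamily sizes; a strongly
  dominant subfamily pulls the pooled "rest" profile towards itself.
* Published per-residue score tables for the THR-like family are keyed
  by structure residue number, and the column↔residue map of the
  original 1158-sequence family alignment was never deposited, so those
  scores are treated as an external score list (selection rules apply)
  rather than recomputed bit-exactly.
* No sequence-redundancy downweighting is applied; redundancy handling
  (e.g. identity clustering) is expected upstream.
* The RELIEF weight is a deliberate simplification (identity metric,
  uniform pair sampling) of the published family of algorithms.
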