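---
title: "Methods: marker selection, bait QC, saturation and barcoding in phylocap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker selection, bait QC, saturation and barcoding in phylocap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocap)
```

phylocap implements the computational steps of a universal
target-enrichment workflow: choosing which loci a bait panel should
target, choosing which sequences represent each locus, designing and
quality-filtering the baits, judging how many loci a stable phylogeny
needs, cleaning multi-copy capture extractions, and identifying unknown
samples by multilocus distance barcoding. This vignette explains each
model, its assumptions, the tunable parameters, and the numerical
decisions that the function reference does not cover.

## Distances

Two pairwise metrics operate on aligned sequences. The **uncorrected
p-distance** is the fraction of differing sites among comparable columns,
where a column is comparable only when both sequences carry an unambiguous
A/C/G/T; gaps and IUPAC ambiguity codes are deleted pairwise. Treating
ambiguity codes as missing avoids inflating distances from low-quality
capture consensus sequences; the cost is that a column with many Ns
contributes nothing. The **blastn-score distance**, used by the barcode
skim, scores comparable columns +5 for a match and −4 for a mismatch and
maps the total S onto a distance 1 − S/(5·L), where 5·L is the maximum
attainable score over the L comparable columns; values are clamped to
[0, 1] (a pair with more than ~55% mismatches would otherwise exceed 1).
Both metrics are symmetric, zero exactly on identical comparable columns,
and error when no column is comparable — the caller decides whether an
undefined pair invalidates a matrix or merely skips a neighbor.

Whether an upstream implementation of the score-based distance skipped or
scored gap columns is not something we claim to reproduce; skipping them
is this package's documented convention, chosen so that both metrics see
the same column support.

## Marker selection by k-medoids convergence

For each locus the package asks: what is the smallest number of actual
sequences (medoids) that can represent the locus's observed diversity?
The clustering is PAM-style k-medoids on the p-distance matrix:

1. draw k distinct random initial medoids (seeded);
2. assign every sequence to its nearest medoid, ties to the
   lexicographically smallest medoid id;
3. replace each cluster's medoid by the member minimizing the
   within-cluster distance sum, ties again lexicographic;
4. repeat until the medoid set is stable.

This alternating update never increases the total assigned distance, so
it terminates; all tie-breaks are deterministic, so a run is a pure
function of the matrix, k and the seed. For each k the search runs
`restarts` restarts (default 100) with seeds derived by hashing
(base seed, gene id, k, restart index) — reruns are reproducible and no
two restarts share a seed. A gene **converges** at the smallest k whose
best restart places at least `f_conv` (default 0.95) of the sequences
within `d_max` (default 0.25, with 0.20 and 0.30 the standard
alternatives) of their medoid. k is searched ascending because the
selection goal is minimality — the fewest representative sequences that
still cover the species diversity of the locus. The 95% fraction is
evaluated per restart over all rows, medoids included (a medoid is within
distance 0 of itself). Genes whose aligned exons are shorter than 600 bp
are discarded before clustering: shorter exons yield too few tiled baits
to capture reliably. Both boundaries are inclusive/exclusive exactly as
tested: a 600 bp gene is clustered, a 599 bp gene is dropped; a
fraction of exactly 0.95 converges, 0.94 does not.

The metric behind these thresholds is the package's choice: the d_max
values are on the p-distance scale, bounded in [0, 1], which matches how
the thresholds are quoted and keeps the convergence fraction
interpretable as "sequences within 25% divergence of a representative".

## Bait design and QC

Representative sequences are gap-stripped, N-runs of length 1–10 are
rewritten to T (hybridization tolerates a few mismatches; longer runs
mean the template is unknown and the bait is later discarded as
RESIDUAL_N), and 80 bp windows are tiled at a 40 bp step (2× tiling).
When the final regular window stops short of the end, one flush window
[L−80, L) is appended so every base is covered; interior bases are
covered exactly twice. Sources shorter than one bait yield no windows and
are reported as `too_short`.

Each bait is annotated independently, and `passed` is the conjunction of
all checks, so filter order is irrelevant:

* **GC**: pass only if 25 < GC% < 67, strict at both ends (a bait at
  exactly 25.0% or 67.0% fails).
* **Repeat**: the soft-masked (lowercase) fraction of the window must not
  exceed 35%; the same bound applies to the window extended by 80 bp on
  each side (clipped at the source ends). Soft-masking is the standard
  carrier of repeat annotation in FASTA, so the package takes the
  annotation as given rather than bundling a repeat finder.
* **Multi-hit**: the bait must not match two or more distinct loci across
  the supplied reference genomes. The screen is an internal deterministic
  seed-and-extend: exact 16-mers shared between bait and genome propose
  diagonals; a diagonal is a locus when the ungapped overlap is at least
  60 bp with identity at least 0.90; both strands are scanned
  (hybridization is strand-agnostic) and loci overlapping by more than
  the 40 bp tile step are merged. A precomputed hit count can be supplied
  instead, so an external BLAST screen slots in transparently. With no
  genomes supplied the screen is skipped with a warning in the report,
  not a flag on the bait.

## Tree toolkit

**Neighbor joining** is the internal tree builder: the classic
Q-criterion agglomeration, with negative branch-length estimates clamped
to zero and ties between candidate joins broken by the lexicographically
smallest pair of subtree labels, making the output deterministic. NJ is
consistent on additive matrices — it reconstructs the generating tree and
its branch lengths exactly, which the tests verify to 1e-9 on random
trees — and it is fast enough to sit inside bootstrap loops and
saturation scans. Wherever a tree is an input, an externally inferred
Newick (e.g. a maximum-likelihood tree) can be supplied instead; the
internal builder is a surrogate for desk-scale, dependency-free runs, not
a claim that NJ replaces ML inference.

**Bootstrap supports** resample alignment columns with replacement,
rebuild the NJ tree per replicate, and attach to each internal edge the
percentage of replicates whose tree contains that bipartition. A
replicate whose resampled columns leave some pair with no comparable
sites is redrawn (at most 10 times) rather than silently dropped.

**Robinson–Foulds distances** are computed on canonical bipartition sets:
each internal edge splits the leaves in two, and the side not containing
a fixed reference leaf (the lexicographically smallest) is the stored
key. Two trees are first pruned to their shared leaves (degree-2 nodes
suppressed; at least 4 shared leaves required). RF is the symmetric
difference of the two sets, and nRF divides by RF_max = (nontrivial
splits of A) + (nontrivial splits of B) — which equals 2(n−3) for binary
trees and degrades gracefully for polytomies.

**Outlier gene trees** are removed with an iterative modified
Thompson-tau rule on each gene's mean nRF to all other gene trees (plus
the species tree as one extra comparator when provided — an open choice;
equal weight is the simplest defensible reading). At each step the
threshold is τ·s with τ = t·(n−1)/(√n·√(n−2+t²)), t the two-sided Student
critical value at α = 0.05 with n−2 degrees of freedom; the single most
deviant value (ties: the larger) is removed and the statistics are
recomputed. The procedure stops when nothing exceeds the threshold, when
the standard deviation is zero, or when fewer than three values remain.
Users should know this test is liberal: on clean i.i.d. scores it still
trims a point in roughly a fifth of samples (about 3% of points), which
in this context errs on the side of discarding a usable locus rather than
keeping a discordant one.

**Topology clusters**: the gene-tree nRF matrix is embedded in 2D by
classical (Torgerson) metric MDS — double-centering and
eigendecomposition, keeping the top two non-negative eigenvalues (nRF
matrices need not be Euclidean, so negative eigenvalues are truncated at
zero) — followed by density-based clustering. The neighborhood radius
defaults to half the median pairwise embedded distance, a scale-free
choice that makes "two clouds far apart" come out as two clusters without
per-data-set tuning; points in no dense neighborhood are labeled −1
(noise). An all-zero distance matrix is one cluster by definition.

**Concordance counts**: for each species-tree bipartition, every gene
tree is concordant (contains the bipartition after restriction to shared
leaves), conflicting (contains an incompatible bipartition — all four
side intersections non-empty), or uninformative (fewer than two shared
leaves on either side, or unresolved). The three counts always sum to the
number of gene trees. This is a deliberately simplified, unrooted
bipartition counter, not a duplication-aware mapping.

## Saturation analysis

Genes are added stepwise (default 20 at a time) to a growing concatenated
matrix, in seeded random order or ordered by increasing relative rate.
The rate surrogate is the gene's mean pairwise p-distance: only the
ordering of loci matters for this analysis, and on simulated data the
surrogate preserves the true rate order (checked as a ≥95% recovery over
seeded simulations). Each point builds an NJ + bootstrap tree and records
the nRF to the reference and the mean internal-edge support. The
reference defaults to the full-set tree from the same builder — so the
final point is exactly 0 by construction and the curve reads as
"distance from the answer you would get with everything" — and a
published phylogeny can be supplied instead. Concatenation pads
sample-by-gene blocks missing from a locus with gaps by default (N is the
alternative, exposed because downstream tools differ in how they treat
the two); a partition table records every locus interval 0-based
half-open, with the RAxML-style export converted to 1-based inclusive
and flagged as such in its header.

## Capture filtering

Capture of universal markers from fungal (especially herbarium) material
routinely co-captures other organisms, so a gene extracted in several
copies may be a paralog or a contaminant ortholog. The filter compares
the deepest copy c1 against the next deepest c2: the depth condition is
c1 ≥ 10·c2, inclusive at the boundary (a ratio of exactly 10 passes; the
tests pin 30:3 retained and 99.9:10 dropped). In `strict` mode a cell
failing the condition is dropped entirely; in `default` mode the copy
most similar to the gene's reference is retained instead (ties broken by
deeper coverage, then copy id). Similarity is the identity over aligned
non-gap columns of a global pairwise alignment (match +1, mismatch −1,
gap open 5, extend 1) — a documented surrogate for whatever aligner score
produced the copies. Coverage values are taken as given from the copy
headers (`sample|gene|copy|cov=<float>`) or a TSV; the filter only ever
uses ratios, so the absolute scale (per-base mean vs assembler k-mer
coverage) does not matter. Completeness is min(1, extracted non-gap
length / reference length) per sample and gene, 0 for missing or dropped
cells; the uncapped raw fraction is preserved in the long-form table so
over-length extractions remain visible.

Strict mode always retains a subset of default mode, and raising the
ratio threshold never retains more multi-copy genes; both monotonicities
are property-tested.

## Multilocus barcoding

A query sample's per-gene sequences are inserted into the prealigned
database: each query is globally aligned against the gene's
majority-consensus profile (match +1, mismatch −1, gap open 5, extend 1)
and query insertions relative to the database columns are discarded, so
the database column space — and with it all concatenation coordinates —
stays fixed. A query whose normalized alignment score is negative shows
no credible homology and the gene is skipped with a warning. Alignments
are then block-filtered (columns with more than 50% gaps removed, then
surviving column runs shorter than 3 removed) and concatenated. The skim
computes the blastn-score distance from the query to every database row,
sorts ascending with ties kept in database order, and greedily takes rows
— skipping any that would exceed 4 of one species — until 20 are taken or
rows run out. Capping during selection (rather than truncating
afterwards) guarantees the neighbor set reaches 20 whenever the database
can supply them. The query plus neighbors are then re-restricted,
re-filtered, re-concatenated, and an NJ + bootstrap tree is built; the
report states the species composition of the smallest clade containing
the query after rooting at the most distant neighbor, whether the top-hit
species is monophyletic there, and whether the top hit is tied across
species (the outcome class of sibling species that barcoding cannot
split).

The loci-resampling analysis quantifies discrimination: for each loci
count on a grid and each of 5 replicates it samples that many genes
without replacement, concatenates, and collects all intraspecific and
interspecific distances for designated species pairs. The default grid
c(3, 10, 25, 50, 100, 150) spans the 3–150 range at roughly logarithmic
spacing — the interesting changes happen at few loci, while the upper end
only needs anchoring. More loci do not move the two distributions apart
on average, but they shrink the replicate spread, which is what turns an
overlapping pair of distributions into a separable one.

## Synthetic data: what it does and does not emulate

The generator produces the statistical structure the analyses assume:
one species tree (Yule, exponential waiting times with a final stretch,
so the expected root-to-tip depth is (1/λ)·Σ_{k=2..n} 1/k),
rate-heterogeneous loci evolved site-i.i.d. under JC69 (per-branch
substitution probability 3/4·(1 − e^{−4rt/3})), species complexes with
intraspecific scatter around species means, contaminant extra copies at
configurable coverage, and soft-masked repeat runs. Coverage values are
deterministic means, not sampled, so filter boundary tests are exact.

It deliberately omits: indels (alignments are simulated already aligned,
so the block filter is exercised by constructed gappy fixtures instead),
substitution-model complexity beyond JC69, rate variation across sites,
read-level artifacts, and real repeat families. Passing tests therefore
demonstrate that the algorithms implement their contracts and recover
planted truth under their own model assumptions — not that the
thresholds are optimal for any particular empirical data set.

## Problem sizes and determinism

The test suite and the acceptance script run seeded simulations at desk
scale: 5–12 taxa, 3–30 loci of 60–2000 bp, 10–25 medoid restarts with
k ≤ 6, 5–30 bootstrap replicates, decoy genomes of a few kilobases.
These sizes are chosen so every oracle comparison (exhaustive medoid
subsets, all-offset hit scans, 200-pair RF checks) stays exact and the
whole suite completes in about a minute; the algorithms themselves carry
production-scale defaults (k up to 70, 100 restarts, 100 bootstrap
replicates). All randomness flows through integer seeds via a single
deterministic hash, so every result in this package — including the CLI
pipelines, which write their configuration to a manifest — is exactly
reproducible from (input, seed).

## Known limitations

* NJ + bootstrap is the only internal inference engine; model-based
  support values and coalescent summaries are out of scope, though
  external trees are accepted everywhere a tree is an input.
* The multi-hit screen's seed-and-extend can miss a qualifying locus
  whose every 16-mer is broken by mismatches (possible from ~4 scattered
  mismatches in 80 bp); real duplicated loci at ≥90% identity rarely do
  this, and the brute-force scan is available for audits.
* The Thompson-tau filter's liberality (above) means marker sets curated
  with it should expect a small fraction of false rejections.
* Barcode queries are aligned to a majority-consensus profile, which can
  misplace bases in regions where the database alignment itself is
  ragged; the block filter downstream removes most such columns.
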