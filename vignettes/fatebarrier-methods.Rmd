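---
title: "Methods: chromatin-state binding, accessibility domains and screen statistics in fatebarrier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-state binding, accessibility domains and screen statistics in fatebarrier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fatebarrier` implements the computational side of a multi-omics
characterization of fate-stabilizing ("barrier") transcription factors:
ChIP-seq binding sites classified by chromatin state, pairwise co-occupancy,
motif enrichment against scrambled backgrounds, pseudobulk differential
accessibility from single-cell ATAC fragments, integration of differential
expression with core-promoter binding, and the statistics of arrayed and
combinatorial siRNA screens. This vignette records the models, the
parameters that matter, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## Coordinates and containers

All on-disk formats (BED, narrowPeak, fragments) are 0-based half-open and
are converted on read to `GRanges` (1-based closed); GTF input (1-based
closed) is read through `rtracklayer`. A single internal convention
eliminates off-by-one drift; the only visible consequence is in strand
mirror tests, where the image of a point sits on the other side of a
half-open TSS coordinate, shifting signed TSS distances by one base.

Pseudobulk accessibility lives in `AccessibilityExperiment`, a thin
`RangedSummarizedExperiment` with `counts` and `normalized` assays and
per-group depths in `colData`; PWMs live in `PWMotif`, a position
probability matrix with background frequencies.

## Chromatin state and co-occupancy

Chromatin state is operational: a binding site is *open* iff it overlaps
the merged ATAC open-region set by at least `minOverlapBp` (default 1 bp,
the common bedtools-intersect semantics; no fraction threshold is imposed
by default because none is standard, but `minOverlapFrac` is exposed on the
interval layer). An empty peak set reports `NA` fractions, never 0.

Co-occupancy `M[a,b]` is the fraction of factor *a*'s peaks overlapped by at
least one peak of factor *b* — row-normalized and deliberately asymmetric,
since the row factor's peak count is the denominator. Stratified runs
restrict the row factor's peaks to one state and, by default, compare them
against the partner's *full* peak set; a same-stratum toggle exists. The
default was chosen because the stratified question ("of a's open sites, how
many does b touch?") does not constrain where b's touching peak lies.

Replicate consolidation defaults to `union_merge` (merge of the
concatenation), which matches counting "peaks merged from two samples";
`intersection` (regions covered in every replicate) implements the stricter
reproducibility reading. Both are provided because either reading of
"replicated peaks" is defensible; union span is always ≥ intersection span.

## Peak annotation

Each peak is reduced to a single point — the narrowPeak summit when
present, the midpoint otherwise — and assigned exactly one feature with
priority `core_promoter > exon > intron > TTS_flank > intergenic`. The
point-based rule forces the percentages to partition the peak set, which an
any-overlap rule would not. Core promoters are strand-aware windows from
1 kb upstream to 0.1 kb downstream of the TSS (clipped at the chromosome
start; a window that clips away entirely is an error); the TTS flank is
±1 kb around the transcription end. When a point falls in windows of
several genes, the nearest TSS wins, with ties broken by lexicographically
smaller gene id, purely for determinism. Upstream tools sometimes
distinguish "promoter/TSS" from "TSS" categories; this package emits a
single `core_promoter` class, since no published boundary separates the
two.

`promoterBoundGenes` flags a gene for a factor iff ≥ 1 peak overlaps its
core-promoter window by ≥ 1 bp; half-open semantics mean a peak starting
exactly at the window end does not bind. The flags table is monotone in the
peak sets.

## Motif scanning and enrichment

A window of width $W$ scores $\sum_{i=1}^{W}\log(p_i(b_i)/q(b_i))$; both
strands are scanned (the minus strand via the reverse-complemented matrix)
and windows containing `N` never score. Count matrices become
probabilities with the JASPAR-style pseudocount 0.8 split by background;
probability matrices containing zeros are smoothed the same way, so scores
are always finite.

The default threshold is the smallest score whose per-window (single
strand) false-positive rate under the background model is ≤ `fpr` (default
$10^{-4}$). The score distribution is computed exactly by
dynamic-programming convolution of the per-position scores discretized at
$10^{-3}$ resolution — equivalent to exhaustive enumeration but linear in
$W$ — and the threshold is lowered by the maximal rounding error
($W/2$ bins) so that continuous scanning scores compare safely. For a sharp
consensus PWM this threshold typically admits only exact consensus matches;
the attained FPR is returned as an attribute and is what calibration tests
check against. Note the coarse class structure of sharp PWMs: a 7-mer
cannot attain an FPR below $4^{-7} \approx 6\times10^{-5}$, so requesting
much smaller `fpr` values yields *zero* hits by construction.

"Scrambled" backgrounds preserve length and, by default, the dinucleotide
multiset of each region (Altschul–Erickson Eulerian-path shuffle;
mononucleotide permutation as the comparison mode, and the automatic
fallback for regions under 2 bp). Enrichment is fraction-based to match
the convention of known-motif tools: fold $= f_t/f_b$ with $f_b$ floored at
$1/(2N_b+1)$ (flagged) and an upper-tail binomial
$P(X \ge k_t \mid n_t, f_b)$. Hit densities (hits/kb, overlapping offsets
each counted once, no greedy masking) are reported alongside, and
`differentialMotifEnrichment` contrasts densities of two region sets with a
two-proportion z-test over scanned windows. Both the fraction-based fold
and the density ratio are reported because the fold-enrichment definition
differs between tools; the fraction-based number is labeled "fold".

## Pseudobulk accessibility and domain calling

Fragments aggregate into $C[r,g]$ = fragments of cluster-group $g$
overlapping region $r$ by ≥ 1 bp (once per region), with group depth
$D[g]$ = *all* fragments of the group, in or out of regions. The
normalized signal is $N = C \times 10^6 / (D \times \mathrm{len_{kb}})$,
invariant under duplicating every fragment.

No published threshold defines "open" and "closed" at the pseudobulk level,
so the package uses explicit normalized-signal thresholds: a region is open
in a group iff $N \ge \tau_{open}$ and closed iff $N \le \tau_{closed}$,
with the zone between acting as a buffer. Defaults are
$\tau_{open} = 2\times$ and $\tau_{closed} = 0.5\times$ the genome-wide
median of the nonzero normalized signal — a parameter-recoverable
definition whose premise is that the typical region sits between the two
modes. Domain 1 is open in *every* reference group and closed in *every*
target group (an all-must-agree rule, since pooling versus intersecting
multiple reference samples is otherwise ambiguous); domain 2 is the
converse. A call additionally requires a pooled two-proportion z-test
(counts against depths, no continuity correction, vectorized) to survive
Benjamini–Hochberg at `alpha` (default 0.05). Adjacent same-class calls
within `mergeGap` bp merge. The construction is exactly antisymmetric:
swapping reference and target swaps domain 1 and domain 2.

TSS-level differential accessibility applies the same test per gene on
core-promoter regions tagged with `gene_id` (duplicates pooled), and the
sorted gene list is the deliverable; downstream ontology analysis is out of
scope.

## Integration and candidate selection

DE filtering keeps adjusted p strictly below `alpha` (0.05) — the strict
inequality matters for boundary rows — with an optional `|log2FC|` floor;
zero-fold-change genes are excluded with a notice because they have no
direction. Gene identifiers match exactly after whitespace/case
normalization; no alias resolution is attempted and unmatched genes count
as unbound, with a logged tally. "Top 25th percentile" candidate selection
ranks by log2 fold-change within the bound-and-DE subset (the magnitude of
the expression response, the natural ranking when none is named; adjusted-p
ranking is available), keeps `ceiling(q·n)` genes, and breaks ties by
smaller adjusted p then gene id so the output is invariant to row order.

## Screen statistics

Folds are reported relative to the control mean, but tests run on the raw
replicate percentages — dividing each replicate by a noisy control mean
would distort the test's level. The test is the two-tailed unpaired
Student's (equal-variance) t-test, with Welch behind a flag; degenerate
zero-variance groups return p = 1 when identical and p = 0 when constant
but different. Hits require fold strictly above 1.25 *and* p < 0.05, with
no multiple-testing correction — the per-siRNA criterion used in arrayed
screens — though a BH column is emitted for reference.
`screenNullCalibration` verifies the level of this exact procedure by
simulation. Combination screens enumerate all $2^n - 1$ subsets
(guarded at $n \le 20$), and each condition is compared against the single
hit with the largest mean fold. Blunting calls use a mean ratio ≤ 0.5 to
the reference condition; the viability gate defaults to 0.7× the control's
cell count, an explicit assumption since no cutoff is standard.

## What the synthetic generator emulates

The generator's defaults emulate the experimental system at toy scale: two 1 Mb
chromosomes, 200 non-overlapping genes, four factors with planted open
fractions 3/94/21/78% (SP7, ZNF207, ATF7IP, JUNB) at 250–800 peaks each,
co-occupancy directives ATF7IP→JUNB 0.50, ZNF207→JUNB 0.97, SP7→ATF7IP
0.70, two replicates per factor at 70% reproducibility, 3000 cells in 7
clusters with 13% in the reprogramming target cluster, planted domain spans
of 70 kb and 45 kb (genome-scale spans of ~7 and ~4.5 Mbp scaled 1:100, preserving
the 7:4.5 ratio), AP-1 motif densities of 1.0 vs 0.25 per kb between the
domains (and a MEF2-like motif planted conversely), a DE table of exactly
501 down and 235 up regulated genes with exactly 348 + 112 of them
promoter-bound, 69 planted arrayed-screen effects above 1.25-fold among
1500 conditions, 4 of 255 combinations planted to beat the best single
siRNA, and 61 planted blunting conditions of which 9 keep viability.

Planting is exact wherever recovery is tested as exact: open/closed
placement is constrained (open peaks centred inside open regions, closed
peaks rejected against them), co-occupancy copies the source interval so
the planted fraction is the measured fraction, peak sets are placed
non-overlapping and non-abutting (greedy-sweep rejection sampling) so
merged counts equal planted counts, and DE/bound/screen counts are drawn as
exact subsets, not Bernoulli. Motif planting first *scrubs* spontaneous
exact occurrences of the consensus (iterating until neither strand
matches, since a replacement can recreate the other pattern) and then
writes the planted copies, so the planted per-kb density is the total
density — without scrubbing, the background occurrence rate of a 7-mer
(~0.12/kb at the default threshold) would bias density ratios. Fragment
counts are Poisson with per-bp rates (so normalized signal is
width-independent within a class) at a 10× open/closed rate ratio and a
depth chosen high enough that the closed side separates from the buffer
zone; a dominant intermediate-accessibility class anchors the genome-wide
median between the open and closed modes, which is the premise of the
default thresholds.

What it does not emulate: Tn5 insertion bias, GC bias, fragment-size
periodicity, doublets, peak-shape structure, read-level noise,
correlated replicate structure beyond simple peak dropout, gene-expression
count distributions (the DE table is consumed downstream of model
fitting), or spatial plate effects. Passing recovery tests therefore
demonstrates the *estimators* are correct and calibrated on clean planted
structure, not that the upstream assay artifacts are handled.

One master seed expands into fixed per-generator child seeds by a counter
scheme, so regenerating one input never perturbs the others, and every
generator is bit-reproducible from (config, seed).

## Problem sizes and determinism

The test suite exercises interval oracles on 0.1–1 Mb toy chromosomes
(per-bp mask and quadratic all-pairs references), parameter recovery at
10,000 peaks on 2 × 25 Mb coordinate-only genomes (open fraction and
co-occupancy within ±0.02), motif density recovery on ~100 kb of planted
regions (±15%), domain recovery on the 2 × 1 Mb default (spans within ±5%,
Jaccard ≥ 0.95), 10,000-replicate null calibration of the screen test, and
two full pipeline runs whose `summary.json` files must be byte-identical.
The whole suite runs in a few minutes on one CPU; `scripts/acceptance.R`
reruns the pipeline from scratch in about a minute.

## Known limitations

* Chromatin state is binary by overlap; no signal-level (e.g. quantile)
  definition of accessibility is offered.
* The domain caller tests pooled counts per region; it does not model
  per-cell variability (no mixture/zero-inflation model), which is
  adequate at pseudobulk depth but anticonservative for very few cells.
* The motif layer is known-motif only; de novo discovery, motif clustering
  and footprinting are out of scope.
* Distal peaks are not linked to target genes; annotation stops at the
  feature level.
* The DE table is consumed as given (no count-model refitting), and screen
  statistics assume a shared plate-wide control with no spatial
  correction.
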