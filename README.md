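# fatebarrier

Some transcription factors do not drive a cell's identity forward — they hold
it in place. Knocking such "barrier" factors down makes fibroblasts easier to
reprogram into cardiomyocyte-like, neuron-like or pluripotent cells.
`fatebarrier` is an R package for the multi-omics analysis that characterizes
a set of four such fate-stabilizing factors (ATF7IP, JUNB, SP7, ZNF207):
where they bind with respect to open and closed chromatin, how often they
co-occupy each other's sites, which sequence motifs their regions carry, how
chromatin accessibility shifts in the rare cells that do reprogram, which
differentially expressed genes they bind at the core promoter, and how the
arrayed and combinatorial siRNA screens that found them are scored.

Every stage is backed by a seeded synthetic-data generator with planted
ground truth, so the full pipeline runs and is tested at desk scale without
any external downloads.

## What it computes

* **Intervals** (`readPeaks`, `mergePeaks`, `consolidateReplicates`,
  `intersectPeaks`) — BED/narrowPeak I/O on 0-based half-open coordinates,
  replicate merging, and per-record overlap reports, on `GRanges` throughout.
* **Chromatin-state landscape** (`classifyByState`, `cooccupancy`) — a
  binding site is *open* when it overlaps an ATAC open-region set by ≥ 1 bp;
  co-occupancy `M[a,b]` is the fraction of factor *a*'s sites overlapped by
  factor *b* (row-normalized, not symmetric), optionally per state stratum.
* **Annotation** (`corePromoterWindows`, `annotatePeaks`,
  `promoterBoundGenes`) — strand-aware core-promoter windows (−1 kb to
  +0.1 kb around the TSS), single-feature peak assignment with priority
  `core_promoter > exon > intron > TTS_flank > intergenic`, and per-gene
  binding flags.
* **Motifs** (`PWMotif`, `scanMotif`, `motifScoreThreshold`,
  `scrambleSequences`, `motifEnrichment`, `differentialMotifEnrichment`) —
  log-odds PWM scanning on both strands with an exact per-window
  false-positive threshold (DP convolution of the score distribution),
  dinucleotide-preserving "scrambled" backgrounds (Altschul–Erickson),
  fraction-of-regions fold enrichment with a binomial upper-tail p, and
  hits/kb density contrasts between two region sets.
* **Accessibility domains** (`pseudobulk`, `callDomains`, `domainSummary`,
  `bindingDensityInDomains`, `tssDifferentialAccessibility`) — pseudobulk
  region × cluster-group fragment counts in a `SummarizedExperiment`
  subclass; *domain 1* = open in the reference groups and closed in the
  target cluster at FDR `alpha` (two-proportion z-test, BH), *domain 2* the
  converse; size/span summaries and per-factor binding densities.
* **DE × binding integration** (`filterDe`, `integrateDeBinding`,
  `selectCandidates`) — adjusted-p filtering, Venn counts of DE against
  promoter-bound genes, per-factor contributions, and top-quartile
  candidate selection.
* **Screen statistics** (`normalizeAndTest`, `callHits`,
  `enumerateCombinations`, `compareToBestSingle`, `bluntingCalls`,
  `viabilityGate`, `foldChange`, `ddctFold`) — control-normalized folds,
  equal-variance t-tests on raw replicates, strict `>1.25`-fold & `p<0.05`
  hit calling, all 2^n − 1 subset combinations, agonist blunting and
  viability gating, and qPCR 2^−ΔΔCt arithmetic.
* **Synthetic data** (`simGenome`, `simPeaks`, `simFragments`,
  `simDeScreen`, `plantMotif`, `simMotifRegions`, `simFixtures`) — toy
  genomes, peak sets with exact planted open fractions and pairwise
  co-occupancy, fragment tables with planted accessibility domains, DE and
  screen tables with exact planted counts, and motif instances written into
  the sequence at controlled densities. One master seed expands into fixed
  per-generator child seeds.
* **Pipeline** (`runPipeline`) — YAML/list-config orchestration of all
  stages with fail-fast input checks, per-stage TSV/BED/JSON outputs, one
  `summary.json` of headline numbers and a `manifest.json` with input
  checksums. A thin CLI lives at `inst/scripts/fatebarrier.R`.

## Worked example

```r
library(fatebarrier)

# seeded fixture set: genome, GTF, peaks, open regions, fragments, tables
fx <- simFixtures("fixtures", seed = 7)

# chromatin state of JUNB binding sites
junb <- consolidateReplicates(list(readPeaks("fixtures/JUNB_rep1.narrowPeak"),
                                   readPeaks("fixtures/JUNB_rep2.narrowPeak")))
open <- readPeaks("fixtures/open.bed", "BED6")
classifyByState(junb, open, tf = "JUNB")
#> chromatin-state classification for JUNB: 800 peaks
#>   open:      624 (78.0%)
#>   closed:    176 (22.0%)

# screen: fold to control and hit calling
plate <- readPlate("fixtures/plate.tsv")
hits <- callHits(normalizeAndTest(plate))
sum(hits$hit)
#> [1] 69

foldChange(6, 36)   # reporter-positive percentage 6% -> 36%
#> [1] 6
```

The planted design mirrors the structure of the experimental system: 78% of JUNB and 94% of
ZNF207 sites open versus 79% and 97% of ATF7IP and SP7 sites closed; 50% of
ATF7IP and 97% of ZNF207 sites co-occupied by JUNB; 736 DE genes
(501 down + 235 up) of which 460 (348 + 112) are core-promoter bound; a
13% reprogramming cell cluster; accessibility domains in a 7 : 4.5 span
ratio with a ~4-fold AP-1 motif density contrast; 69 arrayed screen hits;
255 combinations of 8 validated siRNAs with 4 beating the best single; and
61 blunting siRNAs of which 9 keep viability.

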