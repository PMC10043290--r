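Package: fatebarrier
Title: Multi-Omics Characterization of Barrier Transcription Factors in Cell Fate Reprogramming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of chromatin binding, accessibility and
    expression data around "barrier" transcription factors that oppose cell
    fate reprogramming. Provides chromatin-state classification of ChIP-seq
    binding sites, pairwise co-occupancy, PWM motif enrichment against a
    scrambled (dinucleotide-preserving) background, pseudobulk differential
    chromatin accessibility and open/closed domain calling from single-cell
    ATAC fragments, integration of differential expression with core-promoter
    binding, and arrayed/combinatorial siRNA screen statistics. A seeded
    synthetic-data generator with planted ground truth makes every stage
    testable at desk scale, and a config-driven pipeline orchestrates the
    full analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
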