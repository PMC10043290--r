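#' Run the full barrier-TF analysis pipeline
#'
#' Config-driven orchestration of the stages: replicate-peak consolidation,
#' chromatin-state landscape and co-occupancy, feature annotation and
#' promoter binding, pseudobulk domain calling, motif enrichment (open-peak
#' enrichment against a scrambled background, plus differential motif
#' density between the two called domains), DE x promoter-binding
#' integration, and screen statistics. Every stage writes its tables under
#' `out`; the headline numbers are collected into one `summary.json`, with
#' a `manifest.json` recording parameters and input checksums. Deterministic
#' given inputs and the seed.
#'
#' The config (YAML file or list) has the shape:
#' \preformatted{
#' seed: 7
#' out: results/
#' inputs:
#'   gtf: genes.gtf          # annotation, domains
#'   genome: genome.fa       # motifs
#'   open: open.bed          # landscape
#'   peaks:                  # per factor: one or more replicate files
#'     JUNB: [JUNB_rep1.narrowPeak, JUNB_rep2.narrowPeak]
#'   fragments: fragments.tsv
#'   clusters: clusters.tsv
#'   regions: regions.bed    # optional; default = 500 bp tiles
#'   de: de.tsv
#'   bound: bound.tsv        # promoter-binding flags for integration
#'   plate: plate.tsv
#'   combo_plate: combo_plate.tsv      # optional
#'   agonist_plate: agonist_plate.tsv  # optional
#' stages: {landscape: yes, annotation: yes, domains: yes, motifs: yes,
#'          integration: yes, screen: yes}
#' params: {upstream: 1000, downstream: 100, alpha: 0.05, fold_min: 1.25,
#'          ref_clusters: [c1, c3, c4, c5, c6, c7], tgt_clusters: [c2],
#'          motif_consensus: TGACTCA, enrich_fpr: 1.0e-4,
#'          density_fpr: 1.0e-4}
#' }
#'
#' @param config Path to a YAML config or an equivalent named list.
#' @param out Output directory (overrides `config$out`).
#' @return Invisibly, the summary list written to `summary.json`.
#' @export
runPipeline <- function(config, out = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- config
  out <- out %||% cfg$out
  if (is.null(out)) stop("config error: no output directory", call. = FALSE)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  defaults <- list(upstream = 1000, downstream = 100, min_overlap_bp = 1,
                   alpha = 0.05, fold_min = 1.25, quantile = 0.25,
                   control = "siControl",
                   ref_clusters = c("c1", "c3", "c4", "c5", "c6", "c7"),
                   tgt_clusters = "c2",
                   motif_consensus = "TGACTCA",
                   motif_consensus2 = "CTAAAAATAG",
                   enrich_fpr = 1e-4, density_fpr = 1e-4,
                   n_shuffles = 1)
  par <- modifyList(defaults, cfg$params %||% list())
  seed <- cfg$seed %||% 1
  stageOn <- function(s) isTRUE((cfg$stages %||% list())[[s]] %||% TRUE)
  inp <- cfg$inputs %||% list()
  needFile <- function(key, stage) {
    f <- inp[[key]]
    if (is.null(f)) stop("config error: stage '", stage,
                         "' needs input '", key, "'", call. = FALSE)
    missing <- unlist(f)[!file.exists(unlist(f))]
    if (length(missing)) stop("config error: missing input file(s): ",
                              paste(missing, collapse = ", "), call. = FALSE)
    f
  }
  ## fail fast: resolve every enabled stage's inputs before running
  if (!is.null(inp$peaks)) needFile("peaks", "peaks")
  if (stageOn("landscape")) needFile("open", "landscape")
  if (stageOn("annotation")) needFile("gtf", "annotation")
  if (stageOn("domains")) { needFile("fragments", "domains")
    needFile("clusters", "domains") }
  if (stageOn("motifs")) needFile("genome", "motifs")
  if (stageOn("integration")) { needFile("de", "integration")
    needFile("bound", "integration") }
  if (stageOn("screen")) needFile("plate", "screen")

  summary <- list(seed = seed)
  tsv <- function(df, f) write.table(df, file.path(out, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  peaks <- NULL
  if (!is.null(inp$peaks)) {
    peaks <- stage("peaks", {
      lapply(inp$peaks, function(files)
        consolidateReplicates(lapply(unlist(files), readPeaks)))
    })
    summary$peak_counts <- lapply(peaks, length)
  }

  openRegions <- NULL
  states <- NULL
  if (stageOn("landscape") && !is.null(peaks)) {
    stage("landscape", {
      openRegions <- mergePeaks(readPeaks(inp$open, "BED6"))
      states <- lapply(names(peaks), function(tf)
        classifyByState(peaks[[tf]], openRegions,
                        minOverlapBp = par$min_overlap_bp, tf = tf))
      names(states) <- names(peaks)
      st <- do.call(rbind, lapply(states, function(s)
        data.frame(tf = s$tf, n_open = s$n_open, n_closed = s$n_closed,
                   frac_open = s$frac_open)))
      tsv(st, "state_classification.tsv")
      co <- cooccupancy(peaks, minOverlapBp = par$min_overlap_bp)
      coOpen <- cooccupancy(peaks, minOverlapBp = par$min_overlap_bp,
                            stratum = states, stratumState = "open")
      tsv(cbind(stratum = "all", tf = rownames(co$matrix),
                as.data.frame(co$matrix)), "cooccupancy.tsv")
      summary$frac_open <- setNames(lapply(states, function(s) s$frac_open),
                                     names(states))
      summary$cooccupancy <- apply(co$matrix, 1, as.list, simplify = FALSE)
      summary$cooccupancy_open <- apply(coOpen$matrix, 1, as.list,
                                         simplify = FALSE)
    })
  }

  models <- NULL
  bound <- NULL
  if (stageOn("annotation") && !is.null(peaks)) {
    stage("annotation", {
      models <- readGeneModels(inp$gtf)
      ann <- lapply(names(peaks), function(tf)
        cbind(tf = tf, annotatePeaks(peaks[[tf]], models$genes, models$exons,
                                     upstream = par$upstream,
                                     downstream = par$downstream)$summary))
      tsv(do.call(rbind, ann), "feature_distribution.tsv")
      boundGenes <- promoterBoundGenes(peaks, models$genes,
                                       upstream = par$upstream,
                                       downstream = par$downstream)
      tsv(boundGenes, "promoter_bound_genes.tsv")
      summary$feature_distribution <- lapply(ann, function(a)
        setNames(as.list(a$percent), a$feature))
      names(summary$feature_distribution) <- names(peaks)
      summary$n_promoter_bound_any <- sum(boundGenes$bound_any)
    })
  }

  calls <- NULL
  if (stageOn("domains")) {
    stage("domains", {
      frags <- readFragments(inp$fragments)
      clusters <- readClusterMap(inp$clusters)
      regions <- if (!is.null(inp$regions))
        mergePeaks(readPeaks(inp$regions, "BED6"))
      else tileGenomeRegions(frags, 500)
      groups <- list(ref = as.character(par$ref_clusters),
                     tgt = as.character(par$tgt_clusters))
      mat <- pseudobulk(frags, clusters, regions, groups)
      calls <- callDomains(mat, "ref", "tgt", alpha = par$alpha)
      writeDomainBed(calls, file.path(out, "domain_calls.bed"))
      ds <- domainSummary(calls)
      tsv(ds$summary, "domain_summary.tsv")
      if (!is.null(peaks))
        tsv(bindingDensityInDomains(calls, peaks), "domain_binding.tsv")
      summary$domain1_span_bp <- ds$summary$span_bp[1]
      summary$domain2_span_bp <- ds$summary$span_bp[2]
      summary$domain1_n <- ds$summary$n[1]
      summary$domain2_n <- ds$summary$n[2]
    })
  }

  if (stageOn("motifs")) {
    stage("motifs", {
      genome <- readDNAStringSet(inp$genome)
      names(genome) <- sub("\\s.*", "", names(genome))
      pwm <- pwmFromConsensus(par$motif_consensus, par$motif_consensus)
      if (!is.null(peaks) && !is.null(openRegions)) {
        tf1 <- names(peaks)[[length(peaks)]]
        tgt <- peaks[[tf1]][overlapsAny(peaks[[tf1]], openRegions,
                                        ignore.strand = TRUE)]
        seqs <- regionSequences(genome, tgt)
        bg <- scrambleSequences(seqs, "dinucleotide",
                                nShuffles = par$n_shuffles, seed = seed)
        thr <- as.numeric(motifScoreThreshold(pwm, par$enrich_fpr))
        enr <- motifEnrichment(scanMotif(seqs, pwm, threshold = thr),
                               scanMotif(bg, pwm, threshold = thr))
        tsv(enr, "motif_enrichment.tsv")
        summary$motif_enrichment_fold <- enr$fold
        summary$motif_enrichment_p <- enr$p_value
        summary$motif_enrichment_tf <- tf1
      }
      if (!is.null(calls) && length(calls$domain1) && length(calls$domain2)) {
        pwms <- list(pwm, pwmFromConsensus(par$motif_consensus2,
                                           par$motif_consensus2))
        dme <- differentialMotifEnrichment(
          regionSequences(genome, calls$domain1),
          regionSequences(genome, calls$domain2),
          pwms, fpr = par$density_fpr)
        tsv(dme, "motif_differential.tsv")
        i <- match(par$motif_consensus, dme$motif)
        summary$domain_motif_density1 <- dme$density1[i]
        summary$domain_motif_density2 <- dme$density2[i]
        summary$domain_motif_ratio <- dme$ratio[i]
      }
    })
  }

  if (stageOn("integration")) {
    stage("integration", {
      de <- filterDe(readDeTable(inp$de), alpha = par$alpha)
      boundTab <- read.table(inp$bound, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
      res <- integrateDeBinding(de, boundTab)
      venn <- res[c("n_de", "n_de_down", "n_de_up", "n_bound_de",
                    "n_bound_down", "n_bound_up", "frac_bound",
                    "frac_down_among_bound")]
      write_json(c(venn, list(per_tf = as.list(res$per_tf))),
                 file.path(out, "integration_venn.json"),
                 auto_unbox = TRUE, digits = NA, pretty = TRUE)
      cand <- selectCandidates(res$bound_de, "down", quantile = par$quantile)
      tsv(cand[c("gene_id", "log2fc", "padj", "direction")],
          "candidates_down.tsv")
      summary$integration <- venn
      summary$integration_per_tf <- as.list(res$per_tf)
      summary$n_candidates_down <- nrow(cand)
    })
  }

  if (stageOn("screen")) {
    stage("screen", {
      plate <- readPlate(inp$plate)
      hits <- callHits(normalizeAndTest(plate, control = par$control),
                       foldMin = par$fold_min, alpha = par$alpha)
      tsv(hits, "screen_hits.tsv")
      summary$screen_n_hits <- sum(hits$hit)
      if (!is.null(inp$combo_plate)) {
        cp <- readPlate(inp$combo_plate)
        ch <- normalizeAndTest(cp, control = par$control)
        singles <- ch$condition[!grepl("\\+", ch$condition) &
                                  ch$condition != par$control]
        cmp <- compareToBestSingle(cp, ch, singles, alpha = par$alpha)
        tsv(cmp, "combo_vs_best_single.tsv")
        summary$best_single <- cmp$best_single[1]
        summary$n_combos_exceeding_best <-
          sum(cmp$exceeds & grepl("\\+", cmp$condition))
      }
      if (!is.null(inp$agonist_plate)) {
        ap <- readPlate(inp$agonist_plate)
        ah <- normalizeAndTest(ap, control = par$control)
        ab <- bluntingCalls(ah, reference = "siAJSZ")
        ab <- viabilityGate(ab)
        tsv(ab, "agonist_calls.tsv")
        summary$n_blunted <- sum(ab$blunted &
                                    !ab$condition %in% c(par$control))
        summary$n_blunted_viable <- sum(ab$blunted & ab$viable &
                                           !ab$condition %in% c(par$control))
      }
    })
  }

  write_json(summary, file.path(out, "summary.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(package = "fatebarrier",
                   version = as.character(utils::packageVersion("fatebarrier")),
                   parameters = par, seed = seed,
                   inputs = lapply(inp, function(f)
                     as.list(tools::md5sum(unlist(f)))))
  write_json(manifest, file.path(out, "manifest.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

## fallback regions when no ATAC region BED is supplied: fixed tiles over
## the fragment-covered chromosomes
tileGenomeRegions <- function(frags, tile = 500) {
  lens <- tapply(end(frags), as.character(seqnames(frags)), max)
  out <- lapply(names(lens), function(ch) {
    s <- seq(1L, lens[[ch]], by = tile)
    GRanges(ch, IRanges(s, width = tile))
  })
  sortPeaks(do.call(c, out))
}

## domain calls as BED: class in the name field, q-value in score
writeDomainBed <- function(calls, path) {
  grs <- c(domain1 = calls$domain1, domain2 = calls$domain2)
  df <- calls$calls
  called <- df[!is.na(df$class), , drop = FALSE]
  out <- data.frame(chrom = called$chrom, start = called$start,
                    end = called$end, name = called$class,
                    score = signif(called$q_value, 4),
                    strand = ".")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#fatebarrier domain calls", con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
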