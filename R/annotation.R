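#' Read gene models from GTF
#'
#' Takes `gene` feature rows when present, otherwise derives gene extents
#' from `transcript` (or, failing that, `exon`) rows grouped by `gene_id`.
#' rtracklayer handles the 1-based closed GTF convention; the result is a
#' `GRanges` in the package's usual internal representation. Duplicated
#' `gene_id`s keep the first occurrence with a warning.
#'
#' @param path Path to a GTF file.
#' @return A list with `genes` (`GRanges`, mcols `gene_id`, `gene_name`) and
#'   `exons` (`GRanges` with `gene_id`; empty if the GTF has no exon rows).
#' @export
readGeneModels <- function(path) {
  gtf <- rtracklayer::import(path, format = "gtf")
  type <- as.character(gtf$type)
  exons <- gtf[type == "exon"]
  if (any(type == "gene")) {
    genes <- gtf[type == "gene"]
  } else {
    src <- gtf[type == if (any(type == "transcript")) "transcript" else "exon"]
    if (!length(src)) stop("GTF contains no gene, transcript or exon rows")
    spl <- split(src, src$gene_id)
    genes <- unlist(range(spl))
    genes$gene_id <- names(genes)
    genes$gene_name <- vapply(spl, function(g)
      if (!is.null(g$gene_name)) g$gene_name[1] else g$gene_id[1], character(1))
    names(genes) <- NULL
  }
  if (is.null(genes$gene_name)) genes$gene_name <- genes$gene_id
  dup <- duplicated(genes$gene_id)
  if (any(dup)) {
    warning(sum(dup), " duplicated gene_id(s); keeping first occurrence")
    genes <- genes[!dup]
  }
  mcols(genes) <- mcols(genes)[, c("gene_id", "gene_name")]
  mcols(exons) <- mcols(exons)[, "gene_id", drop = FALSE]
  list(genes = sortPeaks(genes), exons = sortPeaks(exons))
}

## 0-based TSS / TES coordinates of a stranded gene GRanges
tss0 <- function(genes)
  ifelse(as.character(strand(genes)) == "-", end(genes), start(genes) - 1L)
tes0 <- function(genes)
  ifelse(as.character(strand(genes)) == "-", start(genes) - 1L, end(genes))

#' Strand-aware core-promoter windows
#'
#' The core promoter of a gene is the window from `upstream` bp upstream to
#' `downstream` bp downstream of its TSS, in the gene's orientation (default
#' \eqn{-1\,kb} to \eqn{+0.1\,kb}). Windows running off the chromosome start
#' are clipped at 0; a window that clips to zero length is an error.
#'
#' @param genes Stranded `GRanges` of genes (as from [readGeneModels()]).
#' @param upstream,downstream Window extents in bp (>= 0, not both 0).
#' @return `GRanges` of promoter windows carrying the gene metadata columns.
#' @export
#' @examples
#' g <- GenomicRanges::GRanges("chr1:5001-8000:+")
#' corePromoterWindows(g)   # chr1 4000-5100 in BED coordinates
corePromoterWindows <- function(genes, upstream = 1000, downstream = 100) {
  if (upstream < 0 || downstream < 0 || (upstream == 0 && downstream == 0))
    stop("upstream/downstream must be >= 0 and not both 0")
  if (any(!as.character(strand(genes)) %in% c("+", "-")))
    stop("genes must be stranded (+/-)")
  w <- GenomicRanges::promoters(genes, upstream = upstream,
                                downstream = downstream)
  clipped <- start(w) < 1L
  start(w)[clipped] <- 1L
  if (any(width(w) <= 0) || any(end(w) < 1L))
    stop("promoter window entirely off the chromosome start")
  w
}

#' Annotate peaks to genomic features
#'
#' Each peak is represented by a single point — its summit when the
#' narrowPeak `peak` column is set, its midpoint otherwise — and assigned
#' exactly one feature with priority
#' `core_promoter > exon > intron > TTS_flank > intergenic`. Within a
#' feature class, a point falling in windows of several genes is assigned to
#' the gene with the nearest TSS (ties broken by lexicographically smaller
#' `gene_id`). `distance_to_tss` is signed in the gene's orientation
#' (negative upstream of the TSS).
#'
#' @param peaks `GRanges` of peaks.
#' @param genes Stranded gene `GRanges` with `gene_id`.
#' @param exons Optional exon `GRanges` with `gene_id`; when absent the whole
#'   gene body counts as `intron`.
#' @param upstream,downstream Core-promoter window (bp).
#' @param ttsFlank Half-width of the TTS flank window (bp).
#' @return A list with `assignments` (data.frame: `peak`, `feature`,
#'   `gene_id`, `distance_to_tss`) and `summary` (data.frame: `feature`,
#'   `n`, `percent`; a partition of the peaks).
#' @export
annotatePeaks <- function(peaks, genes, exons = NULL,
                          upstream = 1000, downstream = 100, ttsFlank = 1000) {
  mid0 <- peakPoint0(peaks)
  mp <- GRanges(seqnames(peaks), IRanges(mid0 + 1L, width = 1L))
  n <- length(peaks)
  feature <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  gtss <- tss0(genes)
  gtes <- tes0(genes)

  assignClass <- function(windows, win_gene_idx, label, open_slots) {
    hits <- findOverlaps(mp, windows, ignore.strand = TRUE)
    hits <- hits[open_slots[queryHits(hits)]]
    if (!length(hits)) return(invisible())
    gi <- win_gene_idx[subjectHits(hits)]
    d <- abs(mid0[queryHits(hits)] - gtss[gi])
    ord <- order(queryHits(hits), d, genes$gene_id[gi])
    first <- !duplicated(queryHits(hits)[ord])
    qi <- queryHits(hits)[ord][first]
    feature[qi] <<- label
    gene[qi] <<- genes$gene_id[gi[ord][first]]
  }

  open_ <- function() feature == "intergenic"
  prom <- corePromoterWindows(genes, upstream, downstream)
  assignClass(prom, seq_along(genes), "core_promoter", open_())
  if (!is.null(exons) && length(exons)) {
    eg <- match(exons$gene_id, genes$gene_id)
    keep <- !is.na(eg)
    assignClass(exons[keep], eg[keep], "exon", open_())
  }
  assignClass(granges(genes), seq_along(genes), "intron", open_())
  tts <- GRanges(seqnames(genes),
                 IRanges(pmax(1L, gtes - as.integer(ttsFlank) + 1L),
                         gtes + as.integer(ttsFlank)))
  assignClass(tts, seq_along(genes), "TTS_flank", open_())

  gi <- match(gene, genes$gene_id)
  dist <- ifelse(is.na(gi), NA_integer_,
                 ifelse(as.character(strand(genes))[gi] == "-",
                        gtss[gi] - mid0, mid0 - gtss[gi]))
  levs <- c("core_promoter", "exon", "intron", "TTS_flank", "intergenic")
  assignments <- data.frame(peak = seq_len(n),
                            feature = factor(feature, levels = levs),
                            gene_id = gene,
                            distance_to_tss = as.integer(dist))
  tab <- table(assignments$feature)
  summary <- data.frame(feature = names(tab), n = as.integer(tab),
                        percent = if (n) 100 * as.integer(tab) / n else
                          rep(NA_real_, length(tab)))
  list(assignments = assignments, summary = summary)
}

## representative 0-based point of each peak: summit if set, else midpoint
peakPoint0 <- function(peaks) {
  start0 <- start(peaks) - 1L
  mid0 <- as.integer(floor((start0 + end(peaks)) / 2))
  summit <- if ("peak" %in% names(mcols(peaks))) mcols(peaks)$peak else
    rep(-1L, length(peaks))
  summit[is.na(summit)] <- -1L
  ifelse(summit >= 0L, start0 + summit, mid0)
}

#' Flag genes whose core promoter is bound by each factor
#'
#' A gene is flagged for a factor when at least one of that factor's peaks
#' overlaps the gene's core-promoter window by >= 1 bp (half-open: a peak
#' starting exactly at the window end does not bind).
#'
#' @param peakSets Named list of `GRanges`, one per factor.
#' @param genes Stranded gene `GRanges` with `gene_id`.
#' @param upstream,downstream Core-promoter window (bp).
#' @return data.frame: `gene_id`, one logical column per factor, and
#'   `bound_any`.
#' @export
promoterBoundGenes <- function(peakSets, genes, upstream = 1000,
                               downstream = 100) {
  stopifnot(is.list(peakSets), !is.null(names(peakSets)))
  dup <- duplicated(genes$gene_id)
  if (any(dup)) {
    warning(sum(dup), " duplicated gene_id(s); keeping first occurrence")
    genes <- genes[!dup]
  }
  prom <- corePromoterWindows(genes, upstream, downstream)
  out <- data.frame(gene_id = genes$gene_id)
  for (tf in names(peakSets))
    out[[tf]] <- countOverlaps(prom, peakSets[[tf]],
                               ignore.strand = TRUE) > 0
  out$bound_any <- Reduce(`|`, out[names(peakSets)])
  out
}
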