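## Synthetic-data generators with planted ground truth. Every generator is
## deterministic given (config, seed); the master seed expands into
## per-generator child seeds by a fixed counter scheme (childSeeds) so
## regenerating one input never perturbs another. Each generator returns its
## planted truth alongside the data.

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

#' Simulate a toy genome with gene models
#'
#' I.i.d. sequence at the stated GC content; genes are placed uniformly and
#' non-overlapping (by rejection), strands Bernoulli(0.5), each gene with
#' two exons. A 2 kb margin keeps promoters on-chromosome.
#'
#' @param nChrom Number of chromosomes.
#' @param chromLength Length of each chromosome (bp, >= 10 kb).
#' @param gc GC content in (0, 1).
#' @param nGenes Number of genes.
#' @param geneWidth Range of gene widths (bp).
#' @param seed Integer seed.
#' @return List: `genome` (`DNAStringSet`), `genes` (`GRanges` with
#'   `gene_id`, `gene_name`), `exons` (`GRanges` with `gene_id`),
#'   `chromLengths` (named vector).
#' @export
simGenome <- function(nChrom = 2, chromLength = 1e6, gc = 0.5, nGenes = 200,
                      geneWidth = c(1500, 4000), seed = 1) {
  if (chromLength < 1e4) stop("chromosomes must be >= 10 kb")
  withSeed(seed, {
    chroms <- paste0("chr", seq_len(nChrom))
    lens <- setNames(rep(as.integer(chromLength), nChrom), chroms)
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    genome <- DNAStringSet(vapply(chroms, function(ch)
      paste(sample(names(probs), chromLength, TRUE, probs), collapse = ""),
      character(1)))
    names(genome) <- chroms
    margin <- 2000L
    widths <- as.integer(runif(nGenes, geneWidth[1], geneWidth[2]))
    placed <- GRanges()
    tries <- 0L
    for (i in seq_len(nGenes)) {
      repeat {
        tries <- tries + 1L
        if (tries > 50L * nGenes) stop("could not place all genes")
        ch <- sample(chroms, 1, prob = lens)
        s0 <- as.integer(runif(1, margin, lens[[ch]] - margin - widths[i]))
        cand <- grFromBed(ch, s0, s0 + widths[i],
                          strand = sample(c("+", "-"), 1))
        if (!length(placed) ||
            !any(suppressWarnings(overlapsAny(cand, placed,
                                              ignore.strand = TRUE)))) {
          placed <- suppressWarnings(c(placed, cand))
          break
        }
      }
    }
    placed <- sortPeaks(placed)
    placed$gene_id <- sprintf("g%03d", seq_len(nGenes))
    placed$gene_name <- placed$gene_id
    ## two exons per gene: first and last 30% of the body
    w <- width(placed)
    e1 <- GRanges(seqnames(placed),
                  IRanges(start(placed), width = pmax(50L,
                                                      as.integer(0.3 * w))),
                  strand = strand(placed), gene_id = placed$gene_id)
    e2 <- GRanges(seqnames(placed),
                  IRanges(end(placed) - pmax(50L, as.integer(0.3 * w)) + 1L,
                          end(placed)),
                  strand = strand(placed), gene_id = placed$gene_id)
    list(genome = genome, genes = placed, exons = sortPeaks(c(e1, e2)),
         chromLengths = lens)
  })
}

## rejection sampler for peak intervals
## within: GRanges the interval must overlap (sampled inside); NULL = anywhere
## avoid: GRanges the interval must not overlap
samplePeaks <- function(chromLengths, n, widths, within = NULL, avoid = NULL,
                        notWithin = NULL, selfAvoid = FALSE,
                        maxRounds = 2000) {
  out <- GRanges()
  need <- n
  round <- 0L
  while (need > 0) {
    round <- round + 1L
    if (round > maxRounds) stop("cannot place requested peaks (genome full?)")
    m <- max(need * 2L, 10L)
    w <- sample(widths, m, replace = TRUE)
    if (!is.null(within) && length(within)) {
      ri <- sample(seq_along(within), m, TRUE, prob = width(within))
      ctr <- start(within)[ri] +
        as.integer(runif(m, 0, pmax(1, width(within)[ri])))
      ch <- as.character(seqnames(within))[ri]
    } else {
      ch <- sample(names(chromLengths), m, TRUE, prob = chromLengths)
      ctr <- as.integer(runif(m, 1, chromLengths[ch]))
    }
    s <- pmax(1L, ctr - w %/% 2L)
    e <- pmin(as.integer(chromLengths[ch]), s + w - 1L)
    cand <- GRanges(ch, IRanges(s, e))
    ok <- rep(TRUE, m)
    if (!is.null(avoid) && length(avoid))
      ok <- ok & !overlapsAny(cand, avoid, maxgap = 0L,
                              ignore.strand = TRUE)
    if (!is.null(notWithin) && length(notWithin))
      ok <- ok & !overlapsAny(cand, notWithin, ignore.strand = TRUE)
    cand <- cand[ok]
    if (selfAvoid && length(cand)) {
      ## forbid abutment too (maxgap = 0), so merged sets keep their count
      if (length(out)) cand <- cand[!overlapsAny(cand, out, maxgap = 0L,
                                                 ignore.strand = TRUE)]
      if (length(cand) > 1) {
        ## greedy sweep: keep candidates that clear the previous kept one
        cand <- sortPeaks(cand)
        chr <- as.character(seqnames(cand))
        keep <- logical(length(cand))
        lastEnd <- -1L
        lastChr <- ""
        for (ii in seq_along(cand)) {
          if (chr[ii] != lastChr || start(cand)[ii] > lastEnd + 1L) {
            keep[ii] <- TRUE
            lastEnd <- end(cand)[ii]
            lastChr <- chr[ii]
          }
        }
        cand <- cand[keep]
      }
    }
    if (length(cand) > need) cand <- cand[seq_len(need)]
    out <- suppressWarnings(c(out, cand))
    need <- n - length(out)
  }
  sortPeaks(out)
}

#' Simulate TF peak sets with planted chromatin state and co-occupancy
#'
#' Generates an open-chromatin region set, then per-factor peak sets with an
#' exact planted open fraction (open peaks are centred inside open regions,
#' closed peaks never touch them). Pairwise co-occupancy is planted by
#' centre-sharing: a directive `(a, b, rho)` copies exactly
#' `round(rho * n_a)` of factor `a`'s peak centres into factor `b`'s set
#' (factor `a` must be generated before `b`). All independently placed peaks
#' avoid every previously placed factor's peaks, so undirected co-occupancy
#' stays near zero and directed co-occupancy stays near `rho`. Two
#' replicates per factor are derived from the consolidated truth set: each
#' true peak lands in both replicates with probability `reproducibility`,
#' else in one of the two at random.
#'
#' @param chromLengths Named vector of chromosome lengths.
#' @param tfs data.frame with columns `tf`, `n`, `open_fraction`, in
#'   generation order.
#' @param cooc Optional data.frame with columns `a`, `b`, `rho`.
#' @param openCoverage Fraction of the genome covered by open regions.
#' @param openRegionWidth Width of each open region (bp).
#' @param peakWidthMeanLog,peakWidthSdLog Log-normal peak width parameters.
#' @param reproducibility Probability a true peak appears in both replicates.
#' @param seed Integer seed.
#' @return List: `open` (`GRanges`), `peaks` (named list of `GRanges`),
#'   `replicates` (named list of 2-element lists), `truth` (planted and
#'   realized per-factor open counts, per-directive shared counts).
#' @export
simPeaks <- function(chromLengths, tfs, cooc = NULL,
                     openCoverage = 0.25, openRegionWidth = 1000,
                     peakWidthMeanLog = log(250), peakWidthSdLog = 0.25,
                     reproducibility = 0.7, seed = 1) {
  stopifnot(all(c("tf", "n", "open_fraction") %in% names(tfs)))
  withSeed(seed, {
    gsize <- sum(chromLengths)
    nOpen <- max(1L, as.integer(openCoverage * gsize / openRegionWidth))
    open <- samplePeaks(chromLengths, nOpen,
                        widths = as.integer(openRegionWidth),
                        avoid = NULL)
    open <- mergePeaks(open)
    peaks <- list()
    truth <- list(open_regions = length(open),
                  open_span = sum(width(open)), tf = list(), cooc = list())
    widthPool <- function(k) pmax(50L, as.integer(rlnorm(k, peakWidthMeanLog,
                                                         peakWidthSdLog)))
    placedAll <- GRanges()
    for (i in seq_len(nrow(tfs))) {
      tf <- tfs$tf[i]
      n <- tfs$n[i]
      fOpen <- tfs$open_fraction[i]
      shared <- GRanges()
      if (!is.null(cooc)) {
        for (j in which(cooc$b == tf)) {
          a <- cooc$a[j]
          if (!a %in% names(peaks))
            stop("co-occupancy source '", a, "' must be generated before '",
                 tf, "'")
          nShare <- round(cooc$rho[j] * length(peaks[[a]]))
          src <- peaks[[a]][sample(seq_along(peaks[[a]]), nShare)]
          ## shared peaks copy the source interval exactly: with per-factor
          ## self-avoidance this makes the planted co-occupancy fraction
          ## exact (no incidental overlap with the source factor's other
          ## peaks)
          shared <- suppressWarnings(c(shared, granges(src)))
          truth$cooc[[paste(a, tf, sep = "->")]] <-
            list(a = a, b = tf, rho = cooc$rho[j], n_shared = nShare)
        }
      }
      nShared <- length(shared)
      if (nShared > n) stop("co-occupancy directives exceed n for ", tf)
      sharedOpen <- sum(overlapsAny(shared, open, ignore.strand = TRUE))
      nOpenTarget <- round(fOpen * n)
      nOpenFree <- max(0L, nOpenTarget - sharedOpen)
      nClosedFree <- (n - nShared) - nOpenFree
      if (nClosedFree < 0) {
        nOpenFree <- n - nShared
        nClosedFree <- 0L
      }
      po <- samplePeaks(chromLengths, nOpenFree, widthPool(2 * nOpenFree + 10),
                        within = open,
                        avoid = suppressWarnings(c(placedAll, shared)),
                        selfAvoid = TRUE)
      pc <- samplePeaks(chromLengths, nClosedFree,
                        widthPool(2 * nClosedFree + 10),
                        avoid = suppressWarnings(c(placedAll, shared, po)),
                        notWithin = open, selfAvoid = TRUE)
      all <- sortPeaks(suppressWarnings(c(shared, po, pc)))
      all$name <- sprintf("%s_peak%05d", tf, seq_along(all))
      all$score <- 100
      all$signalValue <- round(runif(length(all), 2, 20), 2)
      all$pValue <- round(runif(length(all), 5, 100), 2)
      all$qValue <- round(all$pValue * 0.8, 2)
      all$peak <- width(all) %/% 2L
      peaks[[tf]] <- all
      placedAll <- suppressWarnings(c(placedAll, granges(all)))
      realizedOpen <- sum(overlapsAny(all, open, ignore.strand = TRUE))
      truth$tf[[tf]] <- list(n = n, open_fraction_planted = fOpen,
                             n_open_realized = realizedOpen,
                             open_fraction_realized = realizedOpen / n)
    }
    replicates <- lapply(peaks, function(p) {
      both <- runif(length(p)) < reproducibility
      one <- sample(c(TRUE, FALSE), length(p), TRUE)
      r1 <- p[both | (!both & one)]
      r2 <- p[both | (!both & !one)]
      list(r1, r2)
    })
    truth$reproducibility <- reproducibility
    list(open = open, peaks = peaks, replicates = replicates, truth = truth)
  })
}

#' Embed motif instances into a genome at planted densities
#'
#' Scrubs spontaneous exact occurrences of the consensus (both strands)
#' inside the given regions by resampling their centre base, then writes
#' planted copies at `density` per kb (uniform non-overlapping placements,
#' random strand). The planted density is therefore the *total* density of
#' exact consensus matches in those regions.
#'
#' @param genome Named `DNAStringSet`.
#' @param regions `GRanges` to plant into.
#' @param consensus Consensus string (e.g. `"TGACTCA"`).
#' @param density Planted instances per kb of region span.
#' @param seed Integer seed.
#' @return List: modified `genome`, `n_planted`, `placements` (`GRanges`).
#' @export
plantMotif <- function(genome, regions, consensus, density, seed = 1) {
  withSeed(seed, {
    consensus <- toupper(consensus)
    W <- nchar(consensus)
    rc <- as.character(reverseComplement(DNAString(consensus)))
    seqs <- strsplit(toupper(vapply(names(genome), function(ch)
      as.character(genome[[ch]]), character(1))), "")
    names(seqs) <- names(genome)
    scrub <- function(ch, s, e) {
      pats <- unique(c(consensus, rc))
      repeat {
        ## a replacement can recreate either pattern, so iterate over both
        ## until neither occurs
        str <- paste(seqs[[ch]][s:e], collapse = "")
        hits <- vapply(pats, function(p) regexpr(p, str, fixed = TRUE),
                       integer(1))
        if (all(hits < 0)) break
        hit <- min(hits[hits > 0])
        pos <- s + hit - 1L + W %/% 2L
        old <- seqs[[ch]][pos]
        seqs[[ch]][pos] <<- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      }
    }
    for (i in seq_along(regions))
      scrub(as.character(seqnames(regions))[i], start(regions)[i],
            end(regions)[i])
    span <- sum(width(regions))
    nPlant <- max(0L, round(density * span / 1000))
    placements <- GRanges()
    if (nPlant > 0) {
      ok <- regions[width(regions) >= W]
      ## choose region (prob ~ width) and offset; avoid overlapping plants
      placed <- GRanges()
      tries <- 0L
      while (length(placed) < nPlant) {
        tries <- tries + 1L
        if (tries > 200L * nPlant) stop("cannot place motif instances")
        ri <- sample(seq_along(ok), 1, prob = width(ok))
        off <- as.integer(runif(1, 0, width(ok)[ri] - W + 1))
        s <- start(ok)[ri] + off
        cand <- GRanges(seqnames(ok)[ri], IRanges(s, s + W - 1L))
        if (length(placed) && any(overlapsAny(cand, placed))) next
        placed <- suppressWarnings(c(placed, cand))
      }
      placed <- sortPeaks(placed)
      str <- sample(c(consensus, rc), length(placed), TRUE)
      for (i in seq_along(placed)) {
        ch <- as.character(seqnames(placed))[i]
        seqs[[ch]][start(placed)[i]:end(placed)[i]] <-
          strsplit(str[i], "")[[1]]
      }
      placements <- placed
    }
    genome2 <- DNAStringSet(vapply(seqs, paste, character(1), collapse = ""))
    names(genome2) <- names(genome)
    list(genome = genome2, n_planted = length(placements),
         placements = placements)
  })
}

#' Simulate region sequences with a planted motif fraction
#'
#' Builds `n` i.i.d. random sequences of length `len` with the consensus
#' scrubbed, then plants one exact instance (random strand, random offset)
#' into a `fracWithMotif` share of them — the target/background pair for
#' enrichment recovery.
#'
#' @param n Number of regions.
#' @param len Region length (bp).
#' @param consensus Motif consensus string.
#' @param fracWithMotif Fraction of regions receiving one instance.
#' @param gc GC content.
#' @param seed Integer seed.
#' @return Named character vector of sequences; attribute `with_motif` is
#'   the logical planting mask.
#' @export
simMotifRegions <- function(n, len = 300, consensus = "TGACTCA",
                            fracWithMotif = 0.5, gc = 0.5, seed = 1) {
  withSeed(seed, {
    consensus <- toupper(consensus)
    W <- nchar(consensus)
    rc <- as.character(reverseComplement(DNAString(consensus)))
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    mk <- function() {
      s <- paste(sample(names(probs), len, TRUE, probs), collapse = "")
      while (grepl(consensus, s, fixed = TRUE) || grepl(rc, s, fixed = TRUE)) {
        for (pat in unique(c(consensus, rc))) {
          h <- regexpr(pat, s, fixed = TRUE)
          if (h > 0)
            substr(s, h + W %/% 2L, h + W %/% 2L) <-
              sample(setdiff(c("A", "C", "G", "T"),
                             substr(s, h + W %/% 2L, h + W %/% 2L)), 1)
        }
      }
      s
    }
    seqs <- vapply(seq_len(n), function(i) mk(), character(1))
    with_motif <- seq_len(n) %in% sample(n, round(fracWithMotif * n))
    for (i in which(with_motif)) {
      off <- sample(len - W + 1, 1)
      substr(seqs[i], off, off + W - 1L) <- sample(c(consensus, rc), 1)
    }
    names(seqs) <- sprintf("region%04d", seq_len(n))
    attr(seqs, "with_motif") <- with_motif
    seqs
  })
}

#' Simulate single-cell ATAC fragments with planted accessibility domains
#'
#' Lays out non-overlapping regions, assigns each a class — constitutively
#' open, intermediate (`medium`), low-signal, `domain1` (open in reference
#' clusters, closed in the target cluster) or `domain2` (the converse) —
#' and draws per-region, per-cluster fragment counts as Poisson with rate
#' ratio `rateRatio` between the open and closed side. The intermediate
#' class is the most common, so the genome-wide median accessibility falls
#' between the open and closed modes (which is what the default domain
#' thresholds key on). Domain regions are selected until each planted span
#' target is reached; region widths follow `widthBreaks`/`widthProbs`
#' (default 90% below 600 bp).
#'
#' @param chromLengths Named chromosome lengths.
#' @param cells Named vector: cells per cluster. The default plants 13% of
#'   3000 cells in the target cluster `c2`.
#' @param tgtClusters Cluster ids forming the reprogramming target group.
#' @param nRegions Total regions.
#' @param domain1SpanBp,domain2SpanBp Planted span targets (bp).
#' @param rateRatio Open/closed Poisson rate ratio (> 1).
#' @param fragsPerCellOpen Expected fragments per cell per kb of open region.
#' @param fragWidth Fragment width range (bp).
#' @param widthBreaks,widthProbs Region width distribution.
#' @param seed Integer seed.
#' @return List: `frags` (`GRanges` + `barcode`), `clusters` (named vector),
#'   `regions` (`GRanges`), `truth` (planted `domain1`/`domain2` `GRanges`
#'   and spans, per-region classes).
#' @export
simFragments <- function(chromLengths,
                         cells = c(c1 = 435, c2 = 390, c3 = 435, c4 = 435,
                                   c5 = 435, c6 = 435, c7 = 435),
                         tgtClusters = "c2",
                         nRegions = 600,
                         domain1SpanBp = 70000, domain2SpanBp = 45000,
                         rateRatio = 10, fragsPerCellOpen = 1.5,
                         fragWidth = c(50, 150),
                         widthBreaks = c(200, 600, 1000),
                         widthProbs = c(0.9, 0.1),
                         seed = 1) {
  if (rateRatio <= 1) stop("rateRatio must be > 1")
  if (any(cells < 1)) stop("every cluster needs >= 1 cell")
  withSeed(seed, {
    bin <- sample(length(widthProbs), nRegions, TRUE, widthProbs)
    w <- as.integer(runif(nRegions, widthBreaks[bin], widthBreaks[bin + 1]))
    regions <- samplePeaks(chromLengths, nRegions, w, selfAvoid = TRUE)
    regions <- regions[sample(length(regions))]  # declass ordering
    cls <- rep("open", length(regions))
    cum <- cumsum(width(regions))
    pickSpan <- function(startIdx, target) {
      if (target <= 0) return(integer(0))
      i <- startIdx
      acc <- 0L
      idx <- integer(0)
      while (acc < target && i <= length(regions)) {
        idx <- c(idx, i)
        acc <- acc + width(regions)[i]
        i <- i + 1L
      }
      idx
    }
    i1 <- pickSpan(1L, domain1SpanBp)
    i2 <- pickSpan(if (length(i1)) max(i1) + 1L else 1L, domain2SpanBp)
    cls[i1] <- "domain1"
    cls[i2] <- "domain2"
    rest <- setdiff(seq_along(regions), c(i1, i2))
    ## intermediate accessibility dominates; open and low flank it
    restCls <- sample(c("medium", "open", "low"), length(rest), TRUE,
                      prob = c(0.6, 0.25, 0.15))
    cls[rest] <- restCls
    regions <- sortPeaks(`mcols<-`(regions, value = DataFrame(class = cls)))
    cls <- regions$class
    clusters <- setNames(
      rep(names(cells), cells),
      sprintf("cell%05d", seq_len(sum(cells))))
    isTgt <- names(cells) %in% tgtClusters
    rateFor <- function(class, tgt) {
      hi <- fragsPerCellOpen
      lo <- fragsPerCellOpen / rateRatio
      switch(class,
             open = hi,
             medium = hi / 3,
             low = lo,
             domain1 = if (tgt) lo else hi,
             domain2 = if (tgt) hi else lo)
    }
    out <- vector("list", length(cells))
    for (k in seq_along(cells)) {
      cl <- names(cells)[k]
      bar <- names(clusters)[clusters == cl]
      ## per-bp rates: expected fragments scale with region width, so the
      ## per-kb normalized signal is width-independent within a class
      lam <- vapply(cls, rateFor, numeric(1), tgt = isTgt[k]) * cells[[k]] *
        width(regions) / 1000
      counts <- rpois(length(regions), lam)
      tot <- sum(counts)
      if (!tot) next
      ri <- rep(seq_along(regions), counts)
      fw <- as.integer(runif(tot, fragWidth[1], fragWidth[2]))
      s <- start(regions)[ri] +
        as.integer(runif(tot, 0, pmax(1, width(regions)[ri] - fw)))
      out[[k]] <- GRanges(seqnames(regions)[ri],
                          IRanges(s, width = fw),
                          barcode = sample(bar, tot, TRUE))
    }
    keep <- !vapply(out, is.null, logical(1))
    frags <- if (any(keep)) sortPeaks(do.call(c, out[keep]))
    else {
      g <- GRanges()
      g$barcode <- character(0)
      g
    }
    d1 <- granges(regions[cls == "domain1"])
    d2 <- granges(regions[cls == "domain2"])
    list(frags = frags, clusters = clusters, regions = granges(regions),
         truth = list(classes = cls, domain1 = d1, domain2 = d2,
                      domain1_span = sum(width(d1)),
                      domain2_span = sum(width(d2)),
                      rate_ratio = rateRatio))
  })
}

#' Simulate DE table, promoter-binding flags and screen plates
#'
#' Plants exact counts throughout: `nDown` downregulated and `nUp`
#' upregulated genes at adjusted p < 0.05; exactly
#' `round(pBoundGivenDown * nDown)` of the down genes (and the analogous up
#' share) bound at their core promoter; per-factor flags among bound DE
#' genes at the planted fractions (any bound gene left with no factor gets
#' the first factor). Screen plates: a genome-wide arrayed plate with
#' `nTrueHits` planted effects above the fold threshold; a combinatorial
#' plate over all subsets of 8 validated siRNAs with `nSuperCombos` planted
#' to beat the best single; an agonist plate with `nBlunted` planted
#' blunting conditions, of which `nViableBlunted` keep viability.
#'
#' @param nGenes Gene universe size.
#' @param nDown,nUp Planted DE counts.
#' @param pBoundGivenDown,pBoundGivenUp,pBoundGivenNull Promoter-binding
#'   probabilities by DE status.
#' @param perTf Named planted per-factor fractions among bound DE genes.
#' @param nConditions,nTrueHits Arrayed screen size and planted hits.
#' @param controlMean Control percent-positive.
#' @param hitFoldRange Planted fold range for true hits.
#' @param sigma Replicate noise (sd, percent points).
#' @param nRep Replicates per condition.
#' @param nSuperCombos Combinations planted to beat the best single.
#' @param nAgonist,nBlunted,nViableBlunted Agonist screen layout.
#' @param seed Integer seed.
#' @return List: `de`, `bound`, `plate`, `comboPlate`, `agonistPlate`
#'   data.frames and `truth`.
#' @export
simDeScreen <- function(nGenes = 5000, nDown = 501, nUp = 235,
                        pBoundGivenDown = 348 / 501,
                        pBoundGivenUp = 112 / 235,
                        pBoundGivenNull = 0.25,
                        perTf = c(JUNB = 0.97, ATF7IP = 0.40,
                                  SP7 = 0.15, ZNF207 = 0.20),
                        nConditions = 1500, nTrueHits = 69,
                        controlMean = 6, hitFoldRange = c(1.5, 3),
                        sigma = 0.5, nRep = 4, nSuperCombos = 4,
                        nAgonist = 200, nBlunted = 61, nViableBlunted = 9,
                        seed = 1) {
  if (nDown + nUp > nGenes) stop("nDown + nUp exceeds nGenes")
  withSeed(seed, {
    gid <- sprintf("G%05d", seq_len(nGenes))
    status <- rep("null", nGenes)
    de_idx <- sample(nGenes, nDown + nUp)
    status[de_idx[seq_len(nDown)]] <- "down"
    status[de_idx[nDown + seq_len(nUp)]] <- "up"
    lfc <- rnorm(nGenes, 0, 0.2)
    lfc[status == "down"] <- -runif(nDown, 0.5, 4)
    lfc[status == "up"] <- runif(nUp, 0.5, 4)
    padj <- runif(nGenes, 0.05, 1)
    padj[status != "null"] <- runif(nDown + nUp, 1e-8, 0.0499)
    de <- data.frame(gene_id = gid, log2fc = round(lfc, 4),
                     pvalue = signif(padj * 0.8, 4),
                     padj = signif(padj, 4))
    bound <- rep(FALSE, nGenes)
    bDown <- sample(which(status == "down"), round(pBoundGivenDown * nDown))
    bUp <- sample(which(status == "up"), round(pBoundGivenUp * nUp))
    bNull <- sample(which(status == "null"),
                    round(pBoundGivenNull * sum(status == "null")))
    bound[c(bDown, bUp, bNull)] <- TRUE
    boundDe <- c(bDown, bUp)
    flags <- matrix(FALSE, nGenes, length(perTf),
                    dimnames = list(NULL, names(perTf)))
    for (tf in names(perTf))
      flags[sample(boundDe, round(perTf[[tf]] * length(boundDe))), tf] <- TRUE
    for (tf in names(perTf))
      flags[bNull, tf] <- flags[bNull, tf] | (runif(length(bNull)) <
                                                perTf[[tf]] / 2)
    ## bound genes must carry >= 1 factor; fill with the second factor so
    ## the first (headline) planted fraction stays exact
    none <- bound & rowSums(flags) == 0
    flags[none, min(2L, ncol(flags))] <- TRUE
    boundTab <- data.frame(gene_id = gid, flags, bound_any = bound)
    boundTab <- boundTab[bound, , drop = FALSE]
    rownames(boundTab) <- NULL

    draw <- function(mean, n = nRep)
      pmin(100, pmax(0, rnorm(n, mean, sigma)))
    mkPlate <- function(conds, means, cellsMean = NULL) {
      rows <- lapply(seq_along(conds), function(i) {
        data.frame(condition = conds[i], replicate = seq_len(nRep),
                   percent_positive = round(draw(means[i]), 3),
                   cells = if (is.null(cellsMean)) NA_real_ else
                     round(pmax(0, rnorm(nRep, cellsMean[i], 20))))
      })
      out <- do.call(rbind, rows)
      if (is.null(cellsMean)) out$cells <- NULL
      out
    }
    conds <- sprintf("siTF%04d", seq_len(nConditions))
    hitIdx <- sort(sample(nConditions, nTrueHits))
    foldTrue <- rep(1, nConditions)
    foldTrue[hitIdx] <- runif(nTrueHits, hitFoldRange[1], hitFoldRange[2])
    plate <- rbind(
      mkPlate("siControl", controlMean),
      mkPlate(conds, controlMean * foldTrue))

    singles <- c("siAtf7ip", "siJunb", "siSp7", "siZnf207", "siS5", "siS6",
                 "siS7", "siS8")
    singleFold <- c(4.0, 3.5, 3.2, 3.0, 2.8, 2.5, 2.2, 2.0)
    combos <- enumerateCombinations(singles)
    comboNames <- vapply(combos, paste, character(1), collapse = "+")
    multi <- which(lengths(combos) >= 2)
    super <- sample(multi, nSuperCombos)
    comboMeans <- runif(length(combos), controlMean * 2, 22)
    comboMeans[match(singles, comboNames)] <- controlMean * singleFold
    comboMeans[super] <- 36
    comboPlate <- rbind(
      mkPlate("siControl", controlMean),
      mkPlate(comboNames, comboMeans))

    ag <- sprintf("siAg%03d", seq_len(nAgonist))
    bluntIdx <- sort(sample(nAgonist, nBlunted))
    agMeans <- runif(nAgonist, 24, 44)
    agMeans[bluntIdx] <- runif(nBlunted, 5, 18)
    viableIdx <- sample(bluntIdx, nViableBlunted)
    agCells <- rep(950, nAgonist)
    agCells[setdiff(bluntIdx, viableIdx)] <- 300
    agonistPlate <- rbind(
      mkPlate("siControl", controlMean, cellsMean = 1000),
      mkPlate("siAJSZ", 40, cellsMean = 950),
      mkPlate(ag, agMeans, cellsMean = agCells))

    list(de = de, bound = boundTab, plate = plate, comboPlate = comboPlate,
         agonistPlate = agonistPlate,
         truth = list(n_de = nDown + nUp, n_down = nDown, n_up = nUp,
                      n_bound_de = length(boundDe),
                      n_bound_down = length(bDown),
                      n_bound_up = length(bUp),
                      per_tf = perTf,
                      hit_conditions = conds[hitIdx],
                      n_true_hits = nTrueHits,
                      super_combos = comboNames[super],
                      blunted_conditions = ag[bluntIdx],
                      viable_blunted = ag[sort(match(viableIdx,
                                                     seq_len(nAgonist)))]))
  })
}

#' Write the full synthetic fixture set to disk
#'
#' Expands the master `seed` into per-generator child seeds, runs
#' [simGenome()], [simPeaks()] (with the AP-1 motif planted into domain
#' regions via [plantMotif()]), [simFragments()] and [simDeScreen()], and
#' writes every format the pipeline reads: `genome.fa`, `genes.gtf`,
#' `open.bed`, two replicate `<TF>_rep[12].narrowPeak` per factor,
#' `fragments.tsv`, `clusters.tsv`, `de.tsv`, `bound.tsv`, `plate.tsv`,
#' `combo_plate.tsv`, `agonist_plate.tsv` and a machine-readable
#' `truth.json`.
#'
#' @param dir Output directory (created).
#' @param seed Master seed.
#' @param config Optional list overriding generator arguments; entries
#'   `genome`, `peaks`, `fragments`, `descreen` are argument lists.
#' @return Invisibly, the list of in-memory objects plus `paths`.
#' @export
simFixtures <- function(dir, seed = 1, config = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- childSeeds(seed)
  gconf <- modifyList(list(nChrom = 2, chromLength = 1e6, nGenes = 200,
                           seed = seeds[["genome"]]),
                      config$genome %||% list())
  gen <- do.call(simGenome, gconf)
  tfs <- data.frame(
    tf = c("SP7", "ZNF207", "ATF7IP", "JUNB"),
    n = c(250, 125, 400, 800),
    open_fraction = c(0.03, 0.94, 0.21, 0.78))
  cooc <- data.frame(a = c("ATF7IP", "ZNF207", "SP7"),
                     b = c("JUNB", "JUNB", "ATF7IP"),
                     rho = c(0.50, 0.97, 0.70))
  pconf <- modifyList(list(chromLengths = gen$chromLengths, tfs = tfs,
                           cooc = cooc, seed = seeds[["peaks"]]),
                      config$peaks %||% list())
  pk <- do.call(simPeaks, pconf)
  fconf <- modifyList(list(chromLengths = gen$chromLengths,
                           seed = seeds[["fragments"]]),
                      config$fragments %||% list())
  fr <- do.call(simFragments, fconf)
  ## plant motifs: AP-1 in domain1 at 1/kb vs 0.25/kb in domain2;
  ## MEF2-like in domain2 at 0.6/kb vs 0.17/kb in domain1; AP-1 into half
  ## of JUNB's open peaks for the enrichment stage
  genome <- gen$genome
  m1 <- plantMotif(genome, fr$truth$domain1, "TGACTCA", 1.0,
                   seed = seeds[["shuffle"]])
  genome <- m1$genome
  m2 <- plantMotif(genome, fr$truth$domain2, "TGACTCA", 0.25,
                   seed = seeds[["shuffle"]] + 1L)
  genome <- m2$genome
  m3 <- plantMotif(genome, fr$truth$domain2, "CTAAAAATAG", 0.6,
                   seed = seeds[["shuffle"]] + 2L)
  genome <- m3$genome
  m4 <- plantMotif(genome, fr$truth$domain1, "CTAAAAATAG", 0.17,
                   seed = seeds[["shuffle"]] + 3L)
  genome <- m4$genome
  ## plant into JUNB open peaks, but keep clear of the ATAC regions so the
  ## domain-level planted densities stay exact
  junbOpen <- pk$peaks$JUNB[overlapsAny(pk$peaks$JUNB, pk$open,
                                        ignore.strand = TRUE) &
                              !overlapsAny(pk$peaks$JUNB, fr$regions,
                                           ignore.strand = TRUE)]
  m5 <- plantMotif(genome, granges(junbOpen), "TGACTCA", 3.0,
                   seed = seeds[["shuffle"]] + 4L)
  genome <- m5$genome
  ds <- do.call(simDeScreen, modifyList(list(seed = seeds[["descreen"]]),
                                        config$descreen %||% list()))

  p <- function(f) file.path(dir, f)
  writeXStringSet(genome, p("genome.fa"))
  writeGtf(gen$genes, gen$exons, p("genes.gtf"))
  writePeaks(pk$open, p("open.bed"), header = "synthetic open regions")
  for (tf in names(pk$replicates)) for (r in 1:2)
    writePeaks(pk$replicates[[tf]][[r]],
               p(sprintf("%s_rep%d.narrowPeak", tf, r)),
               format = "narrowPeak", header = paste("synthetic", tf))
  fdf <- data.frame(chrom = as.character(seqnames(fr$frags)),
                    start = start(fr$frags) - 1L, end = end(fr$frags),
                    barcode = fr$frags$barcode)
  write.table(fdf, p("fragments.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(names(fr$clusters), fr$clusters), p("clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  writePeaks(fr$regions, p("regions.bed"), header = "synthetic ATAC regions")
  tsv <- function(df, f) write.table(df, p(f), sep = "\t", quote = FALSE,
                                     row.names = FALSE)
  tsv(ds$de, "de.tsv")
  tsv(ds$bound, "bound.tsv")
  tsv(ds$plate, "plate.tsv")
  tsv(ds$comboPlate, "combo_plate.tsv")
  tsv(ds$agonistPlate, "agonist_plate.tsv")
  truth <- list(seed = seed, child_seeds = as.list(seeds),
                peaks = pk$truth,
                fragments = list(domain1_span = fr$truth$domain1_span,
                                 domain2_span = fr$truth$domain2_span,
                                 rate_ratio = fr$truth$rate_ratio),
                motifs = list(ap1_d1_planted = m1$n_planted,
                              ap1_d2_planted = m2$n_planted,
                              mef2_d2_planted = m3$n_planted,
                              mef2_d1_planted = m4$n_planted,
                              ap1_junb_open_planted = m5$n_planted),
                descreen = ds$truth)
  write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA,
             pretty = TRUE)
  invisible(list(genome = genome, genes = gen$genes, exons = gen$exons,
                 peaks = pk, fragments = fr, descreen = ds, truth = truth,
                 dir = dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write gene models as GTF
#'
#' @param genes,exons `GRanges` with `gene_id` (1-based closed on disk).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGtf <- function(genes, exons, path) {
  row <- function(gr, feat) {
    sprintf("%s\tfatebarrier_sim\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\";",
            as.character(seqnames(gr)), feat, start(gr), end(gr),
            as.character(strand(gr)), gr$gene_id,
            if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id)
  }
  writeLines(c(row(genes, "gene"), row(exons, "exon")), path)
  invisible(path)
}
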