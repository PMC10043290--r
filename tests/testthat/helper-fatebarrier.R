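suppressPackageStartupMessages(library(GenomicRanges))

## Jaccard index of two region sets (bp-level)
jaccardBp <- function(a, b) {
  i <- sum(width(GenomicRanges::intersect(a, b, ignore.strand = TRUE)))
  u <- sum(width(GenomicRanges::union(a, b, ignore.strand = TRUE)))
  if (u == 0) return(1)
  i / u
}

## per-bp boolean-mask merge oracle on a single toy chromosome
maskMerge <- function(starts0, ends0, gap = 0, L = max(ends0) + gap + 1) {
  mask <- logical(L)
  for (i in seq_along(starts0))
    mask[(starts0[i] + 1):ends0[i]] <- TRUE
  if (gap > 0) {
    ## close gaps <= gap between covered runs
    r <- rle(mask)
    cs <- cumsum(r$lengths)
    for (j in seq_along(r$values)) {
      if (!r$values[j] && r$lengths[j] <= gap &&
          j > 1 && j < length(r$values))
        mask[(cs[j] - r$lengths[j] + 1):cs[j]] <- TRUE
    }
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start0 = starts[keep] - 1L, end0 = ends[keep])
}

## quadratic all-pairs overlap oracle mirroring intersectPeaks semantics
quadIntersect <- function(a, b, minBp = 1, minFrac = 0) {
  adf <- bedFrame(a, mcols = FALSE)
  bdf <- bedFrame(b, mcols = FALSE)
  out <- data.frame(overlapped = logical(nrow(adf)),
                    partner = NA_integer_, overlap_bp = 0L)
  for (i in seq_len(nrow(adf))) {
    best <- 0L
    bestj <- NA_integer_
    for (j in seq_len(nrow(bdf))) {
      if (adf$chrom[i] != bdf$chrom[j]) next
      ov <- min(adf$end[i], bdf$end[j]) - max(adf$start[i], bdf$start[j])
      if (ov < minBp || ov < minFrac * (adf$end[i] - adf$start[i])) next
      if (ov > best || (ov == best && !is.na(bestj) &&
                        bdf$start[j] < bdf$start[bestj])) {
        best <- ov
        bestj <- j
      }
    }
    if (!is.na(bestj)) {
      out$overlapped[i] <- TRUE
      out$partner[i] <- bestj
      out$overlap_bp[i] <- best
    }
  }
  out
}

## random interval set on one chromosome (0-based coordinates)
randIntervals <- function(n, L = 1e5, wmax = 500, chrom = "chr1", seed = 1) {
  set.seed(seed)
  s <- sample.int(L - wmax, n, replace = TRUE) - 1L
  w <- sample.int(wmax, n, replace = TRUE)
  grFromBed(rep(chrom, n), s, s + w)
}

## shared default synthetic fixture set + two pipeline runs, built once per
## test session (used by the pipeline and acceptance files)
.fixtureCache <- new.env(parent = emptyenv())
sharedFixtures <- function(seed = 7) {
  key <- paste0("fx", seed)
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  dir <- file.path(tempdir(), paste0("fatebarrier-fx-", seed))
  fx <- simFixtures(dir, seed = seed)
  .fixtureCache[[key]] <- fx
  fx
}

fixtureConfig <- function(fx, out, seed = 7) {
  p <- function(f) file.path(fx$dir, f)
  tfs <- names(fx$peaks$peaks)
  list(seed = seed, out = out,
       inputs = list(
         genome = p("genome.fa"), gtf = p("genes.gtf"), open = p("open.bed"),
         peaks = lapply(setNames(nm = tfs), function(tf)
           list(p(sprintf("%s_rep1.narrowPeak", tf)),
                p(sprintf("%s_rep2.narrowPeak", tf)))),
         fragments = p("fragments.tsv"), clusters = p("clusters.tsv"),
         regions = p("regions.bed"), de = p("de.tsv"), bound = p("bound.tsv"),
         plate = p("plate.tsv"), combo_plate = p("combo_plate.tsv"),
         agonist_plate = p("agonist_plate.tsv")))
}

sharedPipelineRun <- function(which = 1L) {
  key <- paste0("run", which)
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  fx <- sharedFixtures()
  out <- file.path(tempdir(), paste0("fatebarrier-out-", which))
  s <- suppressMessages(runPipeline(fixtureConfig(fx, out)))
  res <- list(summary = s, out = out)
  .fixtureCache[[key]] <- res
  res
}
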