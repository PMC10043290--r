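## Internal coordinate helpers. On-disk formats (BED, narrowPeak, fragments)
## are 0-based half-open; in memory everything is a GRanges (1-based closed).

#' Build a GRanges from 0-based half-open coordinates
#'
#' Convenience constructor mirroring the BED convention used by all on-disk
#' inputs: `start` is 0-based inclusive, `end` exclusive.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand strand codes (`+`, `-`, `*`); recycled.
#' @param ... further metadata columns passed to [GenomicRanges::GRanges].
#' @return A `GRanges`.
#' @export
#' @examples
#' grFromBed(c("chr1", "chr1"), c(0, 20), c(10, 30))
grFromBed <- function(chrom, start, end, strand = "*", ...) {
  stopifnot(length(start) == length(end))
  if (length(chrom) == 1) chrom <- rep(chrom, length(start))
  if (length(strand) == 1) strand <- rep(strand, length(start))
  stopifnot(length(chrom) == length(start))
  if (length(start) && any(start < 0 | start >= end))
    stop("invalid interval: need 0 <= start < end")
  GRanges(seqnames = chrom,
          ranges = IRanges(start = as.integer(start) + 1L,
                           end = as.integer(end)),
          strand = strand, ...)
}

#' Convert a GRanges to a 0-based half-open data.frame
#'
#' @param gr A `GRanges`.
#' @param mcols Keep metadata columns?
#' @return data.frame with `chrom`, `start`, `end` (BED convention) and,
#'   optionally, the metadata columns.
#' @export
bedFrame <- function(gr, mcols = TRUE) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L,
                   end = end(gr),
                   stringsAsFactors = FALSE)
  if (mcols && ncol(S4Vectors::mcols(gr)))
    df <- cbind(df, as.data.frame(S4Vectors::mcols(gr)))
  df
}

## sort by chromosome (natural seqlevel order) then start, ignoring strand
sortPeaks <- function(gr) {
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

## total bp covered, counting overlaps once
coveredBp <- function(gr) {
  sum(width(GenomicRanges::reduce(gr, ignore.strand = TRUE)))
}

## vectorised two-proportion z-test (pooled, no continuity correction):
## counts x1 of n1 vs x2 of n2; returns two-sided p-values.
twoPropZ <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  p <- 2 * pnorm(-abs(z))
  p[!is.finite(z)] <- 1      # zero counts on both sides, or zero variance
  p
}

## deterministic per-generator child seeds from one master seed: a fixed
## counter scheme so regenerating one input never perturbs another.
childSeeds <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  names <- c("genome", "peaks", "fragments", "descreen", "shuffle",
             "pipeline", "spare1", "spare2")
  s <- (as.double(seed) * 48271 + 7919 * seq_along(names)) %% (2^31 - 1)
  setNames(as.integer(s), names)
}
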