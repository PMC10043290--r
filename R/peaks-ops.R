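#' Merge intervals within a gap
#'
#' Unions all intervals that overlap, abut, or lie within `gap` bp of each
#' other (sweep-line semantics, strand-ignorant). Idempotent and invariant to
#' input order; the merged set never spans more bp than the input covers.
#'
#' @param gr A `GRanges`.
#' @param gap Non-negative gap in bp; intervals separated by at most this
#'   many bp are unioned. Default 0 (overlapping or abutting only).
#' @return A sorted, merged `GRanges` (metadata columns dropped).
#' @export
#' @examples
#' mergePeaks(grFromBed("chr1", c(0, 5), c(10, 15)))
mergePeaks <- function(gr, gap = 0) {
  if (!is.numeric(gap) || length(gap) != 1 || is.na(gap) || gap < 0)
    stop("gap must be a single non-negative number")
  sortPeaks(GenomicRanges::reduce(gr, min.gapwidth = gap + 1,
                                  ignore.strand = TRUE))
}

#' Consolidate replicate peak sets for one factor
#'
#' Two readings of "replicated peaks" across ChIP replicates are supported:
#' `union_merge` (default) merges the concatenation of all replicates;
#' `intersection` keeps only the merged regions covered by at least one peak
#' in *every* replicate (reproducibility filtering). The union span is always
#' greater than or equal to the intersection span.
#'
#' @param reps A list of `GRanges`, one per replicate (>= 1).
#' @param mode `"union_merge"` or `"intersection"`.
#' @param gap Merge gap in bp, passed to [mergePeaks()].
#' @return A sorted, merged `GRanges`.
#' @export
#' @examples
#' reps <- list(grFromBed("chr1", 0, 10), grFromBed("chr1", 5, 15))
#' consolidateReplicates(reps)                      # chr1:0-15
#' consolidateReplicates(reps, "intersection")      # chr1:5-10
consolidateReplicates <- function(reps, mode = c("union_merge", "intersection"),
                                  gap = 0) {
  mode <- match.arg(mode)
  if (!is.list(reps) || length(reps) == 0)
    stop("reps must be a non-empty list of GRanges")
  if (mode == "union_merge") {
    mergePeaks(do.call(c, lapply(reps, granges)), gap = gap)
  } else {
    covers <- lapply(reps, mergePeaks, gap = gap)
    out <- Reduce(function(a, b)
      GenomicRanges::intersect(a, b, ignore.strand = TRUE), covers)
    sortPeaks(out)
  }
}

#' Per-record overlap report between two interval sets
#'
#' For every record of `a`, reports whether some record of `b` overlaps it by
#' at least `minOverlapBp` bp *and* at least `minOverlapFrac` of the
#' `a`-record's length, plus the best partner (largest overlap, ties broken
#' by smaller partner start) and the overlap size. The call is asymmetric:
#' swap the arguments for the reciprocal report.
#'
#' @param a,b `GRanges`.
#' @param minOverlapBp Minimum overlap in bp (>= 1).
#' @param minOverlapFrac Minimum overlap as a fraction of the `a` record
#'   length, in `[0, 1]`.
#' @return A data.frame with one row per `a` record: 0-based `chrom`,
#'   `start`, `end`, logical `overlapped`, integer `partner` (index into `b`,
#'   `NA` when none), `overlap_bp`.
#' @export
intersectPeaks <- function(a, b, minOverlapBp = 1, minOverlapFrac = 0) {
  if (minOverlapBp < 1) stop("minOverlapBp must be >= 1")
  if (minOverlapFrac < 0 || minOverlapFrac > 1)
    stop("minOverlapFrac must be in [0, 1]")
  hits <- suppressWarnings(findOverlaps(a, b, ignore.strand = TRUE))
  ov <- suppressWarnings(width(pintersect(granges(a)[queryHits(hits)],
                                          granges(b)[subjectHits(hits)],
                                          ignore.strand = TRUE)))
  qualified <- ov >= minOverlapBp &
    ov >= minOverlapFrac * width(a)[queryHits(hits)]
  hq <- hits[qualified]
  ovq <- ov[qualified]
  n <- length(a)
  out <- data.frame(bedFrame(granges(a), mcols = FALSE),
                    overlapped = rep(FALSE, n),
                    partner = rep(NA_integer_, n),
                    overlap_bp = rep(0L, n))
  if (length(hq)) {
    ## best partner per a record: max overlap, then smallest b start
    ord <- order(queryHits(hq), -ovq, start(b)[subjectHits(hq)])
    first <- !duplicated(queryHits(hq)[ord])
    qi <- queryHits(hq)[ord][first]
    out$overlapped[qi] <- TRUE
    out$partner[qi] <- subjectHits(hq)[ord][first]
    out$overlap_bp[qi] <- ovq[ord][first]
  }
  out
}
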