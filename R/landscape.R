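#' Classify binding sites as open or closed chromatin
#'
#' A peak is called "open" when it overlaps the (merged) open-chromatin
#' region set by at least `minOverlapBp` bp, "closed" otherwise. This is the
#' operational definition of chromatin state used throughout: accessibility
#' is overlap with ATAC peak regions.
#'
#' @param peaks `GRanges` of binding sites for one factor.
#' @param openRegions `GRanges` of open-chromatin regions (merged internally
#'   if not already).
#' @param minOverlapBp Minimum overlap in bp (default 1).
#' @param tf Factor name carried into the result.
#' @return A `stateClassification` list: `tf`, per-peak `state` factor
#'   (`open`/`closed`), `n_open`, `n_closed`, `frac_open`, `frac_closed`
#'   (fractions are `NA` for an empty peak set, never 0).
#' @export
#' @examples
#' classifyByState(grFromBed("chr1", 100, 200), grFromBed("chr1", 150, 160))
classifyByState <- function(peaks, openRegions, minOverlapBp = 1, tf = "TF") {
  openRegions <- mergePeaks(openRegions)
  rep_ <- intersectPeaks(peaks, openRegions, minOverlapBp = minOverlapBp)
  state <- factor(ifelse(rep_$overlapped, "open", "closed"),
                  levels = c("open", "closed"))
  n_open <- sum(state == "open")
  n_closed <- sum(state == "closed")
  total <- n_open + n_closed
  structure(list(tf = tf, state = state,
                 n_open = n_open, n_closed = n_closed,
                 frac_open = if (total) n_open / total else NA_real_,
                 frac_closed = if (total) n_closed / total else NA_real_),
            class = "stateClassification")
}

#' @export
print.stateClassification <- function(x, ...) {
  cat(sprintf("chromatin-state classification for %s: %d peaks\n",
              x$tf, x$n_open + x$n_closed))
  cat(sprintf("  open:   %6d (%s)\n", x$n_open, pct1(x$frac_open)))
  cat(sprintf("  closed: %6d (%s)\n", x$n_closed, pct1(x$frac_closed)))
  invisible(x)
}

pct1 <- function(f) if (is.na(f)) "NA" else sprintf("%.1f%%", 100 * f)

#' Pairwise co-occupancy between factors
#'
#' `M[a, b]` is the fraction of factor `a`'s peaks overlapped by at least one
#' peak of factor `b`; the matrix is therefore row-normalized and not
#' symmetric in general. An optional per-factor chromatin-state
#' classification restricts the row factor's peaks to one stratum; by default
#' the partner's *full* peak set is used, set `samePartnerStratum = TRUE` to
#' restrict both sides.
#'
#' @param peakSets Named list of `GRanges` (>= 2 factors).
#' @param minOverlapBp Minimum overlap in bp defining "co-occupied".
#' @param stratum Optional named list of [classifyByState()] results covering
#'   every factor in `peakSets`.
#' @param stratumState `"all"`, `"open"` or `"closed"` — which stratum to
#'   keep when `stratum` is supplied.
#' @param samePartnerStratum Restrict partner peaks to the same stratum?
#' @return A `cooccupancyMatrix` list: fraction `matrix`, co-occupied
#'   `counts`, row peak totals `n`, and the `stratum` label.
#' @export
cooccupancy <- function(peakSets, minOverlapBp = 1, stratum = NULL,
                        stratumState = c("all", "open", "closed"),
                        samePartnerStratum = FALSE) {
  stratumState <- match.arg(stratumState)
  if (length(peakSets) < 2 || is.null(names(peakSets)))
    stop("peakSets must be a named list of >= 2 GRanges")
  tfs <- names(peakSets)
  if (!is.null(stratum) && stratumState != "all") {
    missing <- setdiff(tfs, names(stratum))
    if (length(missing))
      stop("no state classification for: ", paste(missing, collapse = ", "))
    sel <- lapply(tfs, function(tf)
      peakSets[[tf]][stratum[[tf]]$state == stratumState])
    names(sel) <- tfs
  } else sel <- peakSets
  rows <- sel
  cols <- if (samePartnerStratum) sel else peakSets
  M <- matrix(NA_real_, length(tfs), length(tfs), dimnames = list(tfs, tfs))
  K <- matrix(0L, length(tfs), length(tfs), dimnames = list(tfs, tfs))
  n <- vapply(rows, length, integer(1))
  for (a in tfs) for (b in tfs) {
    if (n[[a]] == 0) next
    k <- sum(suppressWarnings(
      countOverlaps(rows[[a]], cols[[b]], minoverlap = minOverlapBp,
                    ignore.strand = TRUE)) > 0)
    K[a, b] <- k
    M[a, b] <- k / n[[a]]
  }
  structure(list(matrix = M, counts = K, n = n,
                 stratum = if (is.null(stratum)) "all" else stratumState),
            class = "cooccupancyMatrix")
}

#' @export
print.cooccupancyMatrix <- function(x, ...) {
  cat(sprintf("co-occupancy (row peaks overlapped by column factor), stratum = %s\n",
              x$stratum))
  print(round(x$matrix, 3))
  invisible(x)
}
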