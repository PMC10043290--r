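#' Read a fragments table
#'
#' Four-or-more column TSV `(chrom, start, end, barcode)` with 0-based
#' half-open coordinates, optionally gzipped. Extra columns are ignored.
#'
#' @param path Path to the fragments file.
#' @return `GRanges` with a `barcode` metadata column.
#' @export
readFragments <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = c("character", "integer", "integer",
                                  "character"),
                   col.names = c("chrom", "start", "end", "barcode"),
                   fill = TRUE)[, 1:4]
  if (nrow(df) && any(df$start >= df$end))
    stop("fragment with start >= end at row ", which(df$start >= df$end)[1])
  grFromBed(df$chrom, df$start, df$end, barcode = df$barcode)
}

#' Read a barcode-to-cluster map
#'
#' @param path Two-column TSV `(barcode, cluster)`, no header.
#' @return Named character vector `barcode -> cluster`.
#' @export
readClusterMap <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = "character")[, 1:2]
  setNames(df[[2]], df[[1]])
}

#' Pseudobulk accessibility from single-cell fragments
#'
#' Aggregates fragments into a regions x cluster-groups count matrix. A
#' fragment counts once for every region it overlaps by >= 1 bp; fragments
#' outside all regions still contribute to their group's depth. Fragments
#' whose barcode has no cluster label are excluded (count reported in a
#' message).
#'
#' @param frags `GRanges` with a `barcode` column ([readFragments()]).
#' @param clusters Named vector `barcode -> cluster` ([readClusterMap()]).
#' @param regions Merged `GRanges` of regions (bins or peak union).
#' @param groups Named list mapping group name -> character vector of
#'   cluster ids; groups must be disjoint, every group must contain at least
#'   one cell.
#' @return An [AccessibilityExperiment-class].
#' @export
pseudobulk <- function(frags, clusters, regions, groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  allcl <- unlist(groups)
  if (anyDuplicated(allcl)) stop("groups must be disjoint")
  cl <- clusters[frags$barcode]
  unlabeled <- sum(is.na(cl))
  if (unlabeled)
    message(unlabeled, " fragment(s) with unlabeled barcode excluded")
  cellgrp <- rep(NA_character_, length(clusters))
  for (g in names(groups)) {
    if (!any(clusters %in% groups[[g]]))
      stop("group '", g, "' has no cells")
    cellgrp[clusters %in% groups[[g]]] <- g
  }
  grp <- setNames(cellgrp, names(clusters))[frags$barcode]
  counts <- matrix(0L, nrow = length(regions), ncol = length(groups),
                   dimnames = list(NULL, names(groups)))
  depth <- setNames(integer(length(groups)), names(groups))
  ncells <- setNames(integer(length(groups)), names(groups))
  for (g in names(groups)) {
    fg <- frags[!is.na(grp) & grp == g]
    depth[[g]] <- length(fg)
    ncells[[g]] <- sum(cellgrp == g, na.rm = TRUE)
    counts[, g] <- countOverlaps(regions, fg, ignore.strand = TRUE)
  }
  lenkb <- width(regions) / 1000
  norm <- sweep(counts * 1e6, 2, pmax(depth, 1L), "/") / lenkb
  se <- SummarizedExperiment(
    assays = list(counts = counts, normalized = norm),
    rowRanges = regions,
    colData = DataFrame(depth = as.integer(depth),
                        n_cells = as.integer(ncells),
                        row.names = names(groups)))
  new("AccessibilityExperiment", se)
}

#' Call differentially accessible open/closed domains
#'
#' A region is *open* in a group when its normalized signal is at least
#' `tauOpen` and *closed* when at most `tauClosed` (signals in between are a
#' buffer zone). Domain 1 regions are open in every reference group and
#' closed in every target group; domain 2 is the converse. A call
#' additionally requires a Benjamini-Hochberg adjusted two-proportion z-test
#' (pooled fragment counts against pooled depths) at `q <= alpha`. Called
#' regions of the same class within `mergeGap` bp are merged.
#'
#' Thresholds default to 2x (open) and 0.5x (closed) the genome-wide median
#' of the nonzero normalized signal.
#'
#' @param mat An [AccessibilityExperiment-class].
#' @param refGroup,tgtGroup Column (group) names; several reference groups
#'   are combined with an all-must-agree rule.
#' @param tauOpen,tauClosed Normalized-signal thresholds
#'   (`tauClosed < tauOpen`).
#' @param alpha FDR level.
#' @param mergeGap Merge gap for adjacent same-class calls (bp).
#' @return A `domainCalls` list: per-region `calls` data.frame (`class`,
#'   `N_ref`, `N_tgt`, `p_value`, `q_value`), merged `domain1` and `domain2`
#'   `GRanges`, and the thresholds `tau`.
#' @export
callDomains <- function(mat, refGroup, tgtGroup, tauOpen = NULL,
                        tauClosed = NULL, alpha = 0.05, mergeGap = 0) {
  N <- normalizedCounts(mat)
  C <- SummarizedExperiment::assay(mat, "counts")
  D <- groupDepths(mat)
  miss <- setdiff(c(refGroup, tgtGroup), colnames(N))
  if (length(miss)) stop("unknown group(s): ", paste(miss, collapse = ", "))
  if (is.null(tauOpen) || is.null(tauClosed)) {
    med <- stats::median(N[N > 0])
    if (is.null(tauOpen)) tauOpen <- 2 * med
    if (is.null(tauClosed)) tauClosed <- 0.5 * med
  }
  if (tauClosed >= tauOpen) stop("tauClosed must be < tauOpen")
  openIn <- function(groups)
    rowSums(N[, groups, drop = FALSE] >= tauOpen) == length(groups)
  closedIn <- function(groups)
    rowSums(N[, groups, drop = FALSE] <= tauClosed) == length(groups)
  xr <- rowSums(C[, refGroup, drop = FALSE])
  xt <- rowSums(C[, tgtGroup, drop = FALSE])
  nr <- sum(D[refGroup])
  nt <- sum(D[tgtGroup])
  p <- twoPropZ(xr, nr, xt, nt)
  q <- p.adjust(p, "BH")
  d1 <- openIn(refGroup) & closedIn(tgtGroup) & q <= alpha
  d2 <- closedIn(refGroup) & openIn(tgtGroup) & q <= alpha
  cls <- rep(NA_character_, nrow(N))
  cls[d1] <- "domain1"
  cls[d2] <- "domain2"
  regions <- rowRanges(mat)
  calls <- data.frame(bedFrame(granges(regions), mcols = FALSE),
                      class = cls,
                      N_ref = rowMeans(N[, refGroup, drop = FALSE]),
                      N_tgt = rowMeans(N[, tgtGroup, drop = FALSE]),
                      p_value = p, q_value = q)
  structure(list(calls = calls,
                 domain1 = mergePeaks(regions[d1], gap = mergeGap),
                 domain2 = mergePeaks(regions[d2], gap = mergeGap),
                 tau = c(open = tauOpen, closed = tauClosed),
                 alpha = alpha),
            class = "domainCalls")
}

#' @export
print.domainCalls <- function(x, ...) {
  cat(sprintf("domain calls (tau_open %.3g, tau_closed %.3g, alpha %g)\n",
              x$tau[["open"]], x$tau[["closed"]], x$alpha))
  cat(sprintf("  domain1: %d regions, %d bp\n", length(x$domain1),
              sum(width(x$domain1))))
  cat(sprintf("  domain2: %d regions, %d bp\n", length(x$domain2),
              sum(width(x$domain2))))
  invisible(x)
}

#' Summarize called domains
#'
#' @param calls A `domainCalls` object.
#' @param breaks Length-histogram bin edges in bp.
#' @return List with per-class data.frame `summary` (`n`, `span_bp`), the
#'   length `histogram` (class x bin counts) and `per_chromosome` counts.
#' @export
domainSummary <- function(calls,
                          breaks = c(0, 200, 400, 600, 800, 1000, Inf)) {
  classes <- c("domain1", "domain2")
  grs <- list(domain1 = calls$domain1, domain2 = calls$domain2)
  summary <- data.frame(
    class = classes,
    n = vapply(grs, length, integer(1)),
    span_bp = vapply(grs, function(g) sum(width(g)), numeric(1)))
  labs <- paste0("[", head(breaks, -1), ",", breaks[-1], ")")
  hist <- t(vapply(grs, function(g)
    as.integer(table(cut(width(g), breaks, right = FALSE, labels = labs))),
    integer(length(labs))))
  colnames(hist) <- labs
  chroms <- sort(unique(unlist(lapply(grs, function(g)
    as.character(seqnames(g))))))
  perchr <- matrix(
    unlist(lapply(grs, function(g)
      as.integer(table(factor(as.character(seqnames(g)),
                              levels = chroms))))),
    nrow = length(chroms), ncol = length(grs),
    dimnames = list(chroms, classes))
  list(summary = summary, histogram = hist, per_chromosome = perchr)
}

#' Binding density of factors inside called domains
#'
#' @param calls A `domainCalls` object.
#' @param peakSets Named list of `GRanges`, one per factor.
#' @return data.frame: `tf`, `class`, `n_peaks` (peaks overlapping any region
#'   of the class by >= 1 bp), `span_bp`, `density_per_mbp` (`NA` when the
#'   class span is 0).
#' @export
bindingDensityInDomains <- function(calls, peakSets) {
  grs <- list(domain1 = calls$domain1, domain2 = calls$domain2)
  rows <- list()
  for (tf in names(peakSets)) for (cl in names(grs)) {
    span <- sum(width(grs[[cl]]))
    k <- sum(suppressWarnings(countOverlaps(peakSets[[tf]], grs[[cl]],
                                            ignore.strand = TRUE)) > 0)
    rows[[paste(tf, cl)]] <- data.frame(
      tf = tf, class = cl, n_peaks = k, span_bp = span,
      density_per_mbp = if (span > 0) k * 1e6 / span else NA_real_)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Differential accessibility at transcription start sites
#'
#' Runs the two-proportion test per gene on an accessibility matrix whose
#' regions are core-promoter windows tagged with `gene_id` (duplicate
#' windows for one gene are summed). Output is sorted by q-value; the gene
#' list (with direction) is the deliverable.
#'
#' @param mat [AccessibilityExperiment-class] over promoter windows with a
#'   `gene_id` metadata column on its regions.
#' @param refGroup,tgtGroup Group names (pooled within each side).
#' @param alpha FDR level for the `called` flag.
#' @return data.frame: `gene_id`, pooled `count_ref`/`count_tgt`, `direction`
#'   (`"more accessible in target"` / `"more accessible in reference"`),
#'   `p_value`, `q_value`, `called`.
#' @export
tssDifferentialAccessibility <- function(mat, refGroup, tgtGroup,
                                         alpha = 0.05) {
  gid <- rowRanges(mat)$gene_id
  if (is.null(gid)) stop("regions must carry a gene_id column")
  C <- SummarizedExperiment::assay(mat, "counts")
  D <- groupDepths(mat)
  xr <- tapply(rowSums(C[, refGroup, drop = FALSE]), gid, sum)
  xt <- tapply(rowSums(C[, tgtGroup, drop = FALSE]), gid, sum)
  nr <- sum(D[refGroup])
  nt <- sum(D[tgtGroup])
  p <- twoPropZ(as.numeric(xr), nr, as.numeric(xt), nt)
  q <- p.adjust(p, "BH")
  out <- data.frame(gene_id = names(xr),
                    count_ref = as.integer(xr), count_tgt = as.integer(xt),
                    direction = ifelse(xt / nt >= xr / nr,
                                       "more accessible in target",
                                       "more accessible in reference"),
                    p_value = p, q_value = q, called = q <= alpha)
  out[order(out$q_value, out$p_value, out$gene_id), , drop = FALSE]
}
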