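#' AccessibilityExperiment: pseudobulk accessibility counts
#'
#' A thin [SummarizedExperiment::RangedSummarizedExperiment] holding
#' per-region, per-cluster-group fragment counts (`counts` assay), the
#' depth-and-length normalized signal (`normalized` assay, fragments per
#' million per kb), per-group sequencing depths (`colData(x)$depth`) and the
#' number of cells per group (`colData(x)$n_cells`).
#'
#' @export
setClass("AccessibilityExperiment",
         contains = "RangedSummarizedExperiment")

setValidity("AccessibilityExperiment", function(object) {
  a <- SummarizedExperiment::assays(object)
  if (!all(c("counts", "normalized") %in% names(a)))
    return("needs 'counts' and 'normalized' assays")
  if (any(a$counts < 0)) return("counts must be non-negative")
  cd <- SummarizedExperiment::colData(object)
  if (!"depth" %in% names(cd)) return("colData must carry per-group 'depth'")
  if (any(colSums(a$counts) > 0 & cd$depth <= 0))
    return("positive counts with zero depth")
  TRUE
})

#' @describeIn AccessibilityExperiment-class Normalized signal matrix
#'   (fragments per million per kb).
#' @param x An `AccessibilityExperiment`.
#' @export
normalizedCounts <- function(x) SummarizedExperiment::assay(x, "normalized")

#' @describeIn AccessibilityExperiment-class Per-group total fragment depths.
#' @export
groupDepths <- function(x) {
  setNames(SummarizedExperiment::colData(x)$depth, colnames(x))
}

setMethod("show", "AccessibilityExperiment", function(object) {
  cat(sprintf("AccessibilityExperiment: %d regions x %d groups\n",
              nrow(object), ncol(object)))
  cat("  depths:", paste(sprintf("%s=%d", colnames(object),
                                 SummarizedExperiment::colData(object)$depth),
                         collapse = ", "), "\n")
  invisible(object)
})
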