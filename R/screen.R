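#' Read an arrayed-screen plate table
#'
#' TSV with header columns `condition`, `replicate`, `percent_positive` and
#' optionally `cells` (viable-cell count).
#'
#' @param path Path to the TSV.
#' @return data.frame.
#' @export
readPlate <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("condition", "replicate", "percent_positive")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing plate column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Normalize screen conditions to control and test against it
#'
#' For every condition, the fold is the ratio of replicate means to the
#' control mean; the p-value comes from a two-tailed unpaired Student's
#' (equal-variance by default) t-test of the *raw* replicate percentages
#' against the control replicates — normalization is for reporting only,
#' since dividing by a noisy control mean would distort the test. Conditions
#' with a single replicate get their fold but an `NA` p-value.
#'
#' @param plate Plate data.frame ([readPlate()]).
#' @param control Control condition id (must have >= 2 replicates).
#' @param varEqual Equal-variance Student's t-test (default); `FALSE` for
#'   Welch.
#' @return data.frame (`hitTable`): `condition`, `n`, `mean`, `fold`,
#'   `p_value`, plus `mean_cells`/`viability` when the plate has a `cells`
#'   column.
#' @export
normalizeAndTest <- function(plate, control = "siControl", varEqual = TRUE) {
  ctrl <- plate$percent_positive[plate$condition == control]
  if (length(ctrl) < 2) stop("control must have >= 2 replicates")
  m0 <- mean(ctrl)
  if (m0 == 0) stop("control mean is zero")
  conds <- unique(plate$condition)
  rows <- lapply(conds, function(cd) {
    v <- plate$percent_positive[plate$condition == cd]
    p <- if (cd == control) 1.0
    else if (length(v) < 2) NA_real_
    else twoSampleP(v, ctrl, varEqual)
    data.frame(condition = cd, n = length(v), mean = mean(v),
               fold = mean(v) / m0, p_value = p)
  })
  out <- do.call(rbind, rows)
  if ("cells" %in% names(plate)) {
    mc <- tapply(plate$cells, plate$condition, mean)
    out$mean_cells <- as.numeric(mc[out$condition])
    out$viability <- out$mean_cells / mc[[control]]
  }
  rownames(out) <- NULL
  out
}

#' Call screen hits
#'
#' A condition is a hit when its fold strictly exceeds `foldMin` (for
#' `direction = "increase"`; strictly below `1/foldMin` for `"decrease"`)
#' and its t-test p-value is below `alpha`. No multiple-testing correction
#' is applied (per-condition p < alpha criterion); an optional BH column
#' (`padj_bh`) is added for reference.
#'
#' @param hits Hit table from [normalizeAndTest()].
#' @param foldMin Fold threshold (strict), default 1.25.
#' @param alpha P-value threshold (strict), default 0.05.
#' @param direction `"increase"` or `"decrease"`.
#' @return The hit table with `hit` and `padj_bh` columns added.
#' @export
callHits <- function(hits, foldMin = 1.25, alpha = 0.05,
                     direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  passFold <- if (direction == "increase") hits$fold > foldMin else
    hits$fold < 1 / foldMin
  hits$padj_bh <- p.adjust(hits$p_value, "BH")
  hits$hit <- passFold & !is.na(hits$p_value) & hits$p_value < alpha
  hits
}

#' Enumerate all condition combinations
#'
#' All subsets of `items` with at least `minSize` members, ordered by size
#' then lexicographically — e.g. 8 validated siRNAs give
#' \eqn{2^8 - 1 = 255} combinations.
#'
#' @param items Character vector of ids (1 to 20).
#' @param minSize Smallest subset size.
#' @return List of character vectors.
#' @export
enumerateCombinations <- function(items, minSize = 1) {
  n <- length(items)
  if (n < 1 || n > 20) stop("need 1 to 20 items")
  items <- sort(items)
  out <- list()
  for (k in seq(minSize, n))
    out <- c(out, combn(items, k, simplify = FALSE))
  out
}

#' Compare combinations to the most potent single hit
#'
#' Identifies the best single condition (largest mean fold among `singles`)
#' and t-tests every other condition's replicates against it; a combination
#' is flagged when p < `alpha` and its fold exceeds the best single's.
#'
#' @param plate Plate data.frame with combination and single conditions.
#' @param hits Hit table from [normalizeAndTest()] on the same plate.
#' @param singles Condition ids of the single perturbations.
#' @param alpha Significance threshold.
#' @param varEqual Equal-variance t-test (default).
#' @return data.frame: `condition`, `fold`, `best_single`, `p_vs_best`,
#'   `exceeds` flag.
#' @export
compareToBestSingle <- function(plate, hits, singles, alpha = 0.05,
                                varEqual = TRUE) {
  sh <- hits[hits$condition %in% singles, ]
  if (!nrow(sh)) stop("no single conditions found")
  best <- sh$condition[which.max(sh$fold)]
  bv <- plate$percent_positive[plate$condition == best]
  if (length(bv) < 2) stop("best single '", best, "' has < 2 replicates")
  conds <- setdiff(unique(plate$condition), best)
  rows <- lapply(conds, function(cd) {
    v <- plate$percent_positive[plate$condition == cd]
    p <- if (length(v) < 2) NA_real_ else twoSampleP(v, bv, varEqual)
    data.frame(condition = cd, fold = hits$fold[hits$condition == cd][1],
               best_single = best, p_vs_best = p,
               exceeds = !is.na(p) && p < alpha &&
                 mean(v) > mean(bv))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Agonist blunting calls
#'
#' A condition blunts the reference response when its mean percent-positive
#' is at most `threshold` times the reference condition's mean (default:
#' blunted by at least 50%).
#'
#' @param hits Hit table from [normalizeAndTest()].
#' @param reference Reference condition id (e.g. the pooled-knockdown
#'   positive control).
#' @param threshold Blunting threshold on the mean ratio, default 0.5.
#' @return Hit table with `ratio_to_reference` and `blunted` columns.
#' @export
bluntingCalls <- function(hits, reference, threshold = 0.5) {
  ref <- hits$mean[hits$condition == reference]
  if (!length(ref)) stop("reference condition not in table")
  hits$ratio_to_reference <- hits$mean / ref[1]
  hits$blunted <- hits$ratio_to_reference <= threshold &
    hits$condition != reference
  hits
}

#' Viability gate
#'
#' Flags conditions whose mean viable-cell count falls below `minFraction`
#' of the control's (default 0.7; the cutoff is an explicit, configurable
#' assumption).
#'
#' @param hits Hit table carrying a `viability` column
#'   (see [normalizeAndTest()] with a `cells` plate column).
#' @param minFraction Minimum viability relative to control.
#' @return Hit table with a logical `viable` column.
#' @export
viabilityGate <- function(hits, minFraction = 0.7) {
  if (!"viability" %in% names(hits))
    stop("hit table has no viability column (plate lacked cell counts?)")
  hits$viable <- hits$viability >= minFraction
  hits
}

## two-tailed unpaired t-test p-value, robust to zero-variance groups:
## identical groups give p = 1, constant-but-different groups give p = 0
twoSampleP <- function(x, y, varEqual = TRUE) {
  if (stats::sd(c(x, y)) == 0) return(1.0)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (mean(x) == mean(y)) 1.0 else 0.0)
  t.test(x, y, var.equal = varEqual)$p.value
}

#' Type-I error calibration of the screen t-test
#'
#' Simulates null screens — condition and control replicates drawn from the
#' same normal distribution — and reports the fraction rejected at `alpha`
#' by the equal-variance two-tailed t-test, with its Monte-Carlo standard
#' error. Under a correct test the rejection rate is `alpha`.
#'
#' @param nSim Number of simulated condition/control pairs.
#' @param n Replicates per group.
#' @param mu,sigma Null distribution parameters.
#' @param alpha Nominal level.
#' @param seed Integer seed.
#' @return List: `rate`, `se` (binomial Monte-Carlo SE), `nSim`.
#' @export
screenNullCalibration <- function(nSim = 10000, n = 4, mu = 6, sigma = 1,
                                  alpha = 0.05, seed = 1) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x <- matrix(rnorm(nSim * n, mu, sigma), nSim)
  y <- matrix(rnorm(nSim * n, mu, sigma), nSim)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- apply(x, 1, stats::var); vy <- apply(y, 1, stats::var)
  sp <- sqrt(((n - 1) * vx + (n - 1) * vy) / (2 * n - 2))
  tstat <- (mx - my) / (sp * sqrt(2 / n))
  p <- 2 * pt(-abs(tstat), df = 2 * n - 2)
  rate <- mean(p < alpha)
  list(rate = rate, se = sqrt(alpha * (1 - alpha) / nSim), nSim = nSim)
}

#' Simple fold change between two percentages
#'
#' @param a Baseline percent (> 0).
#' @param b Treated percent (> 0).
#' @return `b / a` — e.g. `foldChange(5, 16)` is 3.2.
#' @export
foldChange <- function(a, b) {
  if (any(c(a, b) <= 0)) stop("percentages must be positive")
  b / a
}

#' Relative expression by the 2^-ddCt method
#'
#' \deqn{2^{-((Ct_{target,treated} - Ct_{ref,treated}) -
#'           (Ct_{target,control} - Ct_{ref,control}))}}
#'
#' @param ctTargetTreated,ctRefTreated,ctTargetCtrl,ctRefCtrl Ct values.
#' @return Fold expression of the target in treated relative to control.
#' @export
#' @examples
#' ddctFold(20, 18, 22, 18)  # 4
ddctFold <- function(ctTargetTreated, ctRefTreated, ctTargetCtrl, ctRefCtrl) {
  ct <- c(ctTargetTreated, ctRefTreated, ctTargetCtrl, ctRefCtrl)
  if (any(!is.finite(ct)) || any(ct <= 0)) stop("Ct values must be positive")
  2^-((ctTargetTreated - ctRefTreated) - (ctTargetCtrl - ctRefCtrl))
}
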