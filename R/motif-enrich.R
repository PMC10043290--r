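#' Motif enrichment of target regions over a background
#'
#' Compares the fraction of target regions carrying at least one motif hit
#' (`f_t`) with the same fraction in a background set (`f_b`, typically
#' scrambled versions of the targets): `fold = f_t / f_b` and an upper-tail
#' binomial p-value \eqn{P(X \ge k_t \mid n_t, f_b)}. Hit densities in
#' hits/kb are reported for both sets. `f_b` is floored at
#' \eqn{1/(2 N_b + 1)} (flagged in the result) so the fold is always finite.
#'
#' @param target,background [scanMotif()] results for the same PWM and
#'   threshold.
#' @return A one-row data.frame: `motif`, `n_target`, `k_target`, `f_target`,
#'   `f_background`, `fold`, `p_value`, `density_target`,
#'   `density_background` (hits/kb), `f_background_floored`.
#' @export
motifEnrichment <- function(target, background) {
  stopifnot(inherits(target, "motifHits"), inherits(background, "motifHits"))
  if (target$motif != background$motif ||
      abs(target$threshold - background$threshold) > 1e-9)
    stop("target and background must be scanned with the same PWM/threshold")
  if (target$n_regions == 0) stop("zero target regions")
  if (background$n_regions == 0) stop("zero background regions")
  f_t <- target$n_regions_hit / target$n_regions
  f_b_raw <- background$n_regions_hit / background$n_regions
  floorv <- 1 / (2 * background$n_regions + 1)
  floored <- f_b_raw < floorv
  f_b <- max(f_b_raw, floorv)
  data.frame(motif = target$motif,
             n_target = target$n_regions,
             k_target = target$n_regions_hit,
             f_target = f_t,
             f_background = f_b,
             fold = f_t / f_b,
             p_value = pbinom(target$n_regions_hit - 1, target$n_regions,
                              f_b, lower.tail = FALSE),
             density_target = 1000 * nrow(target$hits) / target$total_bp,
             density_background = 1000 * nrow(background$hits) /
               background$total_bp,
             f_background_floored = floored)
}

#' Differential motif enrichment between two region sets
#'
#' For each PWM, scans both sequence sets and reports hit densities in
#' hits/kb, their ratio (set1/set2), and a two-proportion z-test p-value on
#' hit counts over scanned windows. Sorted by `|log2(ratio)|`, largest
#' first; motifs with zero hits in both sets get an `NA` ratio.
#'
#' @param seqs1,seqs2 Named sequence vectors (`DNAStringSet` or character).
#' @param pwms List of [PWMotif] (or a single one).
#' @param fpr Per-window false-positive rate for the score threshold.
#' @return data.frame: `motif`, `hits1`, `hits2`, `density1`, `density2`
#'   (hits/kb), `ratio`, `log2_ratio`, `p_value`.
#' @export
differentialMotifEnrichment <- function(seqs1, seqs2, pwms, fpr = 1e-4) {
  if (is(pwms, "PWMotif")) pwms <- list(pwms)
  if (!length(seqs1) || !length(seqs2)) stop("both region sets must be non-empty")
  rows <- lapply(pwms, function(pwm) {
    thr <- as.numeric(motifScoreThreshold(pwm, fpr))
    s1 <- scanMotif(seqs1, pwm, threshold = thr)
    s2 <- scanMotif(seqs2, pwm, threshold = thr)
    W <- motifWidth(pwm)
    win1 <- 2 * sum(pmax(0, nchar(as.character(seqs1)) - W + 1))
    win2 <- 2 * sum(pmax(0, nchar(as.character(seqs2)) - W + 1))
    d1 <- 1000 * nrow(s1$hits) / s1$total_bp
    d2 <- 1000 * nrow(s2$hits) / s2$total_bp
    ratio <- if (nrow(s1$hits) + nrow(s2$hits) == 0) NA_real_ else d1 / d2
    data.frame(motif = pwm@name, hits1 = nrow(s1$hits), hits2 = nrow(s2$hits),
               density1 = d1, density2 = d2, ratio = ratio,
               log2_ratio = log2(ratio),
               p_value = twoPropZ(nrow(s1$hits), win1, nrow(s2$hits), win2))
  })
  out <- do.call(rbind, rows)
  out[order(-abs(ifelse(is.na(out$log2_ratio), -Inf, out$log2_ratio))), ,
      drop = FALSE]
}
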