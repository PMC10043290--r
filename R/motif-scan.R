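## PWM scanning, the exact score-distribution threshold, and sequence
## shuffling. Scores are log-odds sums over the window; windows containing
## an N are skipped; both strands are scanned.

BASES <- c("A", "C", "G", "T")

## integer codes 1..4 for ACGT, 5L for anything else (N etc.)
seqCodes <- function(s) {
  v <- match(strsplit(toupper(as.character(s)), "")[[1]], BASES)
  v[is.na(v)] <- 5L
  v
}

## per-window log-odds scores of one coded sequence (one strand);
## rows with code 5 (N) poison their windows to -Inf
windowScores <- function(codes, L) {
  W <- ncol(L)
  n <- length(codes)
  if (n < W) return(numeric(0))
  Lx <- rbind(L, rep(-Inf, W))     # row 5 = N
  s <- numeric(n - W + 1)
  for (i in seq_len(W))
    s <- s + Lx[cbind(codes[i:(n - W + i)], i)]
  s
}

#' Per-window false-positive threshold for a PWM
#'
#' Computes the distribution of the log-odds score of a single window under
#' the background model by dynamic-programming convolution of the
#' discretized per-position scores (bin width `1/scale`), and returns the
#' smallest score whose upper-tail probability is at most `fpr`.
#'
#' @param pwm A [PWMotif].
#' @param fpr Target per-window (single strand) false-positive rate.
#' @param scale Discretization: scores are binned at `1/scale` resolution.
#' @return Numeric threshold with attributes `fpr` (attained upper-tail
#'   probability) and `distribution` (data.frame of score/probability).
#' @export
motifScoreThreshold <- function(pwm, fpr = 1e-4, scale = 1000) {
  L <- scoreMatrix(pwm)
  q <- pwm@background
  D <- round(L * scale)
  ## distribution of the discretized sum, tracked as (offset, vector)
  cur <- c(1)                            # P(sum = 0)
  curlo <- 0
  for (i in seq_len(ncol(D))) {
    vals <- D[, i]
    newlo <- curlo + min(vals)
    newhi <- curlo + length(cur) - 1 + max(vals)
    nxt <- numeric(newhi - newlo + 1)
    for (b in 1:4) {
      sh <- curlo + vals[b] - newlo
      idx <- seq_along(cur) + sh
      nxt[idx] <- nxt[idx] + cur * q[b]
    }
    cur <- nxt
    curlo <- newlo
  }
  scores <- (curlo + seq_along(cur) - 1) / scale
  keep <- cur > 0
  scores <- scores[keep]
  probs <- cur[keep]
  tail <- rev(cumsum(rev(probs)))       # P(S >= scores[i])
  ok <- which(tail <= fpr)
  ## back on the continuous scale, allow for the rounding error of the
  ## discretization (at most half a bin per position)
  err <- ncol(D) / (2 * scale)
  thr <- if (length(ok)) scores[ok[1]] - err else max(scores) + 1 / scale + err
  attained <- if (length(ok)) tail[ok[1]] else 0
  structure(thr, fpr = attained,
            distribution = data.frame(score = scores, probability = probs))
}

#' Scan sequences with a PWM
#'
#' Slides the motif over both strands of each sequence and records every
#' window whose log-odds score \eqn{\sum_i \log(p_i(b_i)/q(b_i))} reaches
#' the threshold. Offsets are 0-based positions of the window start on the
#' forward strand; minus-strand hits are found by scanning with the
#' reverse-complemented matrix. Windows containing `N` never score.
#'
#' @param seqs A named `DNAStringSet` (or named character vector) of region
#'   sequences.
#' @param pwm A [PWMotif].
#' @param threshold Log-odds score threshold; default chosen by
#'   [motifScoreThreshold()] at `fpr`.
#' @param fpr Per-window false-positive rate used when `threshold` is `NULL`.
#' @return A `motifHits` list: `hits` (data.frame `region`, `offset`,
#'   `strand`, `score`), `motif`, `threshold`, `n_regions`,
#'   `n_regions_hit`, `total_bp` scanned.
#' @export
#' @examples
#' ap1 <- pwmFromConsensus("TGACTCA", "AP-1")
#' scanMotif(c(r1 = "AATGACTCAGG"), ap1)$hits
scanMotif <- function(seqs, pwm, threshold = NULL, fpr = 1e-4) {
  if (motifWidth(pwm) < 1) stop("empty PWM")
  if (is.null(threshold)) threshold <- as.numeric(motifScoreThreshold(pwm, fpr))
  nm <- names(seqs)
  seqs <- setNames(as.character(seqs), nm)
  if (is.null(names(seqs))) names(seqs) <- paste0("region", seq_along(seqs))
  L <- scoreMatrix(pwm)
  Lrc <- L[4:1, rev(seq_len(ncol(L))), drop = FALSE]  # revcomp matrix
  rownames(Lrc) <- BASES
  res <- vector("list", length(seqs))
  for (k in seq_along(seqs)) {
    codes <- seqCodes(seqs[[k]])
    fw <- windowScores(codes, L)
    rv <- windowScores(codes, Lrc)
    i_f <- which(fw >= threshold)
    i_r <- which(rv >= threshold)
    if (length(i_f) + length(i_r))
      res[[k]] <- data.frame(region = names(seqs)[k],
                             offset = c(i_f, i_r) - 1L,
                             strand = rep(c("+", "-"),
                                          c(length(i_f), length(i_r))),
                             score = c(fw[i_f], rv[i_r]))
  }
  hits <- do.call(rbind, res)
  if (is.null(hits))
    hits <- data.frame(region = character(), offset = integer(),
                       strand = character(), score = numeric())
  structure(list(hits = hits, motif = pwm@name, threshold = threshold,
                 n_regions = length(seqs),
                 n_regions_hit = length(unique(hits$region)),
                 total_bp = sum(nchar(seqs))),
            class = "motifHits")
}

#' @export
print.motifHits <- function(x, ...) {
  cat(sprintf("%s: %d hits in %d/%d regions (%.0f bp, threshold %.2f)\n",
              x$motif, nrow(x$hits), x$n_regions_hit, x$n_regions,
              x$total_bp, x$threshold))
  invisible(x)
}

#' Scrambled background sequences
#'
#' Per-region shuffles preserving length and composition: `mononucleotide`
#' permutes the letters; `dinucleotide` (default, the usual "scrambled
#' background") preserves the dinucleotide multiset using the
#' Altschul–Erickson Eulerian-path shuffle. Regions shorter than 2 bp fall
#' back to mononucleotide mode with a notice. Deterministic given `seed`.
#'
#' @param seqs Named `DNAStringSet` or character vector.
#' @param mode `"dinucleotide"` or `"mononucleotide"`.
#' @param nShuffles Shuffles per region (>= 1).
#' @param seed Integer seed.
#' @return Named character vector of `length(seqs) * nShuffles` shuffled
#'   sequences (names suffixed `_shufK` when `nShuffles > 1`).
#' @export
scrambleSequences <- function(seqs, mode = c("dinucleotide", "mononucleotide"),
                              nShuffles = 1, seed = 1) {
  mode <- match.arg(mode)
  if (nShuffles < 1) stop("nShuffles must be >= 1")
  nm <- names(seqs)
  seqs <- setNames(as.character(seqs), nm)
  if (is.null(names(seqs))) names(seqs) <- paste0("region", seq_along(seqs))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  short <- 0L
  out <- character(0)
  for (r in seq_len(nShuffles)) {
    sh <- vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      if (mode == "dinucleotide" && length(ch) >= 2)
        paste(dinucShuffle(ch), collapse = "")
      else {
        if (mode == "dinucleotide") short <<- short + 1L
        paste(sample(ch), collapse = "")
      }
    }, character(1))
    names(sh) <- if (nShuffles > 1) paste0(names(seqs), "_shuf", r) else
      names(seqs)
    out <- c(out, sh)
  }
  if (short) message(short, " region(s) < 2 bp: mononucleotide fallback")
  out
}

## Altschul-Erickson dinucleotide-preserving shuffle of a character vector
dinucShuffle <- function(ch) {
  n <- length(ch)
  verts <- unique(ch)
  if (length(verts) == 1) return(ch)
  from <- ch[-n]
  to <- ch[-1]
  last <- ch[n]
  adj <- split(to, factor(from, levels = verts))
  nonlast <- setdiff(verts[lengths(adj) > 0], last)
  ## choose one terminal edge per non-last vertex so they form a tree
  ## rooted at `last` (walk must not cycle before reaching `last`)
  repeat {
    lastEdge <- vapply(nonlast, function(v) {
      e <- adj[[v]]
      e[sample.int(length(e), 1)]
    }, character(1))
    ok <- all(vapply(nonlast, function(v) {
      seen <- character(0)
      while (v != last) {
        if (v %in% seen || !(v %in% nonlast)) return(FALSE)
        seen <- c(seen, v)
        v <- lastEdge[[v]]
      }
      TRUE
    }, logical(1)))
    if (ok) break
  }
  ## shuffle the remaining edges, append the terminal edge
  for (v in verts) {
    e <- adj[[v]]
    if (!length(e)) next
    if (v %in% nonlast) {
      i <- match(lastEdge[[v]], e)
      e <- e[-i]
      adj[[v]] <- c(if (length(e)) e[sample.int(length(e))], lastEdge[[v]])
    } else {
      adj[[v]] <- e[sample.int(length(e))]
    }
  }
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- ch[1]
  v <- ch[1]
  for (i in 2:n) {
    nxt <- adj[[v]][ptr[[v]]]
    ptr[[v]] <- ptr[[v]] + 1L
    out[i] <- nxt
    v <- nxt
  }
  out
}

## extract region sequences from an in-memory genome (named DNAStringSet)
#' Extract region sequences from a genome
#'
#' @param genome Named `DNAStringSet` (one entry per chromosome) or path to
#'   a FASTA file.
#' @param gr `GRanges` of regions.
#' @return Named character vector of sequences (`chrom:start-end` 0-based
#'   names).
#' @export
regionSequences <- function(genome, gr) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- readDNAStringSet(genome)
  ## readDNAStringSet keeps full FASTA headers; use the first word
  names(genome) <- sub("\\s.*", "", names(genome))
  chrom <- as.character(seqnames(gr))
  bad <- setdiff(unique(chrom), names(genome))
  if (length(bad)) stop("chromosome(s) absent from genome: ",
                        paste(bad, collapse = ", "))
  out <- vapply(seq_along(gr), function(i)
    as.character(subseq(genome[[chrom[i]]], start(gr)[i], end(gr)[i])),
    character(1))
  names(out) <- sprintf("%s:%d-%d", chrom, start(gr) - 1L, end(gr))
  out
}
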