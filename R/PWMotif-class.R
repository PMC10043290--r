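#' PWMotif: a position probability matrix with background
#'
#' Holds a motif as a 4 x W position probability matrix (rows A, C, G, T)
#' together with the background nucleotide frequencies used for log-odds
#' scoring. Probabilities are strictly positive (smoothing with a
#' background-split pseudocount happens at construction), so log-odds scores
#' are always finite.
#'
#' @slot name Motif name.
#' @slot matrix 4 x W numeric matrix of column-normalized probabilities.
#' @slot background Named numeric of length 4 summing to 1.
#' @slot pseudocount Pseudocount used when the motif was built from counts.
#' @export
setClass("PWMotif",
         representation(name = "character", matrix = "matrix",
                        background = "numeric", pseudocount = "numeric"))

setValidity("PWMotif", function(object) {
  m <- object@matrix
  q <- object@background
  if (!identical(rownames(m), c("A", "C", "G", "T")))
    return("matrix rows must be A, C, G, T")
  if (ncol(m) < 1) return("motif width must be >= 1")
  if (any(m < 0)) return("probabilities must be non-negative")
  if (any(abs(colSums(m) - 1) > 1e-9))
    return("matrix columns must each sum to 1")
  if (length(q) != 4 || abs(sum(q) - 1) > 1e-9 || any(q <= 0))
    return("background must be 4 positive frequencies summing to 1")
  TRUE
})

#' @describeIn PWMotif-class Construct from a probability (or count) matrix.
#'   A count matrix (column sums > 1) is converted to probabilities with the
#'   pseudocount split by background, \eqn{p = (c + pc\,q_b)/(N + pc)}; a
#'   probability matrix containing zeros is smoothed the same way.
#' @param name Motif name.
#' @param matrix 4 x W matrix, rows A/C/G/T (counts or probabilities).
#' @param background Background frequencies (default uniform).
#' @param pseudocount Pseudocount (default 0.8, the JASPAR convention).
#' @export
PWMotif <- function(name, matrix, background = c(A = .25, C = .25,
                                                 G = .25, T = .25),
                    pseudocount = 0.8) {
  m <- as.matrix(matrix)
  if (is.null(rownames(m))) rownames(m) <- c("A", "C", "G", "T")
  m <- m[c("A", "C", "G", "T"), , drop = FALSE]
  background <- background / sum(background)
  names(background) <- c("A", "C", "G", "T")
  tot <- colSums(m)
  if (any(m < 0)) stop("negative matrix entries")
  if (any(tot == 0)) stop("empty matrix column")
  counts_like <- any(tot > 1 + 1e-6)
  if (counts_like || any(m == 0))
    m <- sweep(m + pseudocount * background, 2, tot + pseudocount, "/")
  else
    m <- sweep(m, 2, tot, "/")
  new("PWMotif", name = name, matrix = m, background = background,
      pseudocount = pseudocount)
}

#' @describeIn PWMotif-class Build a sharp PWM from a consensus string
#'   (e.g. the AP-1 element `"TGACTCA"`), putting probability `p` on the
#'   consensus base at each position.
#' @param consensus Consensus DNA string over A/C/G/T.
#' @param p Probability of the consensus base per position.
#' @export
pwmFromConsensus <- function(consensus, name = consensus, p = 0.85,
                             background = c(A = .25, C = .25,
                                            G = .25, T = .25)) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("consensus must be over A/C/G/T")
  m <- matrix((1 - p) / 3, nrow = 4, ncol = length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(bases, rownames(m)), seq_along(bases))] <- p
  PWMotif(name, m, background = background)
}

#' Read JASPAR-style plain-text PWMs
#'
#' Accepts the common 4-row JASPAR layouts: an optional `>ID NAME` header
#' followed by four rows, either `A [ 3 5 ... ]` or bare numbers in A/C/G/T
#' order. Count matrices are converted to probabilities with the
#' background-split pseudocount.
#'
#' @param path File with one or more matrices.
#' @param background,pseudocount Passed to [PWMotif()].
#' @return A named list of `PWMotif`.
#' @export
readJaspar <- function(path, background = c(A = .25, C = .25,
                                            G = .25, T = .25),
                       pseudocount = 0.8) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) starts <- 1L
  out <- list()
  for (k in seq_along(starts)) {
    i <- starts[k]
    j <- if (k < length(starts)) starts[k + 1] - 1L else length(lines)
    block <- lines[i:j]
    if (grepl("^>", block[1])) {
      hdr <- strsplit(sub("^>", "", block[1]), "\\s+")[[1]]
      nm <- hdr[length(hdr)]
      block <- block[-1]
    } else nm <- paste0("motif", k)
    rows <- lapply(block[1:4], function(l) {
      toks <- regmatches(l, gregexpr("-?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?",
                                     l))[[1]]
      as.numeric(toks)
    })
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    out[[nm]] <- PWMotif(nm, m, background = background,
                         pseudocount = pseudocount)
  }
  out
}

#' @describeIn PWMotif-class Motif width.
#' @param x A `PWMotif`.
#' @export
motifWidth <- function(x) ncol(x@matrix)

#' @describeIn PWMotif-class Log-odds score matrix `log(p/q)` (4 x W).
#' @export
scoreMatrix <- function(x) log(x@matrix / x@background)

setMethod("show", "PWMotif", function(object) {
  cat(sprintf("PWMotif '%s' (width %d)\n", object@name, motifWidth(object)))
  cat("consensus:", paste(rownames(object@matrix)[apply(object@matrix, 2,
                                                        which.max)],
                          collapse = ""), "\n")
  invisible(object)
})
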