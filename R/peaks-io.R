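#' Read peak files (BED3, BED6, ENCODE narrowPeak)
#'
#' Parses a tab-separated peak file into a sorted `GRanges`. Coordinates on
#' disk are 0-based half-open and are converted to the 1-based closed
#' convention of `GRanges`. Missing optional columns are filled with neutral
#' defaults (score 0, signal/p/q `NA`, summit unset). Lines staring with
#' `#`, `track` or `browser` are skipped.
#'
#' narrowPeak metadata columns follow the ENCODE names: `name`, `score`,
#' `signalValue`, `pValue` and `qValue` (both -log10), and `peak` (summit
#' offset from the region start, `-1` when unset).
#'
#' @param path Path to the file.
#' @param format One of `"narrowPeak"`, `"BED6"`, `"BED3"`. Default guesses
#'   from the extension (`.narrowPeak` vs anything else -> BED; BED column
#'   count is then taken from the file).
#' @return A sorted `GRanges` with narrowPeak metadata columns.
#' @export
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200", f)
#' readPeaks(f, "BED3")
readPeaks <- function(path, format = c("auto", "narrowPeak", "BED6", "BED3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (format == "auto")
    format <- if (grepl("\\.narrowPeak$", path)) "narrowPeak" else "BED6"
  need <- c(narrowPeak = 10L, BED6 = 4L, BED3 = 3L)[[format]]
  if (!length(lines))
    return(grFromBed(character(), integer(), integer(),
                     name = character(), score = numeric(),
                     signalValue = numeric(), pValue = numeric(),
                     qValue = numeric(), peak = integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (format == "narrowPeak" && any(nf < need))
    stop("line ", lineno[which(nf < need)[1]], ": expected >= ", need,
         " columns for format ", format)
  if (any(nf < 3L))
    stop("line ", lineno[which(nf < 3L)[1]], ": fewer than 3 columns")
  grab <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default,
           character(1))
  }
  chrom <- grab(1)
  start <- suppressWarnings(as.integer(grab(2)))
  end <- suppressWarnings(as.integer(grab(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("line ", lineno[bad[1]], ": non-integer coordinate")
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    stop("line ", lineno[bad[1]], ": invalid interval (need 0 <= start < end)")
  name <- grab(4)
  name[is.na(name) | name == "."] <- ""
  score <- suppressWarnings(as.numeric(grab(5)))
  score[is.na(score)] <- 0
  strand <- grab(6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "*"
  if (format == "narrowPeak") {
    signal <- suppressWarnings(as.numeric(grab(7)))
    pval <- suppressWarnings(as.numeric(grab(8)))
    qval <- suppressWarnings(as.numeric(grab(9)))
    summit <- suppressWarnings(as.integer(grab(10)))
    summit[is.na(summit)] <- -1L
    bad <- which(summit != -1L & (summit < 0L | summit >= end - start))
    if (length(bad))
      stop("line ", lineno[bad[1]], ": summit offset outside the peak")
  } else {
    signal <- pval <- qval <- rep(NA_real_, length(chrom))
    summit <- rep(-1L, length(chrom))
  }
  gr <- grFromBed(chrom, start, end, strand = strand,
                  name = name, score = score, signalValue = signal,
                  pValue = pval, qValue = qval, peak = summit)
  sortPeaks(gr)
}

#' Write a GRanges as BED or narrowPeak
#'
#' Writes 0-based half-open coordinates with a `#` provenance header line.
#'
#' @param gr A `GRanges` (narrowPeak metadata columns used when present).
#' @param path Output path.
#' @param format `"BED6"` (default) or `"narrowPeak"`.
#' @param header Provenance string placed after `#`; `NULL` for none.
#' @return `path`, invisibly.
#' @export
writePeaks <- function(gr, path, format = c("BED6", "narrowPeak"),
                       header = paste0("fatebarrier ", format(Sys.Date()))) {
  format <- match.arg(format)
  m <- S4Vectors::mcols(gr)
  pick <- function(col, default) {
    if (col %in% names(m)) {
      v <- m[[col]]
      v[is.na(v)] <- default
      v
    } else rep(default, length(gr))
  }
  name <- pick("name", ".")
  name[name == ""] <- "."
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = name, score = pick("score", 0),
                   strand = sub("\\*", ".", as.character(strand(gr))))
  if (format == "narrowPeak")
    df <- cbind(df,
                signalValue = pick("signalValue", 0),
                pValue = pick("pValue", -1),
                qValue = pick("qValue", -1),
                peak = pick("peak", -1L))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("#", header), con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
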