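#' Read a differential-expression table
#'
#' TSV with header columns `gene_id`, `log2fc`, `pvalue`, `padj` (extra
#' columns such as `baseMean` are kept). Input is trusted — `padj < pvalue`
#' rows are only logged, not dropped — but duplicated gene ids are an error.
#'
#' @param path Path to the TSV.
#' @return data.frame.
#' @export
readDeTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "pvalue", "padj")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing DE column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("duplicated gene_id in DE table")
  odd <- sum(!is.na(df$padj) & !is.na(df$pvalue) & df$padj < df$pvalue)
  if (odd) message(odd, " row(s) with padj < pvalue (kept as given)")
  df
}

#' Filter a DE table to significant genes
#'
#' Keeps genes with adjusted p strictly below `alpha` (Benjamini-Hochberg
#' adjusted p-values expected in `padj`) and `|log2fc| >= lfcMin`, and
#' annotates the direction. Genes with `log2fc == 0` are excluded with a
#' notice (no direction).
#'
#' @param de DE data.frame ([readDeTable()]).
#' @param alpha Adjusted-p cutoff (strict `<`), default 0.05.
#' @param lfcMin Minimum absolute log2 fold-change, default 0.
#' @return The DE subset with a `direction` column (`"down"`/`"up"`).
#' @export
filterDe <- function(de, alpha = 0.05, lfcMin = 0) {
  if (!"padj" %in% names(de)) stop("missing padj column")
  keep <- !is.na(de$padj) & de$padj < alpha & abs(de$log2fc) >= lfcMin
  zero <- keep & de$log2fc == 0
  if (any(zero)) {
    message(sum(zero), " significant gene(s) with log2fc = 0 excluded")
    keep <- keep & de$log2fc != 0
  }
  out <- de[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc < 0, "down", "up")
  rownames(out) <- NULL
  out
}

#' Integrate differential expression with promoter binding
#'
#' Crosses a filtered DE table with the per-gene promoter-binding flags from
#' [promoterBoundGenes()]: Venn counts of DE x bound, the down/up breakdown
#' among bound DE genes, and each factor's contribution (fraction of bound
#' DE genes whose core promoter carries that factor). Gene identifiers are
#' matched exactly after whitespace/case normalization; DE genes absent from
#' the binding table count as unbound (logged).
#'
#' @param de Filtered DE data.frame with `direction` (see [filterDe()]).
#' @param bound data.frame from [promoterBoundGenes()].
#' @return An `integrationResult` list: `n_de`, `n_de_down`, `n_de_up`,
#'   `n_bound_de`, `n_bound_down`, `n_bound_up`, `frac_bound`,
#'   `frac_down_among_bound`, `per_tf` (named fractions among bound DE
#'   genes), `bound_de` (the merged table).
#' @export
integrateDeBinding <- function(de, bound) {
  if (!nrow(de)) stop("zero DE genes")
  norm <- function(x) toupper(trimws(x))
  key_de <- norm(de$gene_id)
  key_b <- norm(bound$gene_id)
  idx <- match(key_de, key_b)
  unmatched <- sum(is.na(idx))
  if (unmatched)
    message(unmatched, " DE gene(s) absent from binding table (treated unbound)")
  tfs <- setdiff(names(bound), c("gene_id", "bound_any"))
  flags <- bound[idx, c(tfs, "bound_any"), drop = FALSE]
  flags[is.na(idx), ] <- FALSE
  merged <- cbind(de, flags)
  rownames(merged) <- NULL
  isb <- merged$bound_any
  n_de <- nrow(de)
  n_bound <- sum(isb)
  res <- list(n_de = n_de,
              n_de_down = sum(de$direction == "down"),
              n_de_up = sum(de$direction == "up"),
              n_bound_de = n_bound,
              n_bound_down = sum(isb & merged$direction == "down"),
              n_bound_up = sum(isb & merged$direction == "up"),
              frac_bound = n_bound / n_de,
              frac_down_among_bound = if (n_bound)
                sum(isb & merged$direction == "down") / n_bound else NA_real_,
              per_tf = vapply(tfs, function(tf)
                if (n_bound) sum(merged[[tf]][isb]) / n_bound else NA_real_,
                numeric(1)),
              bound_de = merged[isb, , drop = FALSE])
  structure(res, class = "integrationResult")
}

#' @export
print.integrationResult <- function(x, ...) {
  cat(sprintf("DE genes: %d (%d down, %d up)\n", x$n_de, x$n_de_down,
              x$n_de_up))
  cat(sprintf("bound at core promoter: %d (%.1f%%), %d down + %d up\n",
              x$n_bound_de, 100 * x$frac_bound, x$n_bound_down, x$n_bound_up))
  cat("per-factor contribution among bound DE genes:\n")
  print(round(x$per_tf, 3))
  invisible(x)
}

#' Select top-quantile candidate genes
#'
#' From the bound-and-DE subset, keeps the most extreme `quantile` fraction
#' in one direction — by default the top quartile ranked by log2
#' fold-change (most negative first for `"down"`), matching a
#' top-25-percentile candidate selection. Count is `ceiling(quantile * n)`;
#' ties at the cut break by smaller `padj`, then `gene_id`; the result is
#' invariant to input row order.
#'
#' @param genes data.frame with `gene_id`, `log2fc`, `padj` and `direction`.
#' @param direction `"down"` or `"up"`.
#' @param quantile Fraction to keep, in `(0, 1]`.
#' @param rankBy `"log2fc"` (default) or `"padj"`.
#' @return Ordered data.frame of selected genes (most extreme first).
#' @export
selectCandidates <- function(genes, direction = c("down", "up"),
                             quantile = 0.25, rankBy = c("log2fc", "padj")) {
  direction <- match.arg(direction)
  rankBy <- match.arg(rankBy)
  if (!is.numeric(quantile) || quantile <= 0 || quantile > 1)
    stop("quantile must be in (0, 1]")
  sub <- genes[genes$direction == direction, , drop = FALSE]
  if (!nrow(sub)) stop("no genes in direction '", direction, "'")
  key <- switch(rankBy,
                log2fc = if (direction == "down") sub$log2fc else -sub$log2fc,
                padj = sub$padj)
  ord <- order(key, sub$padj, sub$gene_id)
  k <- ceiling(quantile * nrow(sub))
  out <- sub[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}
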