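## small helper: fragments laid down with exact per-region counts
fragsFor <- function(regions, counts, barcode = "cellA") {
  ri <- rep(seq_along(regions), counts)
  g <- GRanges(seqnames(regions)[ri],
               IRanges(start(regions)[ri] + 5L, width = 20L))
  g$barcode <- barcode
  g
}

test_that("pseudobulk counts fragments per region and tracks depth", {
  regions <- grFromBed("chr1", 0, 1000)
  frags <- grFromBed("chr1", 100, 150, barcode = "cellA")
  mat <- pseudobulk(frags, c(cellA = "c1"), regions, list(g = "c1"))
  expect_s4_class(mat, "AccessibilityExperiment")
  expect_equal(unname(SummarizedExperiment::assay(mat, "counts")[1, 1]), 1L)
  expect_equal(unname(groupDepths(mat)), 1L)

  ## fragment outside all regions contributes to depth only
  frags2 <- c(frags, grFromBed("chr1", 5000, 5100, barcode = "cellA"))
  mat2 <- pseudobulk(frags2, c(cellA = "c1"), regions, list(g = "c1"))
  expect_equal(unname(SummarizedExperiment::assay(mat2, "counts")[1, 1]), 1L)
  expect_equal(unname(groupDepths(mat2)), 2L)

  expect_error(pseudobulk(frags, c(cellA = "c1"), regions,
                          list(g = "c1", h = "c9")), "has no cells")
  expect_error(pseudobulk(frags, c(cellA = "c1"), regions,
                          list(g = "c1", h = "c1")), "disjoint")
  expect_message(
    pseudobulk(c(frags, grFromBed("chr1", 1, 30, barcode = "ghost")),
               c(cellA = "c1"), regions, list(g = "c1")),
    "unlabeled")
})

test_that("pseudobulk counting is exact for planted per-region counts", {
  set.seed(61)
  regions <- grFromBed("chr1", seq(0, 99000, by = 1000),
                       seq(0, 99000, by = 1000) + 500)
  counts <- rpois(length(regions), 20)
  frags <- fragsFor(regions, counts)
  mat <- pseudobulk(frags, c(cellA = "c1"), regions, list(g = "c1"))
  expect_equal(unname(SummarizedExperiment::assay(mat, "counts")[, 1]),
               counts)
})

test_that("normalized signal is invariant under fragment duplication", {
  set.seed(62)
  regions <- grFromBed("chr1", seq(0, 49000, by = 1000),
                       seq(0, 49000, by = 1000) + 400)
  frags <- fragsFor(regions, rpois(length(regions), 15))
  m1 <- pseudobulk(frags, c(cellA = "c1"), regions, list(g = "c1"))
  m2 <- pseudobulk(c(frags, frags), c(cellA = "c1"), regions, list(g = "c1"))
  expect_equal(normalizedCounts(m1), normalizedCounts(m2))
})

test_that("callDomains enforces the open/closed pattern and significance", {
  regions <- grFromBed("chr1", c(0, 2000, 4000), c(1000, 3000, 5000))
  ## region 1: ref-open/tgt-closed; regions 2-3: open on both sides
  fr <- c(fragsFor(regions, c(500, 50, 50), "cellR"),
          fragsFor(regions, c(0, 500, 500), "cellT"))
  mat <- pseudobulk(fr, c(cellR = "cr", cellT = "ct"), regions,
                    list(ref = "cr", tgt = "ct"))
  calls <- callDomains(mat, "ref", "tgt", tauOpen = 5000, tauClosed = 1000)
  expect_equal(calls$calls$class[1], "domain1")
  expect_true(all(is.na(calls$calls$class[2:3])))
  expect_equal(length(calls$domain2), 0)
  expect_error(callDomains(mat, "ref", "tgt", tauOpen = 1, tauClosed = 5),
               "tauClosed")
  expect_error(callDomains(mat, "ref", "nope"), "unknown group")
})

test_that("domain calling is antisymmetric under group swap", {
  fr <- simFragments(c(chr1 = 3e5), cells = c(c1 = 150, c2 = 80),
                     tgtClusters = "c2", nRegions = 120,
                     domain1SpanBp = 12000, domain2SpanBp = 8000, seed = 63)
  mat <- pseudobulk(fr$frags, fr$clusters, fr$regions,
                    list(ref = "c1", tgt = "c2"))
  fwd <- callDomains(mat, "ref", "tgt")
  rev <- callDomains(mat, "tgt", "ref")
  expect_identical(granges(fwd$domain1), granges(rev$domain2))
  expect_identical(granges(fwd$domain2), granges(rev$domain1))
  expect_equal(fwd$calls$p_value, rev$calls$p_value)
})

test_that("planted domains are recovered: span within 5%, Jaccard >= 0.95", {
  fr <- simFragments(c(chr1 = 1e6, chr2 = 1e6), seed = 64)
  mat <- pseudobulk(fr$frags, fr$clusters, fr$regions,
                    list(ref = paste0("c", c(1, 3:7)), tgt = "c2"))
  calls <- callDomains(mat, "ref", "tgt")
  expect_equal(sum(width(calls$domain1)), fr$truth$domain1_span,
               tolerance = 0.05)
  expect_equal(sum(width(calls$domain2)), fr$truth$domain2_span,
               tolerance = 0.05)
  expect_gte(jaccardBp(calls$domain1, fr$truth$domain1), 0.95)
  expect_gte(jaccardBp(calls$domain2, fr$truth$domain2), 0.95)
})

test_that("no planted contrast yields (almost) no calls", {
  fr <- simFragments(c(chr1 = 5e5), cells = c(c1 = 200, c2 = 100),
                     tgtClusters = "c2", nRegions = 200,
                     domain1SpanBp = 0, domain2SpanBp = 0, seed = 65)
  mat <- pseudobulk(fr$frags, fr$clusters, fr$regions,
                    list(ref = "c1", tgt = "c2"))
  calls <- callDomains(mat, "ref", "tgt")
  frac <- (length(calls$domain1) + length(calls$domain2)) / 200
  expect_lte(frac, 0.05)
})

test_that("domainSummary reports spans, histograms and chromosome counts", {
  mk <- function(d1, d2) structure(list(domain1 = d1, domain2 = d2),
                                   class = "domainCalls")
  calls <- mk(grFromBed("chr1", c(0, 1000), c(600, 1400)), GRanges())
  ds <- domainSummary(calls)
  expect_equal(ds$summary$span_bp, c(1000, 0))
  expect_equal(ds$summary$n, c(2L, 0L))
  expect_equal(unname(ds$histogram["domain1", "[600,800)"]), 1L)
  expect_equal(unname(ds$histogram["domain1", "[400,600)"]), 1L)
  expect_equal(unname(ds$per_chromosome[, "domain1"]), 2L)

  empty <- domainSummary(mk(GRanges(), GRanges()))
  expect_equal(empty$summary$span_bp, c(0, 0))

  ## planted width distribution: 90% of regions below 600 bp
  fr <- simFragments(c(chr1 = 1e6), cells = c(c1 = 50, c2 = 30),
                     tgtClusters = "c2", nRegions = 500,
                     domain1SpanBp = 1, domain2SpanBp = 1, seed = 66)
  w <- width(fr$regions)
  expect_equal(mean(w < 600), 0.9, tolerance = 0.03 / 0.9)
})

test_that("binding density in domains is peaks per Mbp of class span", {
  calls <- structure(list(domain1 = grFromBed("chr1", 0, 1000),
                          domain2 = GRanges()),
                     class = "domainCalls")
  dens <- bindingDensityInDomains(calls, list(TF = grFromBed("chr1", 100, 300)))
  d1 <- dens[dens$class == "domain1", ]
  expect_equal(d1$n_peaks, 1L)
  expect_equal(d1$density_per_mbp, 1000)
  expect_true(is.na(dens$density_per_mbp[dens$class == "domain2"]))

  far <- bindingDensityInDomains(calls, list(TF = grFromBed("chr2", 0, 100)))
  expect_equal(far$n_peaks[far$class == "domain1"], 0L)
})

test_that("TSS differential accessibility matches a two-proportion oracle", {
  regions <- grFromBed("chr1", c(0, 2000), c(1000, 3000),
                       gene_id = c("gA", "gB"))
  fr <- c(fragsFor(regions, c(0, 500), "cellR"),
          fragsFor(regions, c(100, 500), "cellT"))
  ## pad depths so the proportions are 0/10000-ish vs 100/10000-ish
  pad <- grFromBed("chr1", rep(9e5, 9400), rep(9e5 + 50, 9400))
  pad$barcode <- rep(c("cellR", "cellT"), length.out = 9400)
  mat <- pseudobulk(c(fr, pad), c(cellR = "cr", cellT = "ct"), regions,
                    list(ref = "cr", tgt = "ct"))
  res <- tssDifferentialAccessibility(mat, "ref", "tgt")
  gA <- res[res$gene_id == "gA", ]
  expect_true(gA$called)
  expect_equal(gA$direction, "more accessible in target")
  ## oracle: prop.test on the same counts
  nr <- sum(groupDepths(mat)["ref"])
  nt <- sum(groupDepths(mat)["tgt"])
  oracle <- prop.test(c(gA$count_ref, gA$count_tgt), c(nr, nt),
                      correct = FALSE)$p.value
  expect_equal(gA$p_value, oracle, tolerance = 1e-8)
  gB <- res[res$gene_id == "gB", ]
  expect_gt(gB$p_value, 0.3)

  ## duplicate gene ids are pooled
  regions2 <- grFromBed("chr1", c(0, 2000), c(1000, 3000),
                        gene_id = c("gA", "gA"))
  fr2 <- fragsFor(regions2, c(3, 4), "cellR")
  mat2 <- pseudobulk(c(fr2, pad), c(cellR = "cr", cellT = "ct"), regions2,
                     list(ref = "cr", tgt = "ct"))
  res2 <- tssDifferentialAccessibility(mat2, "ref", "tgt")
  expect_equal(nrow(res2), 1)
  expect_equal(res2$count_ref, 7L)
})

test_that("planted differentially accessible genes are recovered", {
  set.seed(67)
  nG <- 500
  regions <- grFromBed("chr1", seq(0, by = 2000, length.out = nG),
                       seq(0, by = 2000, length.out = nG) + 1000,
                       gene_id = sprintf("g%03d", seq_len(nG)))
  da <- sort(sample(nG, 50))
  lamR <- rep(20, nG)
  lamT <- rep(20, nG)
  lamT[da] <- 200
  ## pad the reference depth outside the regions so total depths match and
  ## the two-proportion test sees the per-gene contrast only
  pad <- grFromBed("chr1", rep(1.5e6, 9000), rep(1.5e6 + 50, 9000),
                   barcode = "cellR")
  fr <- c(fragsFor(regions, rpois(nG, lamR), "cellR"),
          fragsFor(regions, rpois(nG, lamT), "cellT"), pad)
  mat <- pseudobulk(fr, c(cellR = "cr", cellT = "ct"), regions,
                    list(ref = "cr", tgt = "ct"))
  res <- tssDifferentialAccessibility(mat, "ref", "tgt")
  hits <- res$gene_id[res$called]
  planted <- sprintf("g%03d", da)
  expect_gte(sum(hits %in% planted), 45)
  expect_lte(sum(!hits %in% planted), 0.05 * length(hits))
})
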