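test_that("readPeaks parses BED3/BED6/narrowPeak with neutral defaults", {
  f <- tempfile(fileext = ".bed")

  writeLines(character(0), f)
  expect_length(readPeaks(f, "BED3"), 0)

  writeLines("chr1\t100\t200", f)
  gr <- readPeaks(f, "BED3")
  expect_length(gr, 1)
  expect_equal(width(gr), 100)
  expect_equal(start(gr), 101)   # 0-based on disk, 1-based in memory
  expect_equal(gr$score, 0)
  expect_equal(gr$peak, -1L)

  np <- tempfile(fileext = ".narrowPeak")
  writeLines(c("#header",
               "chr2\t500\t900\tpeakA\t310\t+\t7.25\t12.5\t10.1\t50",
               "chr1\t0\t150\tpeakB\t100\t.\t3.5\t6.2\t4.4\t75"), np)
  gr <- readPeaks(np)
  expect_length(gr, 2)
  ## sorted: chr1 first
  expect_equal(as.character(seqnames(gr)), c("chr1", "chr2"))
  a <- gr[gr$name == "peakA"]
  expect_equal(start(a), 501)
  expect_equal(end(a), 900)
  expect_equal(a$signalValue, 7.25)
  expect_equal(a$pValue, 12.5)
  expect_equal(a$qValue, 10.1)
  expect_equal(a$peak, 50L)
  expect_equal(as.character(strand(a)), "+")
})

test_that("readPeaks rejects malformed records with the line number", {
  f <- tempfile()
  writeLines(c("chr1\t10\t20", "chr1\tabc\t30"), f)
  expect_error(readPeaks(f, "BED3"), "line 2.*non-integer")
  writeLines(c("chr1\t50\t50"), f)
  expect_error(readPeaks(f, "BED3"), "line 1.*start < end")
  writeLines("chr1\t10\t20", f)
  expect_error(readPeaks(f, "narrowPeak"), "expected >= 10")
  expect_error(readPeaks(f, "BEDX"), "arg")
})

test_that("mergePeaks unions overlapping/abutting/gapped intervals", {
  expect_equal(bedFrame(mergePeaks(grFromBed("chr1", c(0, 5), c(10, 15)))),
               data.frame(chrom = "chr1", start = 0, end = 15))
  two <- mergePeaks(grFromBed("chr1", c(0, 20), c(10, 30)))
  expect_length(two, 2)
  ## gap semantics: 10 bp apart merges at gap >= 10
  expect_length(mergePeaks(grFromBed("chr1", c(0, 20), c(10, 30)), gap = 9), 2)
  expect_length(mergePeaks(grFromBed("chr1", c(0, 20), c(10, 30)), gap = 10), 1)
  expect_error(mergePeaks(GRanges(), gap = -1), "non-negative")
})

test_that("mergePeaks matches a per-bp boolean-mask oracle on random input", {
  for (seed in 1:3) {
    gr <- randIntervals(1000, L = 1e5, seed = seed)
    gap <- c(0, 0, 25)[seed]
    got <- bedFrame(mergePeaks(gr, gap = gap))
    ora <- maskMerge(start(gr) - 1L, end(gr), gap = gap)
    expect_equal(got$start, ora$start0)
    expect_equal(got$end, ora$end0)
  }
})

test_that("merge is idempotent and order-invariant, span never grows", {
  gr <- randIntervals(500, seed = 42)
  m1 <- mergePeaks(gr)
  expect_identical(granges(mergePeaks(m1)), granges(m1))
  set.seed(1)
  m2 <- mergePeaks(gr[sample(length(gr))])
  expect_identical(granges(m2), granges(m1))
  expect_lte(sum(width(m1)), sum(width(gr)))
})

test_that("consolidateReplicates supports union-merge and intersection", {
  reps <- list(grFromBed("chr1", 0, 10), grFromBed("chr1", 5, 15))
  expect_equal(bedFrame(consolidateReplicates(reps)),
               data.frame(chrom = "chr1", start = 0, end = 15))
  expect_equal(bedFrame(consolidateReplicates(reps, "intersection")),
               data.frame(chrom = "chr1", start = 5, end = 10))
  expect_error(consolidateReplicates(list()), "non-empty")

  ## union span >= intersection span on random replicates
  r1 <- randIntervals(300, seed = 7)
  r2 <- randIntervals(300, seed = 8)
  u <- consolidateReplicates(list(r1, r2))
  i <- consolidateReplicates(list(r1, r2), "intersection")
  expect_gte(sum(width(u)), sum(width(i)))
})

test_that("replicate intersection recovers the planted reproducibility", {
  n <- 2000
  pk <- simPeaks(c(chr1 = 1e7, chr2 = 1e7),
                 data.frame(tf = "T1", n = n, open_fraction = 0.5),
                 reproducibility = 0.7, seed = 99)
  reps <- pk$replicates$T1
  inter <- consolidateReplicates(reps, "intersection")
  ## peaks present in both replicates ~ Binomial(n, 0.7); merged regions can
  ## fuse or split a handful, so allow a generous band around 0.7 n
  expect_gt(length(inter), 0.7 * n - 150)
  expect_lt(length(inter), 0.7 * n + 150)
  expect_equal(length(consolidateReplicates(reps)), length(pk$peaks$T1),
               tolerance = 0.02)
})

test_that("intersectPeaks reports overlap, best partner and honors thresholds", {
  a <- grFromBed("chr1", 100, 200)
  b <- grFromBed("chr1", 150, 160)
  rep1 <- intersectPeaks(a, b)
  expect_true(rep1$overlapped)
  expect_equal(rep1$overlap_bp, 10L)
  expect_equal(rep1$partner, 1L)

  expect_false(intersectPeaks(a, grFromBed("chr2", 100, 200))$overlapped)
  ## fractional threshold: 10/100 = 0.1 of the a record
  expect_false(intersectPeaks(a, b, minOverlapFrac = 0.2)$overlapped)
  expect_true(intersectPeaks(a, b, minOverlapFrac = 0.1)$overlapped)
  expect_error(intersectPeaks(a, b, minOverlapBp = 0), "minOverlapBp")
  expect_error(intersectPeaks(a, b, minOverlapFrac = 2), "minOverlapFrac")
})

test_that("intersectPeaks agrees with the quadratic all-pairs oracle", {
  a <- randIntervals(400, L = 5e4, seed = 11)
  b <- randIntervals(400, L = 5e4, seed = 12)
  for (pars in list(c(1, 0), c(50, 0), c(1, 0.5))) {
    got <- intersectPeaks(a, b, minOverlapBp = pars[1],
                          minOverlapFrac = pars[2])
    ora <- quadIntersect(a, b, minBp = pars[1], minFrac = pars[2])
    expect_equal(got$overlapped, ora$overlapped)
    expect_equal(got$overlap_bp, ora$overlap_bp)
    expect_equal(got$partner, ora$partner)
  }
})

test_that("writePeaks round-trips through readPeaks", {
  gr <- grFromBed("chr1", c(0, 500), c(300, 900), strand = c("+", "*"),
                  name = c("p1", "p2"), score = c(10, 20),
                  signalValue = c(1.5, 2.5), pValue = c(3, 4),
                  qValue = c(2, 3), peak = c(100L, -1L))
  f <- tempfile(fileext = ".narrowPeak")
  writePeaks(gr, f, format = "narrowPeak")
  expect_true(startsWith(readLines(f, 1), "#"))
  back <- readPeaks(f)
  expect_equal(bedFrame(back, mcols = FALSE), bedFrame(gr, mcols = FALSE))
  expect_equal(back$peak, gr$peak)
  expect_equal(back$name, gr$name)
})
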