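ap1 <- pwmFromConsensus("TGACTCA", "AP-1")

test_that("PWMotif validates probabilities and backgrounds", {
  expect_equal(motifWidth(ap1), 7)
  expect_true(all(abs(colSums(ap1@matrix) - 1) < 1e-12))
  expect_error(pwmFromConsensus("TGACXCA"), "A/C/G/T")
  ## count matrices are converted with the background-split pseudocount
  cm <- matrix(c(10, 0, 0, 0), 4, 3, dimnames = list(c("A", "C", "G", "T")))
  pwm <- PWMotif("polyA", cm)
  expect_true(all(pwm@matrix > 0))
  expect_equal(unname(pwm@matrix["A", 1]), (10 + 0.8 * 0.25) / 10.8)
})

test_that("readJaspar parses bracketed count rows", {
  f <- tempfile(fileext = ".jaspar")
  writeLines(c(">MA0000.1 TESTMOTIF",
               "A [ 10  0  2 ]",
               "C [  0 12  3 ]",
               "G [  1  0  4 ]",
               "T [  1  0  3 ]"), f)
  pwms <- readJaspar(f)
  expect_named(pwms, "TESTMOTIF")
  expect_equal(motifWidth(pwms[[1]]), 3)
  expect_true(all(abs(colSums(pwms[[1]]@matrix) - 1) < 1e-12))
  ## column 1 dominated by A
  expect_equal(unname(which.max(pwms[[1]]@matrix[, 1])), 1L)
})

test_that("scanning finds consensus hits on both strands, skips N windows", {
  h <- scanMotif(c(r1 = "AATGACTCAGG"), ap1)
  expect_equal(nrow(h$hits), 1)
  expect_equal(h$hits$offset, 2L)
  expect_equal(h$hits$strand, "+")

  h <- scanMotif(c(r1 = "AATGAGTCAGG"), ap1)   # contains revcomp TGACTCA
  expect_equal(h$hits$strand, "-")
  expect_equal(h$hits$offset, 2L)

  expect_equal(nrow(scanMotif(c(r1 = "AATGACNCAGG"), ap1)$hits), 0)
  expect_equal(nrow(scanMotif(c(short = "TGAC"), ap1)$hits), 0)
  expect_error(scanMotif(c(r1 = "ACGT"), structure(list(), class = "x")))
})

test_that("scanning is strand-complement symmetric", {
  set.seed(13)
  seqs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("s", 1:20)
  rc <- vapply(seqs, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1))
  expect_equal(nrow(scanMotif(seqs, ap1)$hits),
               nrow(scanMotif(rc, ap1)$hits))
})

test_that("the default threshold admits only exact consensus matches", {
  ## independent oracle: exact string counts on both strands via Biostrings
  set.seed(14)
  s <- paste(sample(c("A", "C", "G", "T"), 1e5, TRUE), collapse = "")
  hits <- scanMotif(c(r = s), ap1)
  dna <- Biostrings::DNAString(s)
  oracle <- Biostrings::countPattern("TGACTCA", dna) +
    Biostrings::countPattern("TGAGTCA", dna)     # revcomp of TGACTCA
  expect_equal(nrow(hits$hits), oracle)
})

test_that("observed hit rate matches the exact score-distribution rate", {
  thr <- motifScoreThreshold(ap1, fpr = 1e-4)
  fpr <- attr(thr, "fpr")
  expect_lte(fpr, 1e-4)
  L <- 2e5
  set.seed(15)
  s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  n <- nrow(scanMotif(c(r = s), ap1, threshold = as.numeric(thr))$hits)
  lambda <- 2 * (L - 6) * fpr
  ## Poisson band (4 sd)
  expect_gte(n, lambda - 4 * sqrt(lambda))
  expect_lte(n, lambda + 4 * sqrt(lambda))
  ## the tail distribution itself sums to 1
  d <- attr(thr, "distribution")
  expect_equal(sum(d$probability), 1, tolerance = 1e-9)
})

test_that("scrambling preserves composition and is seed-deterministic", {
  expect_equal(unname(scrambleSequences(c(a = "AAAA"), seed = 1)), "AAAA")

  set.seed(16)
  seqs <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T", "N"),
                 sample(20:80, 1), TRUE), collapse = ""), character(1))
  names(seqs) <- paste0("s", 1:10)
  dinucs <- function(x) {
    ch <- strsplit(x, "")[[1]]
    sort(paste0(ch[-length(ch)], ch[-1]))
  }
  sh <- scrambleSequences(seqs, "dinucleotide", seed = 99)
  for (i in seq_along(seqs)) {
    expect_equal(dinucs(sh[[i]]), dinucs(seqs[[i]]))
    expect_equal(nchar(sh[[i]]), nchar(seqs[[i]]))
  }
  expect_identical(sh, scrambleSequences(seqs, "dinucleotide", seed = 99))
  expect_false(identical(sh, scrambleSequences(seqs, "dinucleotide",
                                               seed = 100)))

  mono <- scrambleSequences(seqs, "mononucleotide", seed = 1)
  comp <- function(x) sort(strsplit(x, "")[[1]])
  for (i in seq_along(seqs))
    expect_equal(comp(mono[[i]]), comp(seqs[[i]]))

  expect_message(scrambleSequences(c(a = "A"), "dinucleotide", seed = 1),
                 "fallback")
})

test_that("enrichment matches the exact binomial oracle", {
  tgt <- simMotifRegions(100, len = 200, fracWithMotif = 0.5, seed = 51)
  bg <- simMotifRegions(400, len = 200, fracWithMotif = 0.125, seed = 52)
  thr <- as.numeric(motifScoreThreshold(ap1))
  e <- motifEnrichment(scanMotif(tgt, ap1, thr), scanMotif(bg, ap1, thr))
  expect_equal(e$f_target, 0.5)
  expect_equal(e$f_background, 0.125)
  expect_equal(e$fold, 4)
  expect_equal(e$p_value, sum(dbinom(50:100, 100, 0.125)))

  ## identical target and background: fold 1, unremarkable p
  e1 <- motifEnrichment(scanMotif(tgt, ap1, thr), scanMotif(tgt, ap1, thr))
  expect_equal(e1$fold, 1)
  expect_gt(e1$p_value, 0.3)

  expect_error(motifEnrichment(scanMotif(tgt, ap1, thr),
                               scanMotif(bg, ap1, thr + 1)), "same PWM")
})

test_that("planted 80% vs 10% motif regions give ~8-fold enrichment", {
  tgt <- simMotifRegions(500, len = 300, fracWithMotif = 0.8, seed = 53)
  bg <- simMotifRegions(500, len = 300, fracWithMotif = 0.1, seed = 54)
  thr <- as.numeric(motifScoreThreshold(ap1))
  e <- motifEnrichment(scanMotif(tgt, ap1, thr), scanMotif(bg, ap1, thr))
  expect_equal(e$fold, 8, tolerance = 0.10)
  expect_lt(e$p_value, 1e-50)
})

test_that("differential enrichment reports densities in hits/kb", {
  ## 10 planted instances over 5 x 1000 bp -> density 2/kb
  seqs1 <- simMotifRegions(5, len = 1000, fracWithMotif = 0, seed = 55)
  for (i in 1:5) for (off in c(100, 500)) {
    substr(seqs1[i], off, off + 6) <- "TGACTCA"
  }
  seqs2 <- simMotifRegions(5, len = 1000, fracWithMotif = 0, seed = 56)
  d <- differentialMotifEnrichment(seqs1, seqs2, ap1)
  expect_equal(d$density1, 2)
  expect_equal(d$density2, 0)
  expect_equal(d$hits1, 10)

  ## identical sets: ratio exactly 1 (or NA when no hits at all)
  d2 <- differentialMotifEnrichment(seqs1, seqs1, ap1)
  expect_equal(d2$ratio, 1)
  d3 <- differentialMotifEnrichment(seqs2, seqs2, ap1)
  expect_true(is.na(d3$ratio))
})

test_that("planted density contrast is recovered within 15%", {
  g <- simGenome(nChrom = 1, chromLength = 3e5, nGenes = 5, seed = 57)
  set1 <- grFromBed("chr1", seq(1000, 95000, by = 2000),
                    seq(1000, 95000, by = 2000) + 1000)
  set2 <- grFromBed("chr1", seq(150000, 244000, by = 2000),
                    seq(150000, 244000, by = 2000) + 1000)
  gm <- plantMotif(g$genome, set1, "TGACTCA", 1.0, seed = 58)$genome
  gm <- plantMotif(gm, set2, "TGACTCA", 0.25, seed = 59)$genome
  d <- differentialMotifEnrichment(regionSequences(gm, set1),
                                   regionSequences(gm, set2), ap1)
  expect_equal(d$density1, 1.0, tolerance = 0.15)
  expect_equal(d$density2, 0.25, tolerance = 0.15)
  expect_equal(d$ratio, 4.0, tolerance = 0.15)
})
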