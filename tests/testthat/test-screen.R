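mkPlate <- function(conds, values, cells = NULL) {
  n <- length(values[[1]])
  out <- do.call(rbind, lapply(seq_along(conds), function(i)
    data.frame(condition = conds[i], replicate = seq_len(n),
               percent_positive = values[[i]])))
  if (!is.null(cells)) out$cells <- rep(unlist(cells), each = n)[seq_len(nrow(out))]
  out
}

test_that("normalizeAndTest folds to control and t-tests raw replicates", {
  plate <- mkPlate(c("siControl", "same", "up"),
                   list(c(6, 7, 5, 6), c(6, 7, 5, 6), c(35, 36, 37, 36)))
  h <- normalizeAndTest(plate)
  expect_equal(h$fold[h$condition == "siControl"], 1)
  expect_equal(h$p_value[h$condition == "siControl"], 1)
  expect_equal(h$fold[h$condition == "same"], 1)
  expect_equal(h$p_value[h$condition == "same"], 1)   # identical replicates
  expect_equal(h$fold[h$condition == "up"], 6, tolerance = 0.01)
  ## oracle: equal-variance t-test on the raw values
  p_oracle <- t.test(c(35, 36, 37, 36), c(6, 7, 5, 6),
                     var.equal = TRUE)$p.value
  expect_equal(h$p_value[h$condition == "up"], p_oracle)

  single <- rbind(plate, data.frame(condition = "solo", replicate = 1,
                                    percent_positive = 12))
  hs <- normalizeAndTest(single)
  expect_true(is.na(hs$p_value[hs$condition == "solo"]))
  expect_equal(hs$fold[hs$condition == "solo"], 2)

  expect_error(normalizeAndTest(plate, control = "nope"), "control")
  zero <- mkPlate("siControl", list(c(0, 0, 0, 0)))
  expect_error(normalizeAndTest(zero), "zero")
})

test_that("callHits applies strict fold and p thresholds", {
  h <- data.frame(condition = c("a", "b", "c"),
                  fold = c(1.30, 1.25, 2.0),
                  p_value = c(0.01, 0.001, 0.2))
  out <- callHits(h)
  expect_equal(out$hit, c(TRUE, FALSE, FALSE))
  ## decrease direction
  hd <- data.frame(condition = "d", fold = 0.5, p_value = 0.01)
  expect_true(callHits(hd, direction = "decrease")$hit)

  ## row-by-row oracle on a toy table
  set.seed(81)
  toy <- data.frame(condition = sprintf("c%02d", 1:10),
                    fold = runif(10, 0.9, 1.8),
                    p_value = runif(10, 0, 0.2))
  got <- callHits(toy)$hit
  oracle <- vapply(seq_len(10), function(i)
    toy$fold[i] > 1.25 && toy$p_value[i] < 0.05, logical(1))
  expect_equal(got, oracle)
})

test_that("hit calling is monotone in its thresholds", {
  set.seed(82)
  h <- data.frame(condition = sprintf("c%03d", 1:200),
                  fold = runif(200, 0.8, 2),
                  p_value = runif(200, 0, 0.3))
  base <- callHits(h)$hit
  expect_true(all(callHits(h, foldMin = 1.5)$hit <= base))
  expect_true(all(callHits(h, alpha = 0.01)$hit <= base))
})

test_that("enumerateCombinations is complete, ordered, and guarded", {
  expect_length(enumerateCombinations(sprintf("si%d", 1:8)), 255)
  for (n in c(1, 5, 12))
    expect_length(enumerateCombinations(sprintf("x%02d", seq_len(n))),
                  2^n - 1)
  combs <- enumerateCombinations(c("b", "a", "c"))
  expect_equal(combs, list("a", "b", "c", c("a", "b"), c("a", "c"),
                           c("b", "c"), c("a", "b", "c")))
  expect_length(enumerateCombinations(letters[1:4], minSize = 2), 11)
  expect_error(enumerateCombinations(sprintf("x%d", 1:21)), "20")
})

test_that("compareToBestSingle flags combinations beating the best single", {
  plate <- mkPlate(c("siControl", "siA", "siB", "siA+siB", "siSame"),
                   list(c(6, 6, 6, 6), c(24, 25, 23, 24), c(12, 13, 11, 12),
                        c(36, 35, 37, 36), c(24, 25, 23, 24)))
  h <- normalizeAndTest(plate)
  cmp <- compareToBestSingle(plate, h, singles = c("siA", "siB"))
  expect_equal(cmp$best_single[1], "siA")
  expect_true(cmp$exceeds[cmp$condition == "siA+siB"])
  expect_false(cmp$exceeds[cmp$condition == "siSame"])
  expect_equal(cmp$p_vs_best[cmp$condition == "siSame"], 1)
  ## oracle for the flagged combination
  p_oracle <- t.test(c(36, 35, 37, 36), c(24, 25, 23, 24),
                     var.equal = TRUE)$p.value
  expect_equal(cmp$p_vs_best[cmp$condition == "siA+siB"], p_oracle)
})

test_that("planted super-combinations are the only ones flagged", {
  ds <- simDeScreen(seed = 83)
  ch <- normalizeAndTest(ds$comboPlate)
  singles <- c("siAtf7ip", "siJunb", "siSp7", "siZnf207",
               "siS5", "siS6", "siS7", "siS8")
  cmp <- compareToBestSingle(ds$comboPlate, ch, singles)
  flagged <- cmp$condition[cmp$exceeds & grepl("\\+", cmp$condition)]
  expect_setequal(flagged, ds$truth$super_combos)
})

test_that("blunting and viability gates work and recount by oracle", {
  h <- data.frame(condition = c("ref", "a", "b"), n = 4,
                  mean = c(40, 18, 25), fold = 1, p_value = 0.5,
                  viability = c(1, 0.3, 0.9))
  b <- bluntingCalls(h, "ref")
  expect_equal(b$blunted, c(FALSE, TRUE, FALSE))
  v <- viabilityGate(b)
  expect_equal(v$viable, c(TRUE, FALSE, TRUE))
  expect_error(bluntingCalls(h, "missing"), "reference")
  expect_error(viabilityGate(h[, 1:5]), "viability")

  ds <- simDeScreen(seed = 84)
  ah <- normalizeAndTest(ds$agonistPlate)
  ab <- viabilityGate(bluntingCalls(ah, "siAJSZ"))
  ab <- ab[!ab$condition %in% c("siControl", "siAJSZ"), ]
  expect_equal(sum(ab$blunted), 61)
  expect_equal(sum(ab$blunted & ab$viable), 9)
  ## oracle recount from raw means
  ref <- mean(ds$agonistPlate$percent_positive[
    ds$agonistPlate$condition == "siAJSZ"])
  means <- tapply(ds$agonistPlate$percent_positive,
                  ds$agonistPlate$condition, mean)
  means <- means[!names(means) %in% c("siControl", "siAJSZ")]
  expect_equal(sum(means <= 0.5 * ref), 61)
})

test_that("fold change and 2^-ddCt arithmetic", {
  expect_equal(foldChange(5, 16), 3.2)
  expect_equal(foldChange(6, 36), 6)
  expect_error(foldChange(0, 10), "positive")
  expect_equal(ddctFold(20, 20, 20, 20), 1)
  expect_equal(ddctFold(20, 18, 22, 18), 4)
  expect_error(ddctFold(-1, 18, 22, 18), "positive")
})

test_that("the screen t-test is calibrated under the null", {
  cal <- screenNullCalibration(nSim = 10000, n = 4, seed = 85)
  expect_equal(cal$rate, 0.05, tolerance = 0.006 / 0.05)
  expect_equal(cal$se, sqrt(0.05 * 0.95 / 1e4))
})

test_that("readPlate validates required columns", {
  f <- tempfile(fileext = ".tsv")
  write.table(mkPlate("siControl", list(c(6, 6, 6, 6))), f, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_equal(nrow(readPlate(f)), 4)
  write.table(data.frame(condition = "x", value = 1), f, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(readPlate(f), "missing plate column")
})
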