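## 10-sample fixture: 4 samples share a 17q gain, 2 an 11q loss
cohortFixture <- function() {
  segs <- lapply(1:10, function(i) {
    ab <- NULL
    if (i <= 4) ab <- rbind(ab, data.frame(chrom = "17", start = 30e6,
                                           end = 70e6,
                                           annotation = "gain", log2 = 0.4))
    if (i <= 2) ab <- rbind(ab, data.frame(chrom = "11", start = 60e6,
                                           end = 100e6,
                                           annotation = "loss", log2 = -0.5))
    as.data.frame(tileSample(sprintf("s%02d", i), ab,
                             chroms = c("11", "17")))
  })
  CNSegments(do.call(rbind, segs))
}

test_that("aberration frequencies count samples per window", {
  co <- cohortFixture()
  fr <- aberrationFrequency(co, windowSize = 1e6)
  in17q <- fr$chrom == "17" & fr$start >= 30e6 & fr$end <= 70e6
  expect_true(all(fr$gain_freq[in17q] == 0.4))
  in11q <- fr$chrom == "11" & fr$start >= 60e6 & fr$end <= 100e6
  expect_true(all(fr$loss_freq[in11q] == 0.2))
  expect_true(all(fr$gain_freq >= 0 & fr$gain_freq <= 1))
  ## windows outside lesions are zero
  expect_true(all(fr$gain_freq[fr$chrom == "11" & fr$end < 60e6] == 0))
  expect_error(aberrationFrequency(co, windowSize = 0), "positive")
})

test_that("frequencies are invariant to sample order and cohort duplication", {
  co <- cohortFixture()
  fr <- aberrationFrequency(co, windowSize = 5e6)
  d <- as.data.frame(co)
  shuffled <- CNSegments(d[rev(seq_len(nrow(d))), ])
  expect_equal(aberrationFrequency(shuffled, windowSize = 5e6), fr)
  dup <- d
  dup$sample_id <- paste0(dup$sample_id, "_copy")
  doubled <- CNSegments(rbind(d, dup))
  expect_equal(aberrationFrequency(doubled, windowSize = 5e6), fr)
})

test_that("gain and loss fractions are independent and may exceed 1 jointly", {
  d <- rbind(as.data.frame(tileSample("a", data.frame(
    chrom = "17", start = 30e6, end = 40e6, annotation = "gain",
    log2 = 0.4))),
    as.data.frame(tileSample("b", data.frame(
      chrom = "17", start = 30e6, end = 40e6, annotation = "loss",
      log2 = -0.5))))
  fr <- aberrationFrequency(CNSegments(d), windowSize = 1e6)
  w <- fr$chrom == "17" & fr$start >= 30e6 & fr$end <= 40e6
  expect_true(all(fr$gain_freq[w] == 0.5 & fr$loss_freq[w] == 0.5))
})

test_that("region matrices project segments onto windows and genes", {
  seg <- tileSample("s", data.frame(chrom = "17", start = 30e6, end = 70e6,
                                    annotation = "gain", log2 = 0.4))
  win <- data.frame(chrom = "17", start = 40e6, end = 41e6,
                    name = "w17")
  rm1 <- regionMatrix(seg, win)
  expect_equal(rm1$log2["s", "w17"], 0.4)
  expect_equal(rm1$label["s", "w17"], "gain")
  ## window split between two segments: probe-count weighting by the
  ## overlapped fraction of each segment
  d <- data.frame(sample_id = "s", chrom = "1",
                  start = c(0, 10e6), end = c(10e6, 20e6),
                  n_probes = c(100L, 300L), log2_ratio = c(0.0, 0.6),
                  annotation = c("normal", "gain"))
  win2 <- data.frame(chrom = "1", start = 8e6, end = 12e6, name = "w")
  rm2 <- regionMatrix(CNSegments(d), win2)
  ## weights: 100 * 2/10 = 20 (left), 300 * 2/10 = 60 (right)
  expect_equal(rm2$log2["s", "w"], (20 * 0 + 60 * 0.6) / 80)
  expect_equal(rm2$label["s", "w"], "gain")
  ## uncovered region -> NA
  win3 <- data.frame(chrom = "2", start = 0, end = 1e6, name = "none")
  rm3 <- regionMatrix(CNSegments(d), win3)
  expect_true(is.na(rm3$log2["s", "none"]))
})

test_that("co-occurrence p equals the exact hypergeometric computation", {
  a <- rep(c(TRUE, TRUE, FALSE, FALSE), c(20, 5, 5, 20))
  b <- rep(c(TRUE, FALSE, TRUE, FALSE), c(20, 5, 5, 20))
  ct <- cooccurrenceTest(a, b)
  expect_equal(ct$table[1, 1], 20)
  ## base fisher.test as the independent oracle
  expect_equal(ct$p, fisher.test(ct$table)$p.value, tolerance = 1e-12)
  expect_gt(ct$oddsRatio, 1)
  ## random tables up to n = 40
  set.seed(31)
  for (i in 1:30) {
    n <- sample(8:40, 1)
    a <- runif(n) < runif(1, 0.2, 0.8)
    b <- runif(n) < runif(1, 0.2, 0.8)
    if (all(a) || !any(a) || all(b) || !any(b)) next
    ct <- cooccurrenceTest(a, b)
    expect_equal(ct$p, fisher.test(ct$table)$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate and nested co-occurrence inputs are handled", {
  expect_warning(ct <- cooccurrenceTest(rep(TRUE, 10),
                                        rep(c(TRUE, FALSE), 5)),
                 "degenerate")
  expect_equal(ct$p, 1)
  ## perfectly nested flags: zero cell handled by Haldane correction
  a <- rep(c(TRUE, FALSE), c(5, 15))
  b <- rep(c(TRUE, FALSE), c(10, 10))
  ct2 <- cooccurrenceTest(a, b)
  expect_true(is.finite(ct2$oddsRatio))
  expect_gt(ct2$oddsRatio, 1)
})

test_that("arm-pair co-occurrence reports all 28 pairs with BH correction", {
  set.seed(5)
  flags <- data.frame(sample_id = sprintf("s%d", 1:60))
  for (k in armKeys) flags[[k]] <- runif(60) < 0.3
  res <- suppressWarnings(armCooccurrence(flags))
  expect_equal(nrow(res), 28L)
  expect_equal(res$q, p.adjust(res$p, "BH"))
  expect_true(all(res$p >= 0 & res$p <= 1))
})

test_that("QC partition separates silent, near-silent and retained", {
  silent <- as.data.frame(tileSample("silent", NULL, chroms = "1"))
  near <- as.data.frame(tileSample("near", data.frame(
    chrom = "1", start = 1e6, end = 5e6, annotation = "loss",
    log2 = -0.5)))
  big <- as.data.frame(tileSample("big", data.frame(
    chrom = "1", start = 0, end = 51e6, annotation = "loss",
    log2 = -0.5)))
  qc <- qcPartition(CNSegments(rbind(silent, near, big)))
  expect_equal(unname(qc$classes[c("silent", "near", "big")]),
               c("silent", "near_silent", "retained"))
  expect_equal(as.vector(qc$counts), c(1L, 1L, 1L))
})

test_that("cohort summary reports both segmental fractions", {
  f1 <- segmentalFlags(tileSample("a", data.frame(
    chrom = "11", start = 60e6, end = 70e6, annotation = "loss",
    log2 = -0.5)))
  f2 <- segmentalFlags(tileSample("b", data.frame(
    chrom = "5", start = 10e6, end = 20e6, annotation = "gain",
    log2 = 0.4)))
  f3 <- segmentalFlags(tileSample("c", NULL, chroms = "1"))
  fl <- rbind(f1, f2, f3)
  s <- cohortSummary(fl)
  ## flagged-arm lesion in 1 of 3; any-arm lesion in 2 of 3
  expect_equal(s$pct_segmental_8arms, 100 / 3, tolerance = 1e-10)
  expect_equal(s$pct_segmental_any_arm, 200 / 3, tolerance = 1e-10)
  expect_equal(unname(s$flag_freq["loss_11q"]), 1 / 3)
  expect_error(cohortSummary(fl[0, ]), "empty")
})
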