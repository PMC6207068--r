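loss <- function(chrom, start, end)
  data.frame(chrom = chrom, start = start, end = end,
             annotation = "loss", log2 = -0.5)
gain <- function(chrom, start, end)
  data.frame(chrom = chrom, start = start, end = end,
             annotation = "gain", log2 = 0.4)
amp <- function(chrom, start, end)
  data.frame(chrom = chrom, start = start, end = end,
             annotation = "amplification", log2 = 2.5)

test_that("the 3 Mb bound is strict: larger counts, smaller and equal do not", {
  f29 <- segmentalFlags(tileSample("s", loss("1", 1e6, 1e6 + 2.9e6)))
  expect_false(f29$loss_1p)
  expect_false(f29$any_segmental_all)
  f30 <- segmentalFlags(tileSample("s", loss("1", 1e6, 1e6 + 3e6)))
  expect_false(f30$loss_1p)  # exactly 3 Mb is not "larger than 3 Mb"
  f31 <- segmentalFlags(tileSample("s", loss("1", 1e6, 1e6 + 3.1e6)))
  expect_true(f31$loss_1p)
  expect_true(f31$any_segmental)
  expect_identical(f31$profile_class, "segmental")
})

test_that("whole-chromosome aberrations are excluded from arm flags", {
  len17 <- hg19Arms()$length[hg19Arms()$chrom == "17"]
  f <- segmentalFlags(tileSample("s", gain("17", 0, len17)))
  expect_false(f$gain_17q)
  expect_false(f$any_segmental_all)
  expect_identical(f$profile_class, "numerical_only")
  ## a 40% gain is not whole-chromosome
  f2 <- segmentalFlags(tileSample("s", gain("17", 3e7, 3e7 + 0.4 * len17)))
  expect_true(f2$gain_17q)
  expect_identical(f2$profile_class, "segmental")
})

test_that("whole-chromosome coverage threshold acts at 95% of covered extent", {
  seg <- function(frac) {
    len <- 1e8
    CNSegments(data.frame(
      sample_id = "s", chrom = "6",
      start = c(0, frac * len), end = c(frac * len, len),
      n_probes = 10L, log2_ratio = c(0.4, 0),
      annotation = c("gain", "normal")))
  }
  expect_true(isWholeChromosome(seg(0.96)))
  expect_false(isWholeChromosome(seg(0.94)))
  expect_false(isWholeChromosome(seg(0.40)))
  ## single gain spanning all coverage
  one <- CNSegments(data.frame(sample_id = "s", chrom = "6", start = 0,
                               end = 1e8, n_probes = 10L,
                               log2_ratio = 0.4, annotation = "gain"))
  expect_true(isWholeChromosome(one))
})

test_that("amplifications never count as segmental aberrations", {
  f <- segmentalFlags(tileSample("s", amp("2", 15.9e6, 16.4e6)))
  expect_false(f$gain_2p)
  expect_false(f$any_segmental_all)
  ## even a large amplification is excluded
  fBig <- segmentalFlags(tileSample("s", amp("2", 10e6, 20e6)))
  expect_false(fBig$gain_2p)
  expect_false(fBig$any_segmental_all)
  ## but an amplified profile is not silent
  expect_identical(f$profile_class, "segmental")
})

test_that("centromere-spanning aberrations follow the longer-arm rule", {
  arms <- hg19Arms()
  cen <- arms[arms$chrom == "11", ]
  ## q part much longer than p part
  f <- segmentalFlags(tileSample("s", loss("11", cen$cen_start - 2e6,
                                           cen$cen_end + 40e6)))
  expect_true(f$loss_11q)
  ## p part longer: assigned to 11p, which is not a flagged arm
  f2 <- segmentalFlags(tileSample("s", loss("11", cen$cen_start - 40e6,
                                            cen$cen_end + 2e6)))
  expect_false(f2$loss_11q)
  expect_true(f2$any_segmental_all)  # still segmental, just not flagged
})

test_that("homozygous deletions count toward loss flags", {
  hd <- data.frame(chrom = "3", start = 1e6, end = 10e6,
                   annotation = "homozygous_deletion", log2 = -2.5)
  f <- segmentalFlags(tileSample("s", hd))
  expect_true(f$loss_3p)
})

test_that("flags are invariant to fragmentation and segment order", {
  whole <- tileSample("s", loss("11", 60e6, 90e6))
  d <- as.data.frame(whole)
  ## split the lesion into three adjacent loss pieces
  i <- which(d$annotation == "loss")
  piece <- d[i, ]
  splits <- rbind(
    transform(piece, end = 70e6),
    transform(piece, start = 70e6, end = 81e6),
    transform(piece, start = 81e6))
  frag <- CNSegments(rbind(d[-i, ], splits))
  expect_equal(segmentalFlags(frag)[armKeys],
               segmentalFlags(whole)[armKeys])
  ## shuffled input rows give identical flags (container sorts)
  shuf <- CNSegments(d[sample(nrow(d)), ])
  expect_equal(segmentalFlags(shuf)[armKeys],
               segmentalFlags(whole)[armKeys])
})

test_that("profiles are classified as silent / numerical_only / segmental", {
  allNormal <- tileSample("s", NULL, chroms = c("1", "2", "3"))
  expect_identical(unname(classifyProfile(allNormal)), "silent")
  len7 <- hg19Arms()$length[hg19Arms()$chrom == "7"]
  len17 <- hg19Arms()$length[hg19Arms()$chrom == "17"]
  numeric2 <- tileSample("s", rbind(gain("7", 0, len7),
                                    gain("17", 0, len17)))
  expect_identical(unname(classifyProfile(numeric2)), "numerical_only")
  seg1 <- tileSample("s", loss("11", 60e6, 70e6))
  expect_identical(unname(classifyProfile(seg1)), "segmental")
})

test_that("uncalled segments are rejected with guidance", {
  u <- CNSegments(data.frame(sample_id = "s", chrom = "1", start = 0,
                             end = 1e6, n_probes = 5L, log2_ratio = 0))
  expect_error(segmentalFlags(u), "callSegments")
  expect_error(focalAberrations(u), "callSegments")
})

test_that("focal aberrations are reported over genes under 5 Mb only", {
  g <- nbGenes()
  alk <- g[g$gene == "ALK", ]
  ## 1 Mb amplification over ALK
  f <- focalAberrations(tileSample("s", amp("2", alk$start - 2e5,
                                            alk$start + 8e5)))
  expect_equal(f$gene, "ALK")
  expect_equal(f$annotation, "amplification")
  ## 20 Mb gain over ALK: not focal
  f2 <- focalAberrations(tileSample("s", gain("2", alk$start - 1e7,
                                              alk$start + 1e7)))
  expect_equal(nrow(f2), 0L)
  ## no overlap -> empty
  f3 <- focalAberrations(tileSample("s", gain("4", 1e6, 2e6)))
  expect_equal(nrow(f3), 0L)
})
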