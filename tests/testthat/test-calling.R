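test_that("default platform models carry the published cutoffs", {
  affy <- platformModel("affymetrix_snp")
  expect_equal(affy@gainCutoff, 0.15)
  expect_equal(affy@lossCutoff, -0.25)
  expect_equal(affy@ampCutoff, 1.5)
  expect_equal(affy@homdelCutoff, -2)
  ilmn <- platformModel("illumina_snp")
  expect_equal(ilmn@gainCutoff, 0.15)
  expect_equal(ilmn@lossCutoff, -0.25)
  expect_equal(ilmn@ampCutoff, 0.7)
  agil <- platformModel("agilent_acgh")
  expect_equal(agil@gainCutoff, 0.2)
  expect_equal(agil@lossCutoff, -0.3)
  expect_equal(agil@ampCutoff, 2)
  nimb <- platformModel("nimblegen_acgh")
  expect_equal(nimb@gainCutoff, 0.2)
  expect_equal(nimb@lossCutoff, -0.3)
  expect_equal(nimb@ampCutoff, 1.5)
  expect_error(platformModel("agilent"), "unknown platform")
})

test_that("call labels follow the platform cutoffs across all boundaries", {
  ## hand-enumerated truth table spanning every boundary on both
  ## platform classes
  cases <- rbind(
    data.frame(l2 = c(0, 0.14, 0.15, 0.18, 0.7, 1.49, 1.5, -0.24,
                      -0.25, -1.99, -2, -2.5),
               fam = "affymetrix_snp",
               lab = c("normal", "normal", "gain", "gain", "gain",
                       "gain", "amplification", "normal", "loss", "loss",
                       "loss", "homozygous_deletion")),
    data.frame(l2 = c(0.18, 0.2, 0.8, 1.9, 2.0, -0.29, -0.3, -2.5),
               fam = "agilent_acgh",
               lab = c("normal", "gain", "gain", "gain", "amplification",
                       "normal", "loss", "homozygous_deletion")),
    data.frame(l2 = c(0.69, 0.7, 0.8), fam = "illumina_snp",
               lab = c("gain", "amplification", "amplification")),
    data.frame(l2 = c(0.8, 1.5), fam = "nimblegen_acgh",
               lab = c("gain", "amplification")))
  for (fam in unique(cases$fam)) {
    sub <- cases[cases$fam == fam, ]
    expect_equal(callSegment(sub$l2, platformModel(fam)), sub$lab,
                 label = fam)
  }
  expect_error(callSegment(NA_real_, platformModel("agilent_acgh")),
               "non-finite")
})

test_that("raising log2 never moves the call toward deletion", {
  lv <- callLevels()
  for (fam in platformFamilies()) {
    m <- platformModel(fam)
    grid <- sort(c(seq(-3, 3, by = 0.01), m@gainCutoff, m@lossCutoff,
                   m@ampCutoff, m@homdelCutoff))
    ranks <- match(callSegment(grid, m), lv)
    expect_true(all(diff(ranks) >= 0), label = fam)
  }
})

test_that("mixture calibration finds density intersections", {
  ## equal-weight equal-sd components at -0.5 / 0 / +0.5 intersect at
  ## the midpoints
  set.seed(21)
  x <- c(rnorm(2000, -0.5, 0.07), rnorm(2000, 0, 0.07),
         rnorm(2000, 0.5, 0.07))
  cal <- calibrateCutoffs(x, model = platformModel("agilent_acgh"))
  expect_false(cal$fallback)
  expect_equal(cal$gainCutoff, 0.25, tolerance = 0.02)
  expect_equal(cal$lossCutoff, -0.25, tolerance = 0.02)
  expect_equal(cal$model@gainCutoff, cal$gainCutoff)
})

test_that("unequal mixtures match an independent root-find of the densities", {
  set.seed(8)
  w <- c(0.25, 0.6, 0.15)
  mu <- c(-0.5, 0, 0.4); sg <- c(0.1, 0.07, 0.09)
  comp <- sample(1:3, 6000, TRUE, prob = w)
  x <- rnorm(6000, mu[comp], sg[comp])
  cal <- calibrateCutoffs(x, model = platformModel("affymetrix_snp"))
  gainTrue <- uniroot(function(z) w[2] * dnorm(z, mu[2], sg[2]) -
                        w[3] * dnorm(z, mu[3], sg[3]),
                      c(0.01, 0.39))$root
  lossTrue <- uniroot(function(z) w[1] * dnorm(z, mu[1], sg[1]) -
                        w[2] * dnorm(z, mu[2], sg[2]),
                      c(-0.49, -0.01))$root
  expect_equal(cal$gainCutoff, gainTrue, tolerance = 0.03)
  expect_equal(cal$lossCutoff, lossTrue, tolerance = 0.03)
})

test_that("degenerate calibration inputs fall back to platform defaults", {
  m <- platformModel("illumina_snp")
  set.seed(2)
  oneState <- rnorm(500, 0, 0.05)
  expect_warning(cal <- calibrateCutoffs(oneState, model = m), "fallback|defaults")
  expect_true(cal$fallback)
  expect_equal(cal$gainCutoff, m@gainCutoff)
  expect_equal(cal$lossCutoff, m@lossCutoff)
  expect_error(calibrateCutoffs(rnorm(50), model = m), ">= 100")
})

test_that("amplification cutoff scan maximizes discrimination, ties to the top", {
  res <- calibrateAmpCutoff(c(2.1, 2.5, 3.0, 0.2, 0.4, 1.0),
                            c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$cutoff, 1.55)  # midpoint of the separating interval
  expect_equal(res$accuracy, 1.0)
  ## equals the exhaustive-scan oracle on random fixtures
  set.seed(14)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    amp <- runif(n) < 0.4
    if (length(unique(amp)) < 2) next
    l2 <- ifelse(amp, rnorm(n, 2, 0.8), rnorm(n, 0.3, 0.4))
    res <- calibrateAmpCutoff(l2, amp)
    expect_equal(res$cutoff, ampScanOracle(l2, amp))
  }
  expect_error(calibrateAmpCutoff(c(1, 2), c(TRUE, TRUE)), "both")
})

test_that("MYCN status is called from locus-overlapping segments", {
  m <- platformModel("agilent_acgh")
  mk <- function(l2, chrom = "2") CNSegments(data.frame(
    sample_id = "s1", chrom = chrom, start = 15e6, end = 17e6,
    n_probes = 10L, log2_ratio = l2, annotation = "normal"))
  expect_equal(unname(mycnCall(mk(3.1), m)), "amplified")
  expect_equal(unname(mycnCall(mk(1.2), m)), "nonamplified")
  ## 1.2 clears the Illumina cutoff instead
  expect_equal(unname(mycnCall(mk(1.2), platformModel("illumina_snp"))),
               "amplified")
  ## no chr2 coverage -> unknown
  expect_equal(unname(mycnCall(mk(3.1, chrom = "3"), m)), "unknown")
})

test_that("concordance is computed per platform with unknowns set aside", {
  ann <- SampleAnnotations(data.frame(
    sample_id = sprintf("s%02d", 1:20),
    platform = rep(c("agilent_acgh", "illumina_snp"), each = 10),
    mycn_status = rep(c("amplified", "nonamplified"), 10)))
  calls <- setNames(rep(c("amplified", "nonamplified"), 10),
                    sprintf("s%02d", 1:20))
  res <- mycnConcordance(calls, ann)
  expect_equal(res$concordance, c(1, 1))
  ## one wrong call out of 10 on one platform
  calls["s01"] <- "nonamplified"
  res <- mycnConcordance(calls, ann)
  expect_equal(res$concordance[res$platform == "agilent_acgh"], 0.9)
  ## unknowns counted separately, not in the denominator
  calls["s02"] <- "unknown"
  res <- mycnConcordance(calls, ann)
  expect_equal(res$n_unknown[res$platform == "agilent_acgh"], 1L)
  expect_equal(res$n_compared[res$platform == "agilent_acgh"], 9L)
})
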