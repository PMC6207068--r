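## Platform-faithful synthetic cohorts with known truth. Four archetypes
## mirror the recurrent aberration patterns of high-risk neuroblastoma:
##   mna_type        focal MYCN amplification + 1p loss + 17q gain
##   11q_type        11q loss + 3p loss + 17q gain
##   numerical_only  whole-chromosome gains/losses only
##   silent          no aberrations (normal-cell-contamination look-alike)
## Platform families differ in probe noise, in segmental-event log2 means
## (aCGH wider than SNP) and in amplification level (Illumina compressed).

.archetypes <- c("mna_type", "11q_type", "numerical_only", "silent")

#' Simulation configuration
#'
#' All knobs of the synthetic-cohort generator with their defaults. Event
#' log2 means and noise sds are package defaults chosen to mirror the
#' qualitative platform ordering (aCGH dynamic range wider than SNP;
#' Illumina amplifications compressed); they live on the corresponding
#' [platformModel()] objects.
#'
#' @param nSamples Named integer vector: samples per platform family
#'   (default 50 each).
#' @param archetypeWeights Named weights over the four archetypes,
#'   summing to 1 (default mna_type 0.45, 11q_type 0.40, numerical_only
#'   0.10, silent 0.05 - a high-risk case mix dominated by MYCN-amplified
#'   and 11q-deleted tumors).
#' @param probeSpacing Distance between simulated probes in bp (default
#'   2e5; the centromere gap carries no probes).
#' @param noiseSd Optional named per-family override of the probe noise
#'   sd; defaults to each platform model's value.
#' @param ampCenter Optional named per-family override of the
#'   amplification log2 center; defaults to each platform model's value
#'   (Illumina 1.0, Affymetrix/NimbleGen 2.0, Agilent 3.0).
#' @param baselineHazard Exponential event hazard per month for the
#'   silent/numerical archetypes (default 0.012, median OS about 58
#'   months).
#' @param hazardMultipliers Named per-archetype hazard multipliers
#'   (default mna_type 3, 11q_type 2, numerical_only 1, silent 1).
#' @param censorTime Administrative censoring horizon in months (default
#'   120).
#' @param seed Master seed; per-sample substreams are derived from it so
#'   cohorts are reproducible under subsetting.
#' @return A list of class `simulation_config`.
#' @export
simulationConfig <- function(nSamples = NULL, archetypeWeights = NULL,
                             probeSpacing = 2e5, noiseSd = NULL,
                             ampCenter = NULL, baselineHazard = 0.012,
                             hazardMultipliers = NULL, censorTime = 120,
                             seed = 1L) {
  fams <- platformFamilies()
  if (is.null(nSamples))
    nSamples <- setNames(rep(50L, length(fams)), fams)
  if (is.null(archetypeWeights))
    archetypeWeights <- c(mna_type = 0.45, `11q_type` = 0.40,
                          numerical_only = 0.10, silent = 0.05)
  stopifnot(all(names(nSamples) %in% fams),
            setequal(names(archetypeWeights), .archetypes),
            abs(sum(archetypeWeights) - 1) < 1e-8,
            all(archetypeWeights >= 0),
            probeSpacing > 0, baselineHazard > 0, censorTime > 0)
  if (is.null(hazardMultipliers))
    hazardMultipliers <- c(mna_type = 3, `11q_type` = 2,
                           numerical_only = 1, silent = 1)
  stopifnot(setequal(names(hazardMultipliers), .archetypes),
            all(hazardMultipliers > 0))
  structure(list(nSamples = nSamples,
                 archetypeWeights = archetypeWeights[.archetypes],
                 probeSpacing = probeSpacing,
                 noiseSd = noiseSd, ampCenter = ampCenter,
                 baselineHazard = baselineHazard,
                 hazardMultipliers = hazardMultipliers[.archetypes],
                 censorTime = censorTime,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

## True aberration list for one archetype. Coordinates are hg19;
## aberrations sit in the canonical neuroblastoma regions.
.archetypeAberrations <- function(archetype, model, config, arms) {
  sd2 <- function(chrom) arms$length[match(chrom, arms$chrom)]
  gain <- model@gainMean; loss <- model@lossMean
  amp <- if (!is.null(config$ampCenter) &&
             model@family %in% names(config$ampCenter))
    config$ampCenter[[model@family]] else model@ampCenter
  ab <- switch(archetype,
    mna_type = data.frame(
      chrom = c("2", "1", "17"),
      start = c(15.7e6, 0, 30e6),
      end = c(16.6e6, 51e6, sd2("17")),
      type = c("amplification", "loss", "gain"),
      log2 = c(amp, loss, gain)),
    `11q_type` = data.frame(
      chrom = c("11", "3", "17"),
      start = c(55e6, 0, 30e6),
      end = c(sd2("11"), 60e6, sd2("17")),
      type = c("loss", "loss", "gain"),
      log2 = c(loss, loss, gain)),
    numerical_only = {
      k <- sample(2:4, 1L)
      chroms <- sample(as.character(c(4, 6, 7, 9, 13, 14, 18, 19)), k)
      dirGain <- runif(k) < 0.6
      data.frame(chrom = chroms, start = 0, end = sd2(chroms),
                 type = ifelse(dirGain, "gain", "loss"),
                 log2 = ifelse(dirGain, gain, loss))
    },
    silent = data.frame(chrom = character(), start = numeric(),
                        end = numeric(), type = character(),
                        log2 = numeric()),
    stop("invalid archetype: ", archetype, call. = FALSE))
  ab
}

## Probe grid for one chromosome: evenly spaced, skipping the centromere.
.probeGrid <- function(armRow, spacing) {
  pos <- seq(spacing / 2, armRow$length - 1, by = spacing)
  pos[pos < armRow$cen_start | pos >= armRow$cen_end]
}

## Noiseless truth segments tiling every chromosome, with probe counts
## from the grid. Aberration boundaries partition [0, length).
.truthSegmentsForSample <- function(sid, ab, arms, spacing) {
  out <- list()
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    abi <- ab[ab$chrom == a$chrom, , drop = FALSE]
    bounds <- sort(unique(c(0, a$length, abi$start, abi$end)))
    grid <- .probeGrid(a, spacing)
    for (k in seq_len(length(bounds) - 1L)) {
      s <- bounds[k]; e <- bounds[k + 1L]
      j <- which(abi$start <= s & abi$end >= e)
      lab <- if (length(j)) abi$type[j[1L]] else "normal"
      l2 <- if (length(j)) abi$log2[j[1L]] else 0
      np <- sum(grid >= s & grid < e)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid, chrom = a$chrom, start = s, end = e,
        n_probes = max(np, 1L), log2_ratio = l2, annotation = lab)
    }
  }
  do.call(rbind, out)
}

#' Simulate one copy-number profile with known truth
#'
#' Generates the probe-level profile of a single sample: the archetype's
#' true aberrations define a piecewise-constant log2 signal over the hg19
#' probe grid, and Gaussian probe noise at the platform's sd (plus a
#' small random baseline shift, removed again by median normalization) is
#' added on top.
#'
#' @param archetype One of `"mna_type"`, `"11q_type"`,
#'   `"numerical_only"`, `"silent"`.
#' @param model The platform's [PlatformModel].
#' @param config A [simulationConfig()].
#' @param seed Integer seed for this sample.
#' @param sampleId Sample identifier (default derived from the seed).
#' @param noiseSd Probe noise sd; defaults to the platform's value (0
#'   gives noiseless probes at the truth signal).
#' @return A list with `probes` ([CNProbes]), `truthSegments`
#'   ([CNSegments], noiseless, annotated), `aberrations` (data.frame) and
#'   `archetype`.
#' @export
simulateProfile <- function(archetype, model, config = simulationConfig(),
                            seed = 1L, sampleId = NULL, noiseSd = NULL) {
  stopifnot(is(model, "PlatformModel"))
  if (!archetype %in% .archetypes)
    stop("invalid archetype: ", archetype, call. = FALSE)
  arms <- hg19Arms()
  set.seed(seed)
  if (is.null(sampleId)) sampleId <- sprintf("sim_%d", seed)
  if (is.null(noiseSd)) {
    noiseSd <- if (!is.null(config$noiseSd) &&
                   model@family %in% names(config$noiseSd))
      config$noiseSd[[model@family]] else model@noiseSd
  }
  ab <- .archetypeAberrations(archetype, model, config, arms)
  shift <- if (noiseSd > 0) rnorm(1L, 0, 0.2 * noiseSd) else 0
  probes <- list()
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    pos <- .probeGrid(a, config$probeSpacing)
    mu <- numeric(length(pos))
    abi <- ab[ab$chrom == a$chrom, , drop = FALSE]
    for (k in seq_len(nrow(abi)))
      mu[pos >= abi$start[k] & pos < abi$end[k]] <- abi$log2[k]
    probes[[i]] <- data.frame(
      sample_id = sampleId, chrom = a$chrom, position = pos,
      log2_ratio = mu + shift +
        if (noiseSd > 0) rnorm(length(pos), 0, noiseSd) else 0)
  }
  if (nrow(ab)) ab <- cbind(sample_id = sampleId, ab)
  list(probes = CNProbes(do.call(rbind, probes)),
       truthSegments = CNSegments(
         .truthSegmentsForSample(sampleId, ab, arms, config$probeSpacing)),
       aberrations = ab,
       archetype = archetype)
}

#' Simulate a multi-platform cohort with ground truth
#'
#' Draws archetypes from the configured mixture for every platform
#' family, simulates each sample's probe profile, assembles the noiseless
#' truth segments, derives the true arm flags by running
#' [segmentalFlags()] on the truth segments, sets MYCN status from truth
#' and draws exponential survival times whose hazard is scaled by the
#' archetype multiplier, with administrative censoring. Per-sample RNG
#' substreams are derived from the master seed.
#'
#' @param config A [simulationConfig()].
#' @return A [SyntheticCohort] object.
#' @examples
#' \donttest{
#' sc <- simulateCohort(simulationConfig(
#'   nSamples = c(affymetrix_snp = 5, illumina_snp = 5,
#'                agilent_acgh = 5, nimblegen_acgh = 5), seed = 7))
#' sc
#' }
#' @export
simulateCohort <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  fams <- sort(names(config$nSamples))  # lexicographic: keeps rbind sorted
  total <- sum(config$nSamples)
  sampleSeeds <- sample.int(.Machine$integer.max, total)
  labs <- c("lab_eu", "lab_us", "lab_jp")
  probes <- list(); truthSegs <- list(); abs <- list()
  ann <- list()
  idx <- 0L
  for (fam in fams) {
    model <- platformModel(fam)
    for (j in seq_len(config$nSamples[[fam]])) {
      idx <- idx + 1L
      sid <- sprintf("%s_%03d", fam, j)
      ## archetype, lab and survival drawn from the sample's substream
      set.seed(sampleSeeds[idx])
      archetype <- sample(.archetypes, 1L,
                          prob = config$archetypeWeights)
      lab <- sample(labs, 1L)
      rate <- config$baselineHazard *
        config$hazardMultipliers[[archetype]]
      osT <- rexp(1L, rate)
      efsT <- rexp(1L, rate * 1.4)
      profSeed <- sample.int(.Machine$integer.max, 1L)
      prof <- simulateProfile(archetype, model, config, seed = profSeed,
                              sampleId = sid)
      probes[[idx]] <- as.data.frame(prof$probes)
      truthSegs[[idx]] <- as.data.frame(prof$truthSegments)
      if (nrow(prof$aberrations)) abs[[length(abs) + 1L]] <-
        cbind(prof$aberrations, platform = fam)
      ann[[idx]] <- data.frame(
        sample_id = sid, platform = fam, lab = lab,
        archetype = archetype,
        mycn_status = if (archetype == "mna_type") "amplified"
                      else "nonamplified",
        stage = if (archetype == "silent") "4" else
          sample(c("4", "3", "2"), 1L, prob = c(0.8, 0.15, 0.05)),
        age_group = sample(c("<18m", ">=18m"), 1L, prob = c(0.3, 0.7)),
        os_time = min(osT, config$censorTime),
        os_event = as.integer(osT <= config$censorTime),
        efs_time = if (lab == "lab_jp") NA_real_
                   else min(efsT, config$censorTime),
        efs_event = if (lab == "lab_jp") NA_integer_
                    else as.integer(efsT <= config$censorTime),
        time_unit = "months")
    }
  }
  truthSegments <- callTruthSegments(
    CNSegments(do.call(rbind, truthSegs)))
  annotations <- SampleAnnotations(do.call(rbind, ann))
  tf <- segmentalFlags(truthSegments)
  tf$archetype <- annotations@data$archetype[
    match(tf$sample_id, annotations@data$sample_id)]
  tf$platform <- annotations@data$platform[
    match(tf$sample_id, annotations@data$sample_id)]
  new("SyntheticCohort",
      probes = CNProbes(do.call(rbind, probes)),
      truthSegments = truthSegments,
      annotations = annotations,
      truth = if (length(abs)) do.call(rbind, abs) else
        data.frame(sample_id = character(), chrom = character(),
                   start = numeric(), end = numeric(),
                   type = character(), log2 = numeric(),
                   platform = character()),
      truthFlags = tf,
      config = unclass(config))
}

## Truth segments already carry their labels (the simulated event type);
## normalize them so validity and downstream ops see call labels.
callTruthSegments <- function(truthSegments) {
  d <- as.data.frame(truthSegments)
  stopifnot(all(d$annotation %in% c("normal", "gain", "loss",
                                    "amplification")))
  CNSegments(d)
}

#' Measure recovery of simulated truth aberrations
#'
#' For every true aberration larger than `minLength`, checks whether the
#' called segments of the same dosage direction (gain class for gains,
#' loss class for losses) cover at least `minCoverage` of its span. Focal
#' amplification events shorter than `minLength` are not scored.
#'
#' @param segments A called [CNSegments] of the pipeline output.
#' @param truth Truth aberration table from [truthAberrations()]
#'   (columns `sample_id`, `chrom`, `start`, `end`, `type`).
#' @param minLength Only score truth events larger than this (default
#'   3e6, the segmental-aberration bound).
#' @param minCoverage Covered fraction required to count an event as
#'   recovered (default 0.5).
#' @return A list with `rate` (fraction recovered) and `events` (per-event
#'   data.frame with the covered fraction).
#' @export
aberrationRecovery <- function(segments, truth, minLength = 3e6,
                               minCoverage = 0.5) {
  stopifnot(is(segments, "CNSegments"))
  d <- as.data.frame(segments)
  .checkCalled(d)
  tr <- truth[(truth$end - truth$start) > minLength, , drop = FALSE]
  cov <- vapply(seq_len(nrow(tr)), function(i) {
    cls <- if (tr$type[i] == "loss") .lossClass else .gainClass
    sel <- d$sample_id == tr$sample_id[i] & d$chrom == tr$chrom[i] &
      d$annotation %in% cls & d$start < tr$end[i] & d$end > tr$start[i]
    if (!any(sel)) return(0)
    sum(pmin(d$end[sel], tr$end[i]) - pmax(d$start[sel], tr$start[i])) /
      (tr$end[i] - tr$start[i])
  }, 0.0)
  tr$covered <- cov
  tr$recovered <- cov >= minCoverage
  list(rate = mean(tr$recovered), events = tr)
}
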