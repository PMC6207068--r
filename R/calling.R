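## Platform-specific aberration calling. The four platform families carry
## distinct log2-ratio dynamic ranges: aCGH spreads aberrant segments
## wider than SNP arrays, and amplifications reach ~0.7-1.5 on Illumina
## versus 2+ on Agilent. Cutoffs are therefore per family:
##   gains/losses +0.15/-0.25 (SNP: Affymetrix, Illumina)
##                +0.20/-0.30 (aCGH: Agilent, NimbleGen)
##   amplification >= 1.5 (Affymetrix, NimbleGen), 2 (Agilent),
##                 0.7 (Illumina)
##   homozygous deletion < -2 on every platform.

.platformDefaults <- list(
  affymetrix_snp = list(gain = 0.15, loss = -0.25, amp = 1.5,
                        noiseSd = 0.22, ampCenter = 2.0,
                        gainMean = 0.35, lossMean = -0.45),
  illumina_snp   = list(gain = 0.15, loss = -0.25, amp = 0.7,
                        noiseSd = 0.15, ampCenter = 1.0,
                        gainMean = 0.35, lossMean = -0.45),
  agilent_acgh   = list(gain = 0.20, loss = -0.30, amp = 2.0,
                        noiseSd = 0.30, ampCenter = 3.0,
                        gainMean = 0.45, lossMean = -0.55),
  nimblegen_acgh = list(gain = 0.20, loss = -0.30, amp = 1.5,
                        noiseSd = 0.28, ampCenter = 2.0,
                        gainMean = 0.45, lossMean = -0.55)
)

#' Platform calling model with default cutoffs
#'
#' Returns the calling cutoffs for one of the four supported array
#' families, plus the simulation parameters (probe noise sd, typical
#' amplification log2 center, segmental gain/loss means) used by
#' [simulateCohort()]. Cutoffs can be overridden, e.g. after
#' [calibrateCutoffs()].
#'
#' @param family One of [platformFamilies()].
#' @param gainCutoff,lossCutoff,ampCutoff,homdelCutoff Optional overrides
#'   of the default cutoffs (log2 ratio units).
#' @return A [PlatformModel] object.
#' @examples
#' platformModel("affymetrix_snp")
#' platformModel("illumina_snp")@ampCutoff  # 0.7
#' @name PlatformModel-class
#' @aliases platformModel PlatformModel
#' @export
platformModel <- function(family, gainCutoff = NULL, lossCutoff = NULL,
                          ampCutoff = NULL, homdelCutoff = -2) {
  if (!family %in% platformFamilies())
    stop("unknown platform family: ", family, call. = FALSE)
  def <- .platformDefaults[[family]]
  new("PlatformModel",
      family = family,
      gainCutoff = if (is.null(gainCutoff)) def$gain else gainCutoff,
      lossCutoff = if (is.null(lossCutoff)) def$loss else lossCutoff,
      ampCutoff = if (is.null(ampCutoff)) def$amp else ampCutoff,
      homdelCutoff = homdelCutoff,
      noiseSd = def$noiseSd, ampCenter = def$ampCenter,
      gainMean = def$gainMean, lossMean = def$lossMean)
}

#' Call a segment mean log2 ratio
#'
#' Labels in precedence order: homozygous deletion if `log2 <
#' homdelCutoff` (strict, default -2), else loss if `log2 <= lossCutoff`,
#' else amplification if `log2 >= ampCutoff`, else gain if `log2 >=
#' gainCutoff`, else normal. Gain/loss/amplification bounds are inclusive;
#' the homozygous-deletion bound is strict.
#'
#' @param log2 Numeric vector of segment mean log2 ratios (finite).
#' @param model A [PlatformModel].
#' @return Character vector of labels from [callLevels()].
#' @examples
#' m <- platformModel("affymetrix_snp")
#' callSegment(c(0, 0.18, -0.3, 1.6, -2.5), m)
#' @export
callSegment <- function(log2, model) {
  stopifnot(is(model, "PlatformModel"))
  if (any(!is.finite(log2)))
    stop("non-finite segment log2 ratio", call. = FALSE)
  out <- rep("normal", length(log2))
  out[log2 >= model@gainCutoff] <- "gain"
  out[log2 >= model@ampCutoff] <- "amplification"
  out[log2 <= model@lossCutoff] <- "loss"
  out[log2 < model@homdelCutoff] <- "homozygous_deletion"
  out
}

#' Annotate a segment table with aberration calls
#'
#' @param segments A [CNSegments] object.
#' @param model A [PlatformModel] (one platform; call per platform and
#'   combine for mixed cohorts).
#' @return The [CNSegments] with the `annotation` column filled.
#' @export
callSegments <- function(segments, model) {
  stopifnot(is(segments, "CNSegments"))
  d <- as.data.frame(segments)
  d$annotation <- callSegment(d$log2_ratio, model)
  CNSegments(d)
}

## Weighted 1-D EM for a 3-component Gaussian mixture (loss/neutral/gain).
## Hand-rolled because the calibration weights observations by probe
## count, which off-the-shelf mixture fitters do not support.
.weightedGmm3 <- function(x, w, maxIter = 500L, tol = 1e-8) {
  w <- w / sum(w)
  qs <- quantile(x, c(0.10, 0.50, 0.90), names = FALSE)
  mu <- qs
  sdAll <- sqrt(sum(w * (x - sum(w * x))^2))
  sig <- rep(max(sdAll / 2, 1e-3), 3L)
  pi3 <- rep(1 / 3, 3L)
  ll0 <- -Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    dens <- vapply(1:3, function(k) pi3[k] * dnorm(x, mu[k], sig[k]),
                   numeric(length(x)))
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    r <- dens / tot
    ll <- sum(w * log(tot))
    nk <- colSums(w * r)
    pi3 <- nk
    for (k in 1:3) {
      mu[k] <- sum(w * r[, k] * x) / nk[k]
      sig[k] <- sqrt(sum(w * r[, k] * (x - mu[k])^2) / nk[k])
      sig[k] <- max(sig[k], 1e-6)
    }
    if (is.finite(ll0) && abs(ll - ll0) < tol * (abs(ll0) + tol)) {
      converged <- TRUE
      break
    }
    ll0 <- ll
  }
  o <- order(mu)
  list(weight = pi3[o], mean = mu[o], sd = sig[o], converged = converged,
       loglik = ll0)
}

## Density-intersection of two weighted Gaussian components inside
## (mu_a, mu_b); NA when no sign change exists in the open interval.
.densityIntersection <- function(wA, muA, sdA, wB, muB, sdB) {
  f <- function(x) log(wB) + dnorm(x, muB, sdB, log = TRUE) -
    log(wA) - dnorm(x, muA, sdA, log = TRUE)
  eps <- (muB - muA) * 1e-6
  lo <- muA + eps
  hi <- muB - eps
  if (f(lo) >= 0 || f(hi) <= 0) return(NA_real_)
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Calibrate gain/loss cutoffs from the segment log2 distribution
#'
#' Segment-level log2 ratios of a platform's cohort are tri-modal:
#' lost, neutral and gained segments each contribute a mode. A 3-component
#' Gaussian mixture is fitted by probe-count-weighted EM (quantile
#' initialization at the 10th/50th/90th percentiles, tolerance 1e-8, up to
#' 500 iterations); the gain cutoff is the point where the neutral and
#' gain component densities intersect (between their means), and the loss
#' cutoff likewise between the loss and neutral components. When the fit
#' degenerates (any component weight < 1%, non-convergence, or no
#' intersection bracket) the platform's default cutoffs are returned with
#' a warning.
#'
#' @param log2 Numeric vector of segment mean log2 ratios (>= 100 values
#'   spanning the three states).
#' @param weights Positive observation weights, typically segment probe
#'   counts; default equal weights.
#' @param model The platform's [PlatformModel] (fallback cutoffs).
#' @param maxIter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return A list with `gainCutoff`, `lossCutoff`, `model` (a copy of
#'   `model` carrying the calibrated cutoffs), `mixture` (component
#'   weights/means/sds) and `fallback` (logical).
#' @export
calibrateCutoffs <- function(log2, weights = NULL, model,
                             maxIter = 500L, tol = 1e-8) {
  stopifnot(is(model, "PlatformModel"))
  ok <- is.finite(log2)
  log2 <- log2[ok]
  if (is.null(weights)) weights <- rep(1, length(log2))
  else weights <- weights[ok]
  stopifnot(length(weights) == length(log2), all(weights > 0))
  if (length(log2) < 100L)
    stop("calibration needs >= 100 segments", call. = FALSE)
  fit <- .weightedGmm3(log2, weights, maxIter = maxIter, tol = tol)
  fallback <- function(msg) {
    warning("cutoff calibration fell back to platform defaults: ", msg,
            call. = FALSE)
    list(gainCutoff = model@gainCutoff, lossCutoff = model@lossCutoff,
         model = model, mixture = fit, fallback = TRUE)
  }
  if (!fit$converged) return(fallback("EM did not converge"))
  if (any(fit$weight < 0.01)) return(fallback("component weight < 1%"))
  gain <- .densityIntersection(fit$weight[2], fit$mean[2], fit$sd[2],
                               fit$weight[3], fit$mean[3], fit$sd[3])
  loss <- .densityIntersection(fit$weight[1], fit$mean[1], fit$sd[1],
                               fit$weight[2], fit$mean[2], fit$sd[2])
  if (is.na(gain) || is.na(loss) || !(loss < 0 && 0 < gain))
    return(fallback("no usable density intersection"))
  calibrated <- platformModel(model@family, gainCutoff = gain,
                              lossCutoff = loss,
                              ampCutoff = model@ampCutoff,
                              homdelCutoff = model@homdelCutoff)
  list(gainCutoff = gain, lossCutoff = loss, model = calibrated,
       mixture = fit, fallback = FALSE)
}

#' Calibrate the amplification cutoff against FISH/qPCR MYCN status
#'
#' Scans every midpoint between consecutive sorted MYCN-locus segment log2
#' values and returns the threshold that maximizes agreement with the
#' FISH/qPCR amplification labels (amplified iff `log2 >= cutoff`). Among
#' equally accurate thresholds the largest is returned, so high-level
#' gains stay below the cutoff.
#'
#' @param log2 MYCN-locus segment log2 ratio per sample.
#' @param amplified Logical (or "amplified"/"nonamplified") vector of
#'   FISH/qPCR status, same length.
#' @return A list with `cutoff`, `accuracy` and the scanned `candidates`
#'   data.frame.
#' @examples
#' calibrateAmpCutoff(c(2.1, 2.5, 3.0, 0.2, 0.4, 1.0),
#'                    c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))$cutoff
#' @export
calibrateAmpCutoff <- function(log2, amplified) {
  if (is.character(amplified)) amplified <- amplified == "amplified"
  stopifnot(length(log2) == length(amplified), all(is.finite(log2)))
  if (length(unique(amplified)) < 2L)
    stop("need both amplified and nonamplified samples", call. = FALSE)
  s <- sort(unique(log2))
  if (length(s) < 2L)
    stop("need at least two distinct log2 values", call. = FALSE)
  cand <- (head(s, -1L) + tail(s, -1L)) / 2
  acc <- vapply(cand, function(t)
    mean((log2 >= t) == amplified), 0.0)
  best <- max(acc)
  cutoff <- max(cand[acc == best])  # largest among ties
  list(cutoff = cutoff, accuracy = best,
       candidates = data.frame(cutoff = cand, accuracy = acc))
}

#' Call MYCN amplification status from segments
#'
#' A sample is MYCN-amplified when any called segment overlapping the
#' MYCN locus has log2 at or above the platform amplification cutoff;
#' samples with no segment covering the locus are `"unknown"`.
#'
#' @param segments A [CNSegments] object (any number of samples).
#' @param model The platform's [PlatformModel].
#' @param gene Locus as `list(chrom=, start=, end=)`; defaults to MYCN
#'   from [nbGenes()].
#' @return Named character vector ("amplified"/"nonamplified"/"unknown"),
#'   one entry per sample in `segments`.
#' @export
mycnCall <- function(segments, model, gene = NULL) {
  stopifnot(is(segments, "CNSegments"), is(model, "PlatformModel"))
  if (is.null(gene)) {
    g <- nbGenes()
    g <- g[g$gene == "MYCN", ]
    gene <- list(chrom = g$chrom, start = g$start, end = g$end)
  }
  d <- as.data.frame(segments)
  sids <- unique(d$sample_id)
  hit <- d$chrom == gene$chrom & d$start < gene$end & d$end > gene$start
  out <- setNames(rep("unknown", length(sids)), sids)
  for (sid in sids) {
    v <- d$log2_ratio[hit & d$sample_id == sid]
    if (length(v))
      out[sid] <- if (any(v >= model@ampCutoff)) "amplified"
                  else "nonamplified"
  }
  out
}

#' Per-platform concordance of called vs annotated MYCN status
#'
#' @param calls Named vector from [mycnCall()] (names are sample ids).
#' @param annotations A [SampleAnnotations] with `platform` and
#'   `mycn_status` columns.
#' @return A data.frame with one row per platform: `n_compared`,
#'   `n_unknown` (calls or annotations excluded as unknown) and
#'   `concordance` (fraction agreeing).
#' @export
mycnConcordance <- function(calls, annotations) {
  stopifnot(is(annotations, "SampleAnnotations"))
  a <- as.data.frame(annotations)
  .requireCols(a, c("platform", "mycn_status"), "annotation table")
  a <- a[a$sample_id %in% names(calls), , drop = FALSE]
  out <- lapply(split(a, a$platform), function(g) {
    cl <- calls[g$sample_id]
    known <- cl != "unknown" & g$mycn_status != "unknown" &
      !is.na(g$mycn_status)
    data.frame(platform = g$platform[1L],
               n_compared = sum(known),
               n_unknown = sum(!known),
               concordance = if (any(known))
                 mean(cl[known] == g$mycn_status[known]) else NA_real_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call a mixed-platform cohort
#'
#' Splits a segment table by each sample's platform family (from the
#' annotation table) and applies the matching platform cutoffs.
#'
#' @param segments An uncalled [CNSegments] spanning several platforms.
#' @param annotations A [SampleAnnotations] with a `platform` column.
#' @param models Optional named list of [PlatformModel] overrides per
#'   family (e.g. calibrated models); defaults to [platformModel()] for
#'   each family present.
#' @return The called [CNSegments].
#' @export
callCohort <- function(segments, annotations, models = NULL) {
  stopifnot(is(segments, "CNSegments"), is(annotations, "SampleAnnotations"))
  a <- as.data.frame(annotations)
  .requireCols(a, "platform", "annotation table")
  d <- as.data.frame(segments)
  plat <- a$platform[match(d$sample_id, a$sample_id)]
  if (anyNA(plat))
    stop("sample(s) missing from the annotation table: ",
         paste(head(unique(d$sample_id[is.na(plat)]), 5L), collapse = ", "),
         call. = FALSE)
  for (fam in unique(plat)) {
    model <- if (!is.null(models) && fam %in% names(models)) models[[fam]]
             else platformModel(fam)
    i <- plat == fam
    d$annotation[i] <- callSegment(d$log2_ratio[i], model)
  }
  CNSegments(d)
}

#' MYCN status for a mixed-platform cohort
#'
#' [mycnCall()] applied per platform family with the matching
#' amplification cutoff.
#'
#' @inheritParams callCohort
#' @param gene Locus override passed to [mycnCall()].
#' @return Named character vector of MYCN status per sample.
#' @export
mycnCohort <- function(segments, annotations, models = NULL, gene = NULL) {
  stopifnot(is(segments, "CNSegments"), is(annotations, "SampleAnnotations"))
  a <- as.data.frame(annotations)
  .requireCols(a, "platform", "annotation table")
  d <- as.data.frame(segments)
  out <- character(0)
  for (fam in unique(a$platform)) {
    sids <- a$sample_id[a$platform == fam]
    ds <- d[d$sample_id %in% sids, , drop = FALSE]
    if (nrow(ds) == 0L) next
    model <- if (!is.null(models) && fam %in% names(models)) models[[fam]]
             else platformModel(fam)
    out <- c(out, mycnCall(CNSegments(ds), model, gene = gene))
  }
  out
}
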