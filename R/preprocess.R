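#' Median-normalize probe-level profiles
#'
#' Centers each sample's log2 ratios so the per-sample median is exactly
#' zero. Idempotent; probe order and positions are untouched.
#'
#' @param probes A [CNProbes] object (one or many samples; each sample is
#'   normalized independently).
#' @return A [CNProbes] object with per-sample median-zero log2 ratios.
#' @examples
#' p <- CNProbes(data.frame(sample_id = "s1", chrom = "1",
#'                          position = 0:3 * 1e6,
#'                          log2_ratio = c(1, 2, 3, 10)))
#' as.data.frame(medianNormalize(p))$log2_ratio  # -1.5 -0.5 0.5 7.5
#' @export
medianNormalize <- function(probes) {
  stopifnot(is(probes, "CNProbes"))
  d <- as.data.frame(probes)
  for (sid in unique(d$sample_id)) {
    i <- d$sample_id == sid
    v <- d$log2_ratio[i]
    if (!any(is.finite(v)))
      stop("sample '", sid, "' has no finite log2 ratios", call. = FALSE)
    d$log2_ratio[i] <- v - median(v[is.finite(v)])
  }
  CNProbes(d)
}

#' Drop chromosome Y probes
#'
#' Y is uninterpretable when profiling did not use gender-matched
#' references, so it is removed before segmentation.
#'
#' @param probes A [CNProbes] object.
#' @return A [CNProbes] object without chrY rows.
#' @export
dropChrY <- function(probes) {
  stopifnot(is(probes, "CNProbes"))
  d <- as.data.frame(probes)
  keep <- d$chrom != "Y"
  if (!any(keep))
    warning("all probes were on chrY; returning an empty profile",
            call. = FALSE)
  CNProbes(d[keep, , drop = FALSE])
}

#' Mask recurrent platform artefact regions
#'
#' Probes that look aberrant in an implausibly large fraction of the
#' samples run on one platform, and that also show high cross-sample
#' variance, are platform artefacts rather than tumor biology. Such probes
#' are flagged and removed before segmentation.
#'
#' A probe position is masked when (i) its log2 ratio exceeds the
#' platform's gain cutoff or falls below its loss cutoff in more than
#' `recurrenceFraction` of samples, and (ii) its cross-sample variance
#' exceeds the `varianceQuantile` quantile of all probe variances.
#'
#' @param probes A [CNProbes] object holding all samples of one platform,
#'   on a shared probe grid.
#' @param model The platform's [PlatformModel] (for the gain/loss cutoffs).
#' @param recurrenceFraction Fraction of samples above which recurrent
#'   aberration is considered artefactual (default 0.20).
#' @param varianceQuantile Cross-sample variance quantile a probe must
#'   exceed to be masked (default 0.95).
#' @return A list with `probes` (the masked [CNProbes]), `maskedProbes`
#'   (data.frame of flagged positions with recurrence and variance) and
#'   `maskedRegions` (flagged positions merged into regions, BED-ready
#'   columns `chrom`, `start`, `end`).
#' @export
maskArtefacts <- function(probes, model, recurrenceFraction = 0.20,
                          varianceQuantile = 0.95) {
  stopifnot(is(probes, "CNProbes"), is(model, "PlatformModel"))
  d <- as.data.frame(probes)
  nSamp <- length(unique(d$sample_id))
  if (nSamp < 2L)
    stop("artefact masking needs >= 2 samples on the platform",
         call. = FALSE)
  key <- paste(d$chrom, d$position, sep = ":")
  aberr <- d$log2_ratio >= model@gainCutoff |
    d$log2_ratio <= model@lossCutoff
  frac <- tapply(aberr, key, sum) / nSamp
  v <- tapply(d$log2_ratio, key, var)
  vCut <- quantile(v, varianceQuantile, na.rm = TRUE, names = FALSE)
  flagged <- names(frac)[frac > recurrenceFraction & !is.na(v) & v > vCut]
  maskedProbes <- data.frame(
    chrom = sub(":.*", "", flagged),
    position = as.numeric(sub(".*:", "", flagged)),
    frac_aberrant = unname(frac[flagged]),
    variance = unname(v[flagged]))
  maskedProbes <- maskedProbes[order(.chromOrder(maskedProbes$chrom),
                                     maskedProbes$position), , drop = FALSE]
  rownames(maskedProbes) <- NULL
  keep <- !(key %in% flagged)
  list(probes = CNProbes(d[keep, , drop = FALSE]),
       maskedProbes = maskedProbes,
       maskedRegions = .mergeMaskRegions(maskedProbes, d))
}

## Merge flagged probe positions into regions: consecutive flagged probes
## on the shared grid become one interval spanning first to last + 1 bp.
.mergeMaskRegions <- function(maskedProbes, d) {
  if (nrow(maskedProbes) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  out <- list()
  for (ch in unique(maskedProbes$chrom)) {
    grid <- sort(unique(d$position[d$chrom == ch]))
    flagIdx <- sort(match(maskedProbes$position[maskedProbes$chrom == ch],
                          grid))
    runStart <- flagIdx[c(TRUE, diff(flagIdx) > 1L)]
    runEnd <- flagIdx[c(diff(flagIdx) > 1L, TRUE)]
    out[[ch]] <- data.frame(chrom = ch, start = grid[runStart],
                            end = grid[runEnd] + 1)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
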