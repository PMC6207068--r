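## Arm-level scoring of the recurrent segmental lesions of neuroblastoma:
## loss of 1p, 3p, 4p, 11q, 14q and gain of 1q, 2p, 17q. A lesion counts
## when an aberrant run is larger than 3 Mb, is not a whole-chromosome
## aberration and is not an amplification; centromere-spanning runs go to
## the arm holding the longer part.

.armFlagKeys <- c("loss_1p", "loss_3p", "loss_4p", "loss_11q", "loss_14q",
                  "gain_1q", "gain_2p", "gain_17q")

.segDirection <- function(annotation) {
  dir <- integer(length(annotation))
  dir[annotation == "gain"] <- 1L
  dir[annotation %in% c("loss", "homozygous_deletion")] <- -1L
  dir  # normal and amplification stay 0: amplifications never count
}

.checkCalled <- function(d) {
  if (any(!nzchar(d$annotation)))
    stop("segments are uncalled; run callSegments() first", call. = FALSE)
}

## Merge maximal runs of consecutive same-direction aberrant segments on
## one chromosome of one sample. Splitting an aberrant segment into
## adjacent same-label pieces cannot hide a lesion: merging precedes the
## length test. Returns one row per run with genomic span and covered bp.
.aberrantRuns <- function(dc) {
  dir <- .segDirection(dc$annotation)
  r <- rle(dir)
  endIdx <- cumsum(r$lengths)
  startIdx <- endIdx - r$lengths + 1L
  keep <- r$values != 0L
  if (!any(keep))
    return(data.frame(start = numeric(), end = numeric(),
                      covered = numeric(), direction = integer()))
  data.frame(
    start = dc$start[startIdx[keep]],
    end = dc$end[endIdx[keep]],
    covered = vapply(which(keep), function(k)
      sum(dc$end[startIdx[k]:endIdx[k]] - dc$start[startIdx[k]:endIdx[k]]),
      0.0),
    direction = r$values[keep])
}

#' Is an aberration a whole-chromosome aberration?
#'
#' A maximal run of same-direction aberrant segments is a
#' whole-chromosome (numerical) aberration when it covers at least
#' `coverageFraction` (default 0.95) of the chromosome's segment-covered
#' extent. Amplification segments never form runs.
#'
#' @param segments A called [CNSegments] restricted to one sample and one
#'   chromosome.
#' @param coverageFraction Required covered fraction (default 0.95).
#' @return `TRUE` iff some maximal aberrant run reaches the coverage
#'   fraction.
#' @export
isWholeChromosome <- function(segments, coverageFraction = 0.95) {
  stopifnot(is(segments, "CNSegments"))
  d <- as.data.frame(segments)
  .checkCalled(d)
  stopifnot(length(unique(d$sample_id)) <= 1L,
            length(unique(d$chrom)) <= 1L)
  if (nrow(d) == 0L) return(FALSE)
  runs <- .aberrantRuns(d)
  if (nrow(runs) == 0L) return(FALSE)
  extent <- sum(d$end - d$start)
  any(runs$covered >= coverageFraction * extent)
}

## Per-sample core: qualifying segmental runs + profile bookkeeping.
.sampleArmData <- function(ds, arms, minLength, coverageFraction) {
  runsAll <- list()
  aberrant <- ds$annotation != "normal"
  aberrantInWhole <- logical(nrow(ds))
  for (ch in unique(ds$chrom)) {
    sel <- ds$chrom == ch
    dc <- ds[sel, , drop = FALSE]
    runs <- .aberrantRuns(dc)
    if (nrow(runs) == 0L) next
    extent <- sum(dc$end - dc$start)
    runs$whole <- runs$covered >= coverageFraction * extent
    runs$chrom <- ch
    ## mark member segments of whole-chromosome runs
    for (k in seq_len(nrow(runs))) {
      if (runs$whole[k]) {
        member <- sel & ds$start >= runs$start[k] & ds$end <= runs$end[k] &
          .segDirection(ds$annotation) == runs$direction[k]
        aberrantInWhole[member] <- TRUE
      }
    }
    runsAll[[ch]] <- runs
  }
  runs <- if (length(runsAll)) do.call(rbind, runsAll)
          else data.frame(start = numeric(), end = numeric(),
                          covered = numeric(), direction = integer(),
                          whole = logical(), chrom = character())
  segmental <- runs[(runs$end - runs$start) > minLength & !runs$whole, ,
                    drop = FALSE]
  hasAmp <- any(ds$annotation == "amplification")
  list(runs = runs, segmental = segmental,
       anyAberrant = any(aberrant),
       allAberrantWhole = all(aberrantInWhole[aberrant]) && !hasAmp,
       arms = arms)
}

.flagsFromRuns <- function(segmental, arms) {
  flags <- setNames(rep(FALSE, length(.armFlagKeys)), .armFlagKeys)
  for (k in seq_len(nrow(segmental))) {
    ov <- armOverlap(segmental$chrom[k], segmental$start[k],
                     segmental$end[k], arms)
    if (ov[["p"]] == 0 && ov[["q"]] == 0) next
    arm <- if (ov[["p"]] > ov[["q"]]) "p" else "q"
    key <- paste0(if (segmental$direction[k] > 0L) "gain_" else "loss_",
                  segmental$chrom[k], arm)
    if (key %in% names(flags)) flags[key] <- TRUE
  }
  flags
}

#' Flag the 8 recurrent segmental arm lesions per sample
#'
#' For each sample, determines the presence of loss of 1p, 3p, 4p, 11q and
#' 14q and gain of 1q, 2p and 17q. An aberration counts when a merged run
#' of same-direction aberrant segments spans more than `minLength` bp
#' (default 3 Mb), is not a whole-chromosome aberration and is not an
#' amplification; a centromere-spanning run is assigned to the arm holding
#' its longer part (ties to q). Homozygous deletions count toward loss.
#'
#' @param segments A called [CNSegments] (any number of samples).
#' @param arms Arm table, defaults to [hg19Arms()].
#' @param minLength Minimum genomic span, exclusive (default 3e6).
#' @param coverageFraction Whole-chromosome coverage threshold passed to
#'   the run test (default 0.95).
#' @return A data.frame with one row per sample: the 8 logical flag
#'   columns, `any_segmental` (any of the 8 flags), `any_segmental_all`
#'   (a qualifying segmental aberration on any arm, flagged or not) and
#'   `profile_class` ("segmental", "numerical_only" or "silent").
#' @export
segmentalFlags <- function(segments, arms = hg19Arms(), minLength = 3e6,
                           coverageFraction = 0.95) {
  stopifnot(is(segments, "CNSegments"))
  d <- as.data.frame(segments)
  .checkCalled(d)
  out <- lapply(unique(d$sample_id), function(sid) {
    ds <- d[d$sample_id == sid, , drop = FALSE]
    info <- .sampleArmData(ds, arms, minLength, coverageFraction)
    flags <- .flagsFromRuns(info$segmental, arms)
    cls <- if (!info$anyAberrant) "silent"
           else if (info$allAberrantWhole) "numerical_only"
           else "segmental"
    cbind(data.frame(sample_id = sid),
          as.data.frame(as.list(flags)),
          data.frame(any_segmental = any(flags),
                     any_segmental_all = nrow(info$segmental) > 0L,
                     profile_class = cls))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify a copy-number profile
#'
#' `"silent"` when no aberrant segment exists, `"numerical_only"` when
#' every aberrant segment belongs to a whole-chromosome aberration, else
#' `"segmental"`.
#'
#' @inheritParams segmentalFlags
#' @return Named character vector, one class per sample.
#' @export
classifyProfile <- function(segments, arms = hg19Arms(),
                            coverageFraction = 0.95) {
  f <- segmentalFlags(segments, arms, coverageFraction = coverageFraction)
  setNames(f$profile_class, f$sample_id)
}

#' Focal aberrations over known neuroblastoma genes
#'
#' Reports every aberrant segment shorter than `maxLength` (default 5 Mb)
#' that overlaps a gene interval, e.g. focal gains or amplifications of
#' ALK or LIN28B.
#'
#' @param segments A called [CNSegments].
#' @param genes Gene table (`gene`, `chrom`, `start`, `end`); defaults to
#'   [nbGenes()].
#' @param maxLength Exclusive focal length bound in bp (default 5e6).
#' @return A data.frame with columns `sample_id`, `gene`, `annotation`,
#'   `chrom`, `start`, `end`, `log2_ratio` (zero rows when nothing
#'   qualifies).
#' @export
focalAberrations <- function(segments, genes = nbGenes(),
                             maxLength = 5e6) {
  stopifnot(is(segments, "CNSegments"))
  d <- as.data.frame(segments)
  .checkCalled(d)
  d <- d[d$annotation != "normal" & (d$end - d$start) < maxLength, ,
         drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    hit <- d$chrom == g$chrom & d$start < g$end & d$end > g$start
    if (any(hit))
      out[[length(out) + 1L]] <- data.frame(
        sample_id = d$sample_id[hit], gene = g$gene,
        annotation = d$annotation[hit], chrom = d$chrom[hit],
        start = d$start[hit], end = d$end[hit],
        log2_ratio = d$log2_ratio[hit])
  }
  if (!length(out))
    return(data.frame(sample_id = character(), gene = character(),
                      annotation = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      log2_ratio = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$sample_id, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}
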