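#' Probe-level copy-number table
#'
#' One row per array probe: `sample_id`, `chrom` (1-22, X, Y), `position`
#' (bp, 0-based), `log2_ratio`. Rows are kept sorted by (sample, chrom,
#' position); duplicate positions within a sample/chromosome are rejected.
#'
#' @param data A data.frame with columns `sample_id`, `chrom`, `position`,
#'   `log2_ratio`. Chromosome names may carry a "chr" prefix; rows are
#'   sorted on construction (with a warning if they arrived unsorted).
#' @return A `CNProbes` object.
#' @seealso [readProbes()], [medianNormalize()], [segmentProfile()]
#' @name CNProbes-class
#' @aliases CNProbes
#' @export
CNProbes <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("sample_id", "chrom", "position", "log2_ratio")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("probe table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  data <- data[need]
  data$sample_id <- as.character(data$sample_id)
  data$chrom <- .normChrom(data$chrom)
  data$position <- as.numeric(data$position)
  data$log2_ratio <- as.numeric(data$log2_ratio)
  o <- order(data$sample_id, .chromOrder(data$chrom), data$position)
  if (!identical(o, seq_len(nrow(data)))) {
    warning("probe table was not sorted; sorting by (sample, chrom, position)",
            call. = FALSE)
    data <- data[o, , drop = FALSE]
  }
  rownames(data) <- NULL
  new("CNProbes", data = data)
}

#' Segment-level copy-number table
#'
#' One row per constant-copy-number segment: `sample_id`, `chrom`, `start`,
#' `end` (bp, 0-based half-open), `n_probes`, `log2_ratio` (mean of member
#' probes) and `annotation` (a call label from [callLevels()], or `""` when
#' not yet called). Segments are sorted and non-overlapping within each
#' sample/chromosome.
#'
#' @param data A data.frame with the columns above (`annotation` optional,
#'   defaults to `""`).
#' @return A `CNSegments` object.
#' @seealso [readSegments()], [callSegments()], [segmentalFlags()]
#' @name CNSegments-class
#' @aliases CNSegments
#' @export
CNSegments <- function(data) {
  stopifnot(is.data.frame(data))
  if (!"annotation" %in% names(data)) data$annotation <- ""
  need <- c("sample_id", "chrom", "start", "end", "n_probes",
            "log2_ratio", "annotation")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("segment table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  data <- data[need]
  data$sample_id <- as.character(data$sample_id)
  data$chrom <- .normChrom(data$chrom)
  data$start <- as.numeric(data$start)
  data$end <- as.numeric(data$end)
  data$n_probes <- as.integer(data$n_probes)
  data$log2_ratio <- as.numeric(data$log2_ratio)
  data$annotation <- as.character(data$annotation)
  data <- data[order(data$sample_id, .chromOrder(data$chrom), data$start), ,
               drop = FALSE]
  rownames(data) <- NULL
  new("CNSegments", data = data)
}

#' Patient / sample annotation table
#'
#' Carries per-sample metadata: `sample_id`, `platform` (a family from
#' [platformFamilies()]), optionally `lab`, `mycn_status` ("amplified",
#' "nonamplified" or "unknown"), `stage`, `age_group`, survival columns
#' `os_time`/`os_event` and `efs_time`/`efs_event` (missing allowed), and
#' optional pre-computed arm-flag columns.
#'
#' @param data A data.frame with at least `sample_id`.
#' @return A `SampleAnnotations` object.
#' @seealso [readAnnotations()], [stratifyByFlag()]
#' @name SampleAnnotations-class
#' @aliases SampleAnnotations
#' @export
SampleAnnotations <- function(data) {
  stopifnot(is.data.frame(data))
  if (!"sample_id" %in% names(data))
    stop("annotation table missing column: sample_id", call. = FALSE)
  data$sample_id <- as.character(data$sample_id)
  if ("mycn_status" %in% names(data)) {
    bad <- !(data$mycn_status %in% c("amplified", "nonamplified", "unknown",
                                     NA))
    if (any(bad))
      stop("invalid mycn_status value(s): ",
           paste(unique(data$mycn_status[bad]), collapse = ", "),
           call. = FALSE)
  }
  rownames(data) <- NULL
  new("SampleAnnotations", data = data)
}

#' Synthetic cohort with ground truth
#'
#' Returned by [simulateCohort()]: the noisy probe table, the noiseless
#' truth segments, sample annotations (MYCN status from truth, survival),
#' the per-sample list of true aberrations (`truth`), the true arm flags
#' (`truthFlags`) and the generating configuration.
#'
#' @name SyntheticCohort-class
#' @aliases SyntheticCohort
#' @seealso [simulateCohort()], [simulationConfig()]
NULL

## ---- as.data.frame / accessors -------------------------------------------

#' @export
setMethod("as.data.frame", "CNProbes",
          function(x, ...) x@data)
#' @export
setMethod("as.data.frame", "CNSegments",
          function(x, ...) x@data)
#' @export
setMethod("as.data.frame", "SampleAnnotations",
          function(x, ...) x@data)

#' @rdname accessors
#' @export
setMethod("sampleIds", "CNProbes",
          function(x) unique(x@data$sample_id))
#' @rdname accessors
#' @export
setMethod("sampleIds", "CNSegments",
          function(x) unique(x@data$sample_id))
#' @rdname accessors
#' @export
setMethod("sampleIds", "SampleAnnotations",
          function(x) x@data$sample_id)
#' @rdname accessors
#' @export
setMethod("sampleIds", "SyntheticCohort",
          function(x) sampleIds(x@annotations))

#' @rdname accessors
#' @export
setMethod("nSamples", "ANY", function(x) length(sampleIds(x)))

#' @export
setMethod("nrow", "CNProbes", function(x) nrow(x@data))
#' @export
setMethod("nrow", "CNSegments", function(x) nrow(x@data))

## ---- SyntheticCohort accessors -------------------------------------------

#' @rdname SyntheticCohort-class
#' @param x A `SyntheticCohort`.
#' @export
cohortProbes <- function(x) x@probes

#' @rdname SyntheticCohort-class
#' @export
truthSegments <- function(x) x@truthSegments

#' @rdname SyntheticCohort-class
#' @export
cohortAnnotations <- function(x) x@annotations

#' @rdname SyntheticCohort-class
#' @export
truthAberrations <- function(x) x@truth

#' @rdname SyntheticCohort-class
#' @export
truthFlags <- function(x) x@truthFlags

## ---- show ----------------------------------------------------------------

setMethod("show", "CNProbes", function(object) {
  d <- object@data
  cat(sprintf("CNProbes: %d probes, %d sample(s), %d chromosome(s)\n",
              nrow(d), length(unique(d$sample_id)),
              length(unique(d$chrom))))
  if (nrow(d)) print(head(d, 4L))
})

setMethod("show", "CNSegments", function(object) {
  d <- object@data
  called <- sum(nzchar(d$annotation))
  cat(sprintf("CNSegments: %d segments, %d sample(s)%s\n",
              nrow(d), length(unique(d$sample_id)),
              if (called) sprintf(", %d called", called) else " (uncalled)"))
  if (nrow(d)) print(head(d, 4L))
})

setMethod("show", "SampleAnnotations", function(object) {
  d <- object@data
  cat(sprintf("SampleAnnotations: %d sample(s); columns: %s\n",
              nrow(d), paste(names(d), collapse = ", ")))
})

setMethod("show", "PlatformModel", function(object) {
  cat(sprintf(
    "PlatformModel <%s>: gain >= %+.3g, loss <= %+.3g, amp >= %+.3g, homdel < %+.3g\n",
    object@family, object@gainCutoff, object@lossCutoff,
    object@ampCutoff, object@homdelCutoff))
  cat(sprintf("  simulation: probe noise sd %.3g, amplification center %.3g\n",
              object@noiseSd, object@ampCenter))
})

setMethod("show", "SyntheticCohort", function(object) {
  tab <- table(object@truthFlags$archetype)
  cat(sprintf("SyntheticCohort: %d samples (%s)\n",
              nSamples(object),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  %d probes, %d truth segments\n",
              nrow(object@probes), nrow(object@truthSegments)))
})
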