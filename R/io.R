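## Readers/writers for the tables the pipeline touches. Native dialect is
## headered TSV with 0-based half-open coordinates; IGV SEG is supported
## for interoperability (1-based inclusive, no annotation column).

.requireCols <- function(d, need, what) {
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(what, " is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Read a segment table
#'
#' @param path Path to a TSV file.
#' @param dialect `"native"` (columns `sample_id`, `chrom`, `start`, `end`,
#'   `n_probes`, `log2_ratio`, `annotation`; 0-based half-open) or `"seg"`
#'   (IGV SEG: `ID`, `chrom`, `loc.start`, `loc.end`, `num.mark`,
#'   `seg.mean`; 1-based inclusive).
#' @param labelMap Optional named character vector translating the file's
#'   annotation vocabulary to [callLevels()] (external deposits use
#'   unspecified label strings); names are file values, values are call
#'   labels. Unmapped non-empty values are an error.
#' @return A [CNSegments] object.
#' @seealso [writeSegments()]
#' @export
readSegments <- function(path, dialect = c("native", "seg"),
                         labelMap = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- read.delim(path, colClasses = "character", check.names = FALSE)
  if (dialect == "native") {
    .requireCols(d, c("sample_id", "chrom", "start", "end", "n_probes",
                      "log2_ratio"), "segment table")
    if (!"annotation" %in% names(d)) d$annotation <- ""
  } else {
    .requireCols(d, c("ID", "chrom", "loc.start", "loc.end", "num.mark",
                      "seg.mean"), "SEG file")
    d <- data.frame(sample_id = d$ID, chrom = d$chrom,
                    start = as.numeric(d$loc.start) - 1,
                    end = as.numeric(d$loc.end),
                    n_probes = d$num.mark, log2_ratio = d$seg.mean,
                    annotation = "", check.names = FALSE)
  }
  d$start <- as.numeric(d$start); d$end <- as.numeric(d$end)
  d$n_probes <- as.integer(d$n_probes)
  d$log2_ratio <- as.numeric(d$log2_ratio)
  if (!is.null(labelMap)) {
    nz <- nzchar(d$annotation)
    mapped <- labelMap[d$annotation[nz]]
    if (anyNA(mapped))
      stop("annotation value(s) not covered by labelMap: ",
           paste(unique(d$annotation[nz][is.na(mapped)]), collapse = ", "),
           call. = FALSE)
    d$annotation[nz] <- unname(mapped)
  }
  bad <- nzchar(d$annotation) & !(d$annotation %in% callLevels())
  if (any(bad))
    stop("unknown annotation label(s): ",
         paste(unique(d$annotation[bad]), collapse = ", "),
         "; supply a labelMap", call. = FALSE)
  CNSegments(d)
}

#' Write a segment table
#'
#' Native TSV round-trips bit-stable through [readSegments()]. SEG export
#' converts to 1-based inclusive coordinates and drops the annotation
#' column (IGV SEG has no such field).
#'
#' @param segments A [CNSegments] object.
#' @param path Output path.
#' @param dialect `"native"` or `"seg"`.
#' @return `path`, invisibly.
#' @export
writeSegments <- function(segments, path, dialect = c("native", "seg")) {
  dialect <- match.arg(dialect)
  stopifnot(is(segments, "CNSegments"))
  d <- as.data.frame(segments)
  if (dialect == "seg") {
    d <- data.frame(ID = d$sample_id, chrom = d$chrom,
                    `loc.start` = format(d$start + 1, scientific = FALSE,
                                         trim = TRUE),
                    `loc.end` = format(d$end, scientific = FALSE,
                                       trim = TRUE),
                    `num.mark` = d$n_probes, `seg.mean` = d$log2_ratio,
                    check.names = FALSE)
  } else {
    d$start <- format(d$start, scientific = FALSE, trim = TRUE)
    d$end <- format(d$end, scientific = FALSE, trim = TRUE)
  }
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-level table
#'
#' Expects TSV columns `sample_id`, `chrom`, `position`, `log2_ratio`.
#' Out-of-order rows are sorted on load with a warning.
#'
#' @param path Path to a TSV file.
#' @return A [CNProbes] object.
#' @export
readProbes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- read.delim(path, check.names = FALSE)
  .requireCols(d, c("sample_id", "chrom", "position", "log2_ratio"),
               "probe table")
  CNProbes(d)
}

#' Write a probe-level table
#'
#' @param probes A [CNProbes] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeProbes <- function(probes, path) {
  stopifnot(is(probes, "CNProbes"))
  d <- as.data.frame(probes)
  d$position <- format(d$position, scientific = FALSE, trim = TRUE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Expects TSV with at least `sample_id` and `platform`; recognised
#' optional columns are `lab`, `mycn_status`, `stage`, `age_group`,
#' `os_time`, `os_event`, `efs_time`, `efs_event` and arm-flag columns.
#'
#' @param path Path to a TSV file.
#' @return A [SampleAnnotations] object.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- read.delim(path, check.names = FALSE)
  .requireCols(d, c("sample_id", "platform"), "annotation table")
  SampleAnnotations(d)
}

#' Write an annotation table
#'
#' @param annotations A [SampleAnnotations] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(annotations, path) {
  stopifnot(is(annotations, "SampleAnnotations"))
  write.table(as.data.frame(annotations), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Export called segments as BED
#'
#' Writes 0-based half-open BED with the call label in the name column and
#' the segment mean log2 ratio in the score column. By default only
#' aberrant (non-`normal`) segments are written.
#'
#' @param segments A called [CNSegments] object.
#' @param path Output path.
#' @param includeNormal Write `normal` segments too? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
writeBed <- function(segments, path, includeNormal = FALSE) {
  stopifnot(is(segments, "CNSegments"))
  d <- as.data.frame(segments)
  if (!all(nzchar(d$annotation)))
    stop("segments are uncalled; run callSegments() first", call. = FALSE)
  if (!includeNormal) d <- d[d$annotation != "normal", , drop = FALSE]
  bed <- data.frame(chrom = d$chrom,
                    start = format(d$start, scientific = FALSE, trim = TRUE),
                    end = format(d$end, scientific = FALSE, trim = TRUE),
                    name = paste(d$sample_id, d$annotation, sep = "|"),
                    score = d$log2_ratio)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file written by [writeBed()]
#'
#' @param path Path to a BED file.
#' @return A data.frame with columns `chrom`, `start`, `end`, `sample_id`,
#'   `annotation`, `log2_ratio`.
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- read.delim(path, header = FALSE,
                  col.names = c("chrom", "start", "end", "name", "score"))
  parts <- strsplit(as.character(d$name), "|", fixed = TRUE)
  data.frame(chrom = .normChrom(d$chrom),
             start = as.numeric(d$start), end = as.numeric(d$end),
             sample_id = vapply(parts, `[`, "", 1L),
             annotation = vapply(parts, `[`, "", 2L),
             log2_ratio = as.numeric(d$score))
}
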