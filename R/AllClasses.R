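## Central S4 containers. Coordinates are 0-based half-open everywhere
## inside the package; 1-based inclusive only on SEG export.

#' Call labels, ordered from deepest loss to highest gain
#'
#' @return Character vector of the five call labels in dosage order.
#' @export
callLevels <- function() {
  c("homozygous_deletion", "loss", "normal", "gain", "amplification")
}

#' Supported array platform families
#'
#' @return Character vector of the four platform family identifiers.
#' @export
platformFamilies <- function() {
  c("affymetrix_snp", "illumina_snp", "agilent_acgh", "nimblegen_acgh")
}

.validChroms <- function() c(as.character(1:22), "X", "Y")

## Normalize chromosome names: strip "chr" prefix, uppercase X/Y.
.normChrom <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  x <- toupper(x)
  bad <- !(x %in% .validChroms())
  if (any(bad)) {
    stop("unknown chromosome name(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  x
}

.chromOrder <- function(x) match(x, .validChroms())

#' @rdname CNProbes-class
#' @export
setClass("CNProbes", representation(data = "data.frame"))

#' @rdname CNSegments-class
#' @export
setClass("CNSegments", representation(data = "data.frame"))

#' @rdname SampleAnnotations-class
#' @export
setClass("SampleAnnotations", representation(data = "data.frame"))

#' @rdname PlatformModel-class
#' @export
setClass("PlatformModel",
  representation(
    family      = "character",
    gainCutoff  = "numeric",
    lossCutoff  = "numeric",
    ampCutoff   = "numeric",
    homdelCutoff = "numeric",
    noiseSd     = "numeric",
    ampCenter   = "numeric",
    gainMean    = "numeric",
    lossMean    = "numeric"
  )
)

#' @rdname SyntheticCohort-class
#' @export
setClass("SyntheticCohort",
  representation(
    probes        = "CNProbes",
    truthSegments = "CNSegments",
    annotations   = "SampleAnnotations",
    truth         = "data.frame",
    truthFlags    = "data.frame",
    config        = "list"
  )
)

setValidity("CNProbes", function(object) {
  d <- object@data
  need <- c("sample_id", "chrom", "position", "log2_ratio")
  if (!all(need %in% names(d)))
    return(paste("missing column(s):",
                 paste(setdiff(need, names(d)), collapse = ", ")))
  if (nrow(d) == 0L) return(TRUE)
  if (!all(d$chrom %in% .validChroms())) return("invalid chromosome names")
  if (anyNA(d$position) || any(d$position < 0))
    return("positions must be non-negative")
  key <- paste(d$sample_id, d$chrom)
  o <- order(d$sample_id, .chromOrder(d$chrom), d$position)
  if (is.unsorted(o) && !identical(o, seq_len(nrow(d))))
    return("probes must be sorted by (sample, chrom, position)")
  dup <- duplicated(paste(key, d$position))
  if (any(dup))
    return(paste("duplicate probe position(s), e.g. row",
                 which(dup)[1L]))
  TRUE
})

setValidity("CNSegments", function(object) {
  d <- object@data
  need <- c("sample_id", "chrom", "start", "end", "n_probes",
            "log2_ratio", "annotation")
  if (!all(need %in% names(d)))
    return(paste("missing column(s):",
                 paste(setdiff(need, names(d)), collapse = ", ")))
  if (nrow(d) == 0L) return(TRUE)
  if (!all(d$chrom %in% .validChroms())) return("invalid chromosome names")
  if (any(d$end <= d$start)) return("segment end must exceed start")
  if (any(d$n_probes < 1L)) return("n_probes must be >= 1")
  if (any(!is.finite(d$log2_ratio))) return("log2_ratio must be finite")
  ## sorted, non-overlapping within sample/chrom
  sp <- split(seq_len(nrow(d)), paste(d$sample_id, d$chrom))
  for (idx in sp) {
    s <- d$start[idx]; e <- d$end[idx]
    if (is.unsorted(s, strictly = FALSE))
      return("segments must be sorted by start within sample/chrom")
    if (length(idx) > 1L) {
      ov <- which(s[-1L] < e[-length(e)])
      if (length(ov))
        return(sprintf("overlapping segments at rows %d and %d",
                       idx[ov[1L]], idx[ov[1L] + 1L]))
    }
  }
  TRUE
})

setValidity("SampleAnnotations", function(object) {
  d <- object@data
  if (!"sample_id" %in% names(d)) return("missing column: sample_id")
  if (anyDuplicated(d$sample_id)) return("sample_ids must be unique")
  for (tc in intersect(c("os_time", "efs_time"), names(d))) {
    v <- d[[tc]]
    if (any(v < 0, na.rm = TRUE))
      return(paste(tc, "must be non-negative"))
  }
  for (ec in intersect(c("os_event", "efs_event"), names(d))) {
    v <- d[[ec]]
    if (!all(v %in% c(0, 1, NA)))
      return(paste(ec, "must be 0/1"))
  }
  TRUE
})

setValidity("PlatformModel", function(object) {
  if (!(object@lossCutoff < 0 && 0 < object@gainCutoff))
    return("need lossCutoff < 0 < gainCutoff")
  if (!(object@gainCutoff < object@ampCutoff))
    return("need gainCutoff < ampCutoff")
  if (!(object@homdelCutoff < object@lossCutoff))
    return("need homdelCutoff < lossCutoff")
  TRUE
})
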