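## hg19 chromosome/arm geometry. The arm table ships as TSV under
## inst/extdata and is cached per session. chrY is deliberately absent:
## profiles without gender-matched references make Y uninterpretable.

.armEnv <- new.env(parent = emptyenv())

#' hg19 chromosome-arm table
#'
#' Chromosome lengths and centromere intervals for chromosomes 1-22 and X
#' (hg19, from the UCSC cytoBand acen bands). The p arm spans
#' `[0, cen_start)`, the q arm `[cen_end, length)`; chrY is excluded.
#'
#' @return A data.frame with columns `chrom`, `length`, `cen_start`,
#'   `cen_end` (bp, 0-based half-open).
#' @examples
#' arms <- hg19Arms()
#' subset(arms, chrom == "17")
#' @export
hg19Arms <- function() {
  if (is.null(.armEnv$arms)) {
    path <- system.file("extdata", "hg19_arms.tsv", package = "armcall",
                        mustWork = TRUE)
    a <- read.delim(path, colClasses = c("character", rep("numeric", 3L)))
    stopifnot(
      nrow(a) == 23L,
      !"Y" %in% a$chrom,
      all(a$cen_start > 0),
      all(a$cen_start <= a$cen_end),
      all(a$cen_end < a$length)
    )
    .armEnv$arms <- a
  }
  .armEnv$arms
}

#' Neuroblastoma-relevant gene coordinates (hg19)
#'
#' Small built-in table of loci recurrently hit by focal aberrations in
#' neuroblastoma: MYCN, ALK, LIN28B, CHD5 and ODC1.
#'
#' @return A data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @examples
#' nbGenes()
#' @export
nbGenes <- function() {
  path <- system.file("extdata", "hg19_genes.tsv", package = "armcall",
                      mustWork = TRUE)
  g <- read.delim(path, colClasses = c("character", "character",
                                       "numeric", "numeric"))
  stopifnot(all(g$start < g$end),
            all(g$chrom %in% hg19Arms()$chrom),
            all(c("MYCN", "ALK", "LIN28B", "CHD5", "ODC1") %in% g$gene))
  g
}

.armRow <- function(chrom, arms) {
  i <- match(.normChrom(chrom), arms$chrom)
  if (is.na(i))
    stop("chromosome '", chrom, "' not in arm table", call. = FALSE)
  arms[i, ]
}

#' Overlap of an interval with the p and q arms
#'
#' Computes how much of a genomic interval falls on the p arm
#' (`[0, cen_start)`) and on the q arm (`[cen_end, length)`). Bases inside
#' the centromere interval count toward neither arm.
#'
#' @param chrom Chromosome name ("1".."22", "X"; "chr" prefix accepted).
#' @param start,end Interval bounds, 0-based half-open, `end > start`.
#' @param arms Arm table, defaults to [hg19Arms()].
#' @return Named numeric vector `c(p = ..., q = ...)` in bp.
#' @examples
#' armOverlap("11", 5e7, 9e7)
#' @export
armOverlap <- function(chrom, start, end, arms = hg19Arms()) {
  stopifnot(is.numeric(start), is.numeric(end))
  if (end <= start) stop("end must exceed start", call. = FALSE)
  a <- .armRow(chrom, arms)
  p <- max(0, min(end, a$cen_start) - max(start, 0))
  q <- max(0, min(end, a$length) - max(start, a$cen_end))
  c(p = p, q = q)
}

#' Assign an interval to a chromosome arm
#'
#' A centromere-spanning aberration is assigned to the p arm if its portion
#' on p is longer, and to the q arm otherwise (ties go to q).
#'
#' @inheritParams armOverlap
#' @return `"p"` or `"q"`.
#' @examples
#' assignArm("17", 3e7, 8e7)  # "q"
#' @export
assignArm <- function(chrom, start, end, arms = hg19Arms()) {
  ov <- armOverlap(chrom, start, end, arms)
  if (ov[["p"]] == 0 && ov[["q"]] == 0)
    stop("interval lies entirely within the centromere gap", call. = FALSE)
  if (ov[["p"]] > ov[["q"]]) "p" else "q"
}
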