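## Cohort-level summaries: genome-wide gain/loss frequency tracks,
## window/gene region matrices, lesion co-occurrence tests and the
## silent / near-silent QC partition.

.gainClass <- c("gain", "amplification")
.lossClass <- c("loss", "homozygous_deletion")

.tileGenome <- function(windowSize, arms) {
  out <- lapply(seq_len(nrow(arms)), function(i) {
    starts <- seq(0, arms$length[i] - 1, by = windowSize)
    data.frame(chrom = arms$chrom[i], start = starts,
               end = pmin(starts + windowSize, arms$length[i]))
  })
  do.call(rbind, out)
}

.segGRanges <- function(d) {
  GRanges(d$chrom, IRanges(d$start + 1, d$end))  # to 1-based closed
}

#' Genome-wide aberration frequency track
#'
#' For fixed genomic windows, the fraction of samples carrying an
#' overlapping gain-class (gain or amplification) and loss-class (loss or
#' homozygous deletion) segment. Both fractions can be non-zero in the
#' same window; they are independent proportions.
#'
#' @param segments A called [CNSegments] with at least one sample.
#' @param windowSize Window width in bp (default 1e6).
#' @param arms Arm table, defaults to [hg19Arms()].
#' @return A data.frame `chrom`, `start`, `end`, `gain_freq`, `loss_freq`.
#' @export
aberrationFrequency <- function(segments, windowSize = 1e6,
                                arms = hg19Arms()) {
  stopifnot(is(segments, "CNSegments"))
  if (windowSize <= 0) stop("windowSize must be positive", call. = FALSE)
  d <- as.data.frame(segments)
  .checkCalled(d)
  if (nrow(d) == 0L) stop("empty cohort", call. = FALSE)
  n <- length(unique(d$sample_id))
  win <- .tileGenome(windowSize, arms)
  winGR <- GRanges(win$chrom, IRanges(win$start + 1, win$end))
  freq <- function(dd) {
    if (nrow(dd) == 0L) return(numeric(nrow(win)))
    hits <- findOverlaps(winGR, .segGRanges(dd))
    cnt <- tapply(dd$sample_id[subjectHits(hits)], queryHits(hits),
                  function(s) length(unique(s)))
    out <- numeric(nrow(win))
    out[as.integer(names(cnt))] <- cnt
    out / n
  }
  win$gain_freq <- freq(d[d$annotation %in% .gainClass, , drop = FALSE])
  win$loss_freq <- freq(d[d$annotation %in% .lossClass, , drop = FALSE])
  win
}

#' Export a frequency track as bedGraph
#'
#' @param freq Output of [aberrationFrequency()].
#' @param path Output path; two tracks (gain, loss) separated by track
#'   lines.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(freq, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (what in c("gain_freq", "loss_freq")) {
    writeLines(sprintf('track type=bedGraph name="%s"', what), con)
    write.table(data.frame(freq$chrom,
                           format(freq$start, scientific = FALSE,
                                  trim = TRUE),
                           format(freq$end, scientific = FALSE,
                                  trim = TRUE),
                           freq[[what]]),
                con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

## Precedence for the label cell of a region matrix: the label furthest
## from normal wins (amplification, then homozygous deletion, gain, loss).
.labelPrecedence <- c(amplification = 4L, homozygous_deletion = 3L,
                      gain = 2L, loss = 1L, normal = 0L)

#' Sample-by-region matrices of copy number and call labels
#'
#' Projects a called segment table onto fixed regions (windows or genes).
#' The numeric cell is the probe-count-weighted mean log2 ratio of the
#' overlapping segments (each segment weighted by the estimated number of
#' its probes inside the region, i.e. `n_probes` times its overlapped
#' fraction); the label cell is the highest-precedence overlapping call.
#' Regions without coverage are `NA`.
#'
#' @param segments A called [CNSegments].
#' @param regions A data.frame with `chrom`, `start`, `end` and optionally
#'   `gene` (or `name`) for region names; e.g. [nbGenes()] or windows.
#' @return A list with numeric matrix `log2` and character matrix `label`
#'   (rows samples, columns regions).
#' @export
regionMatrix <- function(segments, regions) {
  stopifnot(is(segments, "CNSegments"))
  d <- as.data.frame(segments)
  .checkCalled(d)
  rn <- if ("gene" %in% names(regions)) regions$gene
        else if ("name" %in% names(regions)) regions$name
        else paste0(regions$chrom, ":", regions$start, "-", regions$end)
  samples <- unique(d$sample_id)
  log2M <- matrix(NA_real_, length(samples), nrow(regions),
                  dimnames = list(samples, rn))
  labelM <- matrix(NA_character_, length(samples), nrow(regions),
                   dimnames = list(samples, rn))
  regChrom <- .normChrom(regions$chrom)
  lv <- union(unique(regChrom), unique(d$chrom))  # shared seqlevels
  regGR <- GRanges(factor(regChrom, lv),
                   IRanges(regions$start + 1, regions$end))
  segGR <- GRanges(factor(d$chrom, lv), IRanges(d$start + 1, d$end))
  hits <- findOverlaps(regGR, segGR)
  if (length(hits)) {
    ovWidth <- width(pintersect(regGR[queryHits(hits)],
                                segGR[subjectHits(hits)]))
    sh <- subjectHits(hits)
    w <- d$n_probes[sh] * ovWidth / (d$end[sh] - d$start[sh])
    df <- data.frame(region = queryHits(hits), sample = d$sample_id[sh],
                     log2 = d$log2_ratio[sh], w = w,
                     prec = .labelPrecedence[d$annotation[sh]],
                     label = d$annotation[sh])
    for (grp in split(df, paste(df$sample, df$region))) {
      i <- grp$sample[1L]; j <- grp$region[1L]
      log2M[i, j] <- weighted.mean(grp$log2, grp$w)
      labelM[i, j] <- grp$label[which.max(grp$prec)]
    }
  }
  list(log2 = log2M, label = labelM)
}

#' Exact co-occurrence test for two lesion flags
#'
#' Builds the 2x2 table of two per-sample logical flags, computes the
#' sample odds ratio (with Haldane's +0.5 correction when any cell is
#' zero) and a two-sided exact p-value from the hypergeometric
#' distribution (sum of all table probabilities no larger than the
#' observed one, at fixed margins).
#'
#' @param flagsA,flagsB Logical vectors over the same samples.
#' @return A list with `table` (2x2 counts, A rows, B columns),
#'   `oddsRatio` and `p`.
#' @export
cooccurrenceTest <- function(flagsA, flagsB) {
  stopifnot(length(flagsA) == length(flagsB), length(flagsA) >= 1L)
  flagsA <- as.logical(flagsA); flagsB <- as.logical(flagsB)
  tab <- matrix(c(sum(flagsA & flagsB), sum(flagsA & !flagsB),
                  sum(!flagsA & flagsB), sum(!flagsA & !flagsB)),
                2L, 2L, byrow = TRUE,
                dimnames = list(A = c("TRUE", "FALSE"),
                                B = c("TRUE", "FALSE")))
  n <- sum(tab)
  if (all(flagsA) || !any(flagsA) || all(flagsB) || !any(flagsB)) {
    warning("degenerate margin; co-occurrence p set to 1", call. = FALSE)
    p <- 1
  } else {
    ## two-sided exact test: P(tables with prob <= observed | margins)
    m <- sum(flagsB); nn <- n - m; k <- sum(flagsA)
    support <- max(0L, k - nn):min(k, m)
    probs <- dhyper(support, m, nn, k)
    pObs <- dhyper(tab[1L, 1L], m, nn, k)
    p <- min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
  }
  t2 <- tab
  if (any(tab == 0L)) t2 <- tab + 0.5  # Haldane correction
  orr <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(table = tab, oddsRatio = orr, p = p)
}

#' Co-occurrence across all pairs of the 8 arm-lesion flags
#'
#' Runs [cooccurrenceTest()] on each of the 28 flag pairs and adds
#' Benjamini-Hochberg adjusted q-values.
#'
#' @param flags Output of [segmentalFlags()].
#' @return A data.frame with one row per pair: `flag_a`, `flag_b`, the
#'   2x2 counts (`n11`, `n10`, `n01`, `n00`), `odds_ratio`, `p`, `q`.
#' @export
armCooccurrence <- function(flags) {
  stopifnot(all(.armFlagKeys %in% names(flags)))
  pairs <- utils::combn(.armFlagKeys, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    ct <- suppressWarnings(cooccurrenceTest(flags[[a]], flags[[b]]))
    data.frame(flag_a = a, flag_b = b,
               n11 = ct$table[1, 1], n10 = ct$table[1, 2],
               n01 = ct$table[2, 1], n00 = ct$table[2, 2],
               odds_ratio = ct$oddsRatio, p = ct$p)
  })
  res <- do.call(rbind, out)
  res$q <- p.adjust(res$p, method = "BH")
  res
}

#' Silent / near-silent quality-control partition
#'
#' Profiles with no called aberration are `silent`; profiles whose total
#' aberrant genomic length stays under `minAberrantLength` (default
#' 10 Mb) are `near_silent`; the remainder is `retained`. Silent and
#' near-silent profiles are the signature of normal-cell contamination
#' and are typically excluded from cohort statistics.
#'
#' @param segments A called [CNSegments].
#' @param minAberrantLength Total aberrant bp below which a non-silent
#'   profile is near-silent (default 1e7).
#' @param arms Arm table, defaults to [hg19Arms()].
#' @return A list with `classes` (named character per sample) and
#'   `counts` (table over retained / near_silent / silent).
#' @export
qcPartition <- function(segments, minAberrantLength = 1e7,
                        arms = hg19Arms()) {
  stopifnot(is(segments, "CNSegments"))
  d <- as.data.frame(segments)
  .checkCalled(d)
  cls <- vapply(unique(d$sample_id), function(sid) {
    ds <- d[d$sample_id == sid, , drop = FALSE]
    ab <- ds$annotation != "normal"
    if (!any(ab)) return("silent")
    if (sum(ds$end[ab] - ds$start[ab]) < minAberrantLength)
      return("near_silent")
    "retained"
  }, "")
  counts <- table(factor(cls, levels = c("retained", "near_silent",
                                         "silent")))
  list(classes = cls, counts = counts)
}

#' Cohort summary of segmental-lesion burden
#'
#' Reports the fraction of samples carrying any segmental aberration,
#' under both readings: any of the 8 recurrent arm flags
#' (`pct_segmental_8arms`) and a qualifying segmental aberration on any
#' arm (`pct_segmental_any_arm`); per-flag frequencies; and, when an
#' annotation table with `mycn_status` is supplied, MYCN-status by flag
#' cross-tabulations.
#'
#' @param flags Output of [segmentalFlags()].
#' @param annotations Optional [SampleAnnotations] with `mycn_status`.
#' @return A list with `n`, `pct_segmental_8arms`, `pct_segmental_any_arm`
#'   (percent scale), `flag_freq` (named fractions), `profile_classes`
#'   (table) and optionally `mycn_crosstab`.
#' @export
cohortSummary <- function(flags, annotations = NULL) {
  if (nrow(flags) == 0L) stop("empty cohort", call. = FALSE)
  res <- list(
    n = nrow(flags),
    pct_segmental_8arms = 100 * mean(flags$any_segmental),
    pct_segmental_any_arm = 100 * mean(flags$any_segmental_all),
    flag_freq = vapply(flags[.armFlagKeys], mean, 0.0),
    profile_classes = table(factor(flags$profile_class,
                                   levels = c("segmental",
                                              "numerical_only",
                                              "silent"))))
  if (!is.null(annotations)) {
    a <- as.data.frame(annotations)
    if ("mycn_status" %in% names(a)) {
      m <- a$mycn_status[match(flags$sample_id, a$sample_id)]
      res$mycn_crosstab <- lapply(
        setNames(.armFlagKeys, .armFlagKeys),
        function(k) table(mycn = m, flag = flags[[k]]))
    }
  }
  res
}
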