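## Automatic penalized changepoint segmentation. Each chromosome of each
## sample is partitioned exactly (optimal partitioning, O(n^2) dynamic
## programming in C++) to minimize
##     sum over segments of within-segment SSE + penalty * n_segments.
## This is a deterministic, headless replacement for interactive
## segmentation tools; externally produced segment tables are equally
## accepted downstream via readSegments().

#' Data-driven segmentation penalty
#'
#' A BIC-flavoured penalty `2 * sigma^2 * log(n)` where `sigma` is the
#' robust difference-based noise estimate `mad(diff(y)) / sqrt(2)` (the
#' `mad` already carries the 1.4826 normal-consistency factor; successive
#' differences of a piecewise-constant signal have variance `2 sigma^2`
#' away from breakpoints, so the estimator is immune to the segments
#' themselves).
#'
#' @param y Numeric vector of ordered log2 ratios (>= 3 values).
#' @return A single positive penalty value.
#' @examples
#' set.seed(1)
#' autoPenalty(rnorm(1000, sd = 0.1))  # about 2 * 0.01 * log(1000)
#' @export
autoPenalty <- function(y) {
  y <- y[is.finite(y)]
  n <- length(y)
  if (n < 3L) stop("autoPenalty needs >= 3 finite values", call. = FALSE)
  sigma <- mad(diff(y)) / sqrt(2)
  if (sigma == 0) return(.Machine$double.eps)
  2 * sigma^2 * log(n)
}

#' Segment probe-level profiles
#'
#' Partitions each (sample, chromosome) probe series into constant-mean
#' segments by exact penalized least-squares changepoint detection. The
#' optimum of `sum(SSE) + penalty * n_segments` is found by dynamic
#' programming, so the result is the global minimum, not a heuristic.
#'
#' Segment bounds span the first to last member probe: `start` is the
#' first probe position, `end` the last probe position + 1. Chromosomes
#' with fewer probes than `minProbes` become a single segment with a
#' warning.
#'
#' @param probes A [CNProbes] object (typically median-normalized and
#'   artefact-masked).
#' @param penalty Per-segment cost (>= 0), or `"auto"` to use
#'   [autoPenalty()] per sample chromosome (falling back to a pooled
#'   per-sample estimate for very short chromosomes).
#' @param minProbes Minimum probes per segment (default 2).
#' @return An uncalled [CNSegments] object.
#' @examples
#' p <- CNProbes(data.frame(sample_id = "s1", chrom = "1",
#'                          position = 0:5 * 1e5,
#'                          log2_ratio = c(0, 0, 0, 1, 1, 1)))
#' as.data.frame(segmentProfile(p, penalty = 0.01))
#' @export
segmentProfile <- function(probes, penalty = "auto", minProbes = 2L) {
  stopifnot(is(probes, "CNProbes"))
  minProbes <- as.integer(minProbes)
  stopifnot(minProbes >= 1L)
  auto <- identical(penalty, "auto")
  if (!auto) stopifnot(is.numeric(penalty), penalty >= 0)
  d <- as.data.frame(probes)
  if (nrow(d) == 0L) stop("empty probe table", call. = FALSE)
  out <- vector("list", 0L)
  for (sid in unique(d$sample_id)) {
    ds <- d[d$sample_id == sid, , drop = FALSE]
    pooled <- if (auto) {
      diffs <- unlist(lapply(split(ds$log2_ratio, ds$chrom), diff),
                      use.names = FALSE)
      if (length(diffs) >= 2L) max(mad(diffs) / sqrt(2), 0) else 0
    }
    for (ch in unique(ds$chrom)) {
      dc <- ds[ds$chrom == ch, , drop = FALSE]
      y <- dc$log2_ratio
      n <- length(y)
      pen <- if (!auto) penalty
             else if (n >= 3L) autoPenalty(y)
             else if (pooled > 0) 2 * pooled^2 * log(max(n, 2L))
             else .Machine$double.eps
      if (n < minProbes) {
        warning(sprintf(
          "sample %s chr%s has %d probe(s) < minProbes=%d; single segment",
          sid, ch, n, minProbes), call. = FALSE)
        ends <- n
      } else {
        fit <- .dpSegment(y, pen, minProbes)
        ends <- fit$ends
      }
      starts <- c(1L, head(ends, -1L) + 1L)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid, chrom = ch,
        start = dc$position[starts],
        end = dc$position[ends] + 1,
        n_probes = ends - starts + 1L,
        log2_ratio = vapply(seq_along(ends), function(k)
          mean(y[starts[k]:ends[k]]), 0.0),
        annotation = "")
    }
  }
  CNSegments(do.call(rbind, out))
}

#' Total cost of a segmentation (internal helper exposed for validation)
#'
#' Computes `sum(within-segment SSE) + penalty * n_segments` for a given
#' set of segment end indices, without running the optimizer.
#'
#' @param y Numeric vector.
#' @param ends Integer vector of 1-based segment end indices (last must be
#'   `length(y)`).
#' @param penalty Per-segment cost.
#' @return The total penalized cost.
#' @keywords internal
#' @export
segmentationCost <- function(y, ends, penalty) {
  stopifnot(ends[length(ends)] == length(y), !is.unsorted(ends))
  starts <- c(1L, head(ends, -1L) + 1L)
  sse <- sum(vapply(seq_along(ends), function(k) {
    seg <- y[starts[k]:ends[k]]
    sum((seg - mean(seg))^2)
  }, 0.0))
  sse + penalty * length(ends)
}
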