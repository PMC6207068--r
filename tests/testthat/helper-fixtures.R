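## Shared fixture builders and independent oracles.

## Build a called segment table for one sample: each chromosome in
## `chroms` is tiled completely, with the given aberrant intervals cut
## out of a neutral background (mirrors how real profiles tile the
## genome, so whole-chromosome coverage fractions are meaningful).
## aberrations: data.frame(chrom, start, end, annotation, log2)
tileSample <- function(sid, aberrations = NULL, chroms = NULL,
                       probeSpacing = 2e5) {
  arms <- hg19Arms()
  if (is.null(chroms))
    chroms <- unique(c(aberrations$chrom, "1"))
  if (is.null(aberrations))
    aberrations <- data.frame(chrom = character(), start = numeric(),
                              end = numeric(), annotation = character(),
                              log2 = numeric())
  rows <- list()
  for (ch in chroms) {
    len <- arms$length[match(ch, arms$chrom)]
    abi <- aberrations[aberrations$chrom == ch, , drop = FALSE]
    bounds <- sort(unique(c(0, len, abi$start, abi$end)))
    for (k in seq_len(length(bounds) - 1L)) {
      s <- bounds[k]; e <- bounds[k + 1L]
      j <- which(abi$start <= s & abi$end >= e)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, chrom = ch, start = s, end = e,
        n_probes = max(1L, round((e - s) / probeSpacing)),
        log2_ratio = if (length(j)) abi$log2[j[1L]] else 0,
        annotation = if (length(j)) abi$annotation[j[1L]] else "normal")
    }
  }
  CNSegments(do.call(rbind, rows))
}

## Exhaustive-enumeration oracle for penalized least-squares
## segmentation: tries all 2^(n-1) break patterns (subject to the
## minimum segment size) and returns the minimum total cost.
bruteForceSegmentCost <- function(y, penalty, minSize = 1L) {
  n <- length(y)
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    breaks <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    ends <- c(breaks, n)
    lens <- diff(c(0L, ends))
    if (any(lens < minSize)) next
    cost <- segmentationCost(y, ends, penalty)
    if (cost < best) best <- cost
  }
  best
}

## Independent exhaustive scan for the amplification cutoff: walks every
## midpoint, counts agreement directly.
ampScanOracle <- function(log2, amplified) {
  s <- sort(unique(log2))
  cand <- (s[-length(s)] + s[-1]) / 2
  acc <- sapply(cand, function(t) sum((log2 >= t) == amplified))
  best <- max(acc)
  max(cand[acc == best])
}

## Small noisy single-sample probe profile on an artificial 1-chromosome
## grid (positions in bp).
probeFixture <- function(y, sid = "s1", chrom = "1", spacing = 1e5) {
  CNProbes(data.frame(sample_id = sid, chrom = chrom,
                      position = seq_along(y) * spacing,
                      log2_ratio = y))
}

armKeys <- c("loss_1p", "loss_3p", "loss_4p", "loss_11q", "loss_14q",
             "gain_1q", "gain_2p", "gain_17q")
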