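## Kaplan-Meier stratification by lesion flag. The estimators themselves
## come from the survival package; this layer handles flag joins, missing
## endpoints and the tabular export the rest of the pipeline expects.
## Time units are carried through from the annotation table, never
## assumed.

#' Kaplan-Meier product-limit estimate
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @return A data.frame `time`, `n_risk`, `n_event`, `n_censor`, `surv`
#'   (one row per distinct observed time, `S(0) = 1` implied).
#' @examples
#' kmEstimate(c(5, 8), c(1, 0))
#' @export
kmEstimate <- function(time, event) {
  if (any(time < 0, na.rm = TRUE))
    stop("negative survival times", call. = FALSE)
  stopifnot(length(time) == length(event), length(time) >= 1L,
            all(event %in% c(0, 1)))
  fit <- survfit(Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, n_censor = fit$n.censor,
             surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard chi-square log-rank statistic with 1 degree of freedom. With
#' zero events in both groups the test is undefined and `p = 1` is
#' returned with a warning.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param group Two-level grouping vector.
#' @return A list with `statistic` (chi-square), `p`, and `n` per group.
#' @export
logrank <- function(time, event, group) {
  stopifnot(length(time) == length(event),
            length(time) == length(group))
  g <- factor(group)
  if (nlevels(g) != 2L)
    stop("logrank needs exactly two non-empty groups", call. = FALSE)
  if (sum(event) == 0) {
    warning("no events in either group; log-rank p set to 1",
            call. = FALSE)
    return(list(statistic = 0, p = 1, n = table(g)))
  }
  sd <- survdiff(Surv(time, event) ~ g)
  list(statistic = unname(sd$chisq),
       p = unname(1 - stats::pchisq(sd$chisq, df = 1L)),
       n = table(g))
}

#' Kaplan-Meier stratification by an arm-lesion flag
#'
#' Splits the cohort by a logical flag column (e.g. `loss_11q`) and
#' compares survival between flagged and unflagged samples. Samples
#' without the requested endpoint (e.g. cohorts lacking event-free
#' survival) are excluded and counted.
#'
#' @param flags Output of [segmentalFlags()] (or any data.frame with
#'   `sample_id` and logical flag columns).
#' @param annotations A [SampleAnnotations] carrying `os_time`/`os_event`
#'   and/or `efs_time`/`efs_event`.
#' @param flag Name of the flag column to stratify on.
#' @param endpoint `"OS"` or `"EFS"`.
#' @return A list with `curves` (list of two [kmEstimate()] tables,
#'   `flagged` and `unflagged`), `logrank`, `nExcluded` (samples without
#'   the endpoint) and `endpoint`.
#' @export
stratifyByFlag <- function(flags, annotations, flag,
                           endpoint = c("OS", "EFS")) {
  endpoint <- match.arg(endpoint)
  stopifnot(is(annotations, "SampleAnnotations"))
  if (!flag %in% names(flags))
    stop("unknown flag column: ", flag, call. = FALSE)
  a <- as.data.frame(annotations)
  tc <- if (endpoint == "OS") "os_time" else "efs_time"
  ec <- if (endpoint == "OS") "os_event" else "efs_event"
  .requireCols(a, c(tc, ec), "annotation table")
  m <- merge(flags[c("sample_id", flag)],
             a[c("sample_id", tc, ec)], by = "sample_id")
  ok <- complete.cases(m[c(tc, ec)])
  nExcluded <- sum(!ok)
  m <- m[ok, , drop = FALSE]
  fl <- as.logical(m[[flag]])
  if (!any(fl)) stop("stratum 'flagged' is empty", call. = FALSE)
  if (all(fl)) stop("stratum 'unflagged' is empty", call. = FALSE)
  list(curves = list(
         flagged = kmEstimate(m[[tc]][fl], m[[ec]][fl]),
         unflagged = kmEstimate(m[[tc]][!fl], m[[ec]][!fl])),
       logrank = logrank(m[[tc]], m[[ec]], fl),
       nExcluded = nExcluded,
       endpoint = endpoint)
}

#' Export a Kaplan-Meier curve as TSV
#'
#' @param km A [kmEstimate()] data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeKm <- function(km, path) {
  write.table(km, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
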