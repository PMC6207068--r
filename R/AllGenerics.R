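#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Generic accessors
#'
#' `sampleIds()` returns the unique sample identifiers carried by a
#' container; `nSamples()` their count.
#'
#' @param x A [CNProbes], [CNSegments], [SampleAnnotations] or
#'   [SyntheticCohort] object.
#' @return `sampleIds()`: character vector; `nSamples()`: integer.
#' @name accessors
#' @aliases sampleIds nSamples
NULL
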