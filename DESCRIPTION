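Package: armcall
Title: Harmonized Copy-Number Aberration Calling and Chromosome-Arm
    Annotation for Multi-Platform Neuroblastoma Profiles
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Processes probe-level DNA copy-number profiles (log2 ratios)
    from heterogeneous aCGH and SNP array platforms into harmonized,
    aberration-annotated segment tables. Provides median normalization and
    platform artefact masking, exact penalized least-squares changepoint
    segmentation, platform-specific cutoff management and data-driven
    cutoff calibration (Gaussian-mixture density intersections for
    gain/loss, discrimination scans against FISH/qPCR MYCN status for
    amplifications), chromosome-arm-level annotation of the recurrent
    segmental lesions of neuroblastoma (loss of 1p, 3p, 4p, 11q, 14q and
    gain of 1q, 2p, 17q), cohort summaries (aberration frequency tracks,
    region matrices, lesion co-occurrence tests), Kaplan-Meier
    stratification by lesion, and a platform-faithful synthetic cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    survival
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
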