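# armcall

Harmonized somatic copy-number aberration calling and chromosome-arm
annotation for multi-platform neuroblastoma profiles.

## The problem

High-risk neuroblastoma is driven by DNA copy-number aberrations, and
their pattern is prognostic: tumors with only whole-chromosome
("numerical") changes fare better than tumors carrying segmental
lesions — loss of 1p, 3p, 4p, 11q or 14q, gain of 1q, 2p or 17q — or
*MYCN* amplification. Because the disease is rare, adequately powered
cohorts are assembled by pooling profiles from many centers and array
technologies, and the platforms disagree about scale: aCGH arrays
(Agilent, NimbleGen) produce log2 ratios with a much wider dynamic range
than SNP arrays (Affymetrix, Illumina), and Illumina compresses
amplifications to log2 ≈ 0.7–1.5 where Agilent reports 2 or more.

`armcall` is for analysts harmonizing such mixed-platform cohorts. It
takes probe-level log2-ratio tables (or pre-segmented tables) and
produces per-segment aberration calls, per-sample arm-lesion flags and
profile classes, cohort-level summaries, and survival stratifications —
with every stage testable against a built-in synthetic cohort generator
whose ground truth is known exactly.

## The method

1. **Normalize** — per-sample median centering of log2 ratios; chrY
   dropped; recurrently aberrant high-variance probes masked as platform
   artefacts.
2. **Segment** — exact penalized least-squares changepoint detection:
   minimize `sum(within-segment SSE) + penalty × #segments` by dynamic
   programming (compiled), penalty `2·σ̂²·log n` with
   `σ̂ = mad(diff(y))/√2` by default.
3. **Call** — one label per segment (`homozygous_deletion < -2`, else
   `loss`, `amplification`, `gain`, `normal`) using platform-specific
   cutoffs: gains/losses **+0.15/−0.25** on SNP arrays,
   **+0.20/−0.30** on aCGH; amplification at **1.5** (Affymetrix,
   NimbleGen), **2** (Agilent), **0.7** (Illumina). Cutoffs can be
   re-derived from data: Gaussian-mixture density intersections for
   gain/loss, a discrimination scan against FISH/qPCR *MYCN* status for
   the amplification cutoff.
4. **Annotate arms** — flag the 8 recurrent segmental lesions: merged
   same-direction runs **> 3 Mb**, excluding whole-chromosome
   aberrations (≥ 95% of covered extent) and amplifications;
   centromere-spanning lesions go to the longer-overlap arm. Profiles
   classify as `segmental` / `numerical_only` / `silent`.
5. **Summarize & stratify** — aberration frequency tracks, region
   matrices, exact co-occurrence tests with BH correction, silent /
   near-silent QC partition, Kaplan-Meier + log-rank by lesion flag.

See the methods vignette (`vignettes/copy-number-arm-calling.Rmd`) for
the full model, parameter defaults and design rationale.

## Worked example

```r
library(armcall)

cfg <- simulationConfig(nSamples = c(affymetrix_snp = 5, illumina_snp = 5,
                                     agilent_acgh = 5, nimblegen_acgh = 5),
                        seed = 17)
cohort <- simulateCohort(cfg)
#> SyntheticCohort: 20 samples (11q_type=12, mna_type=6, numerical_only=2)
#>   296780 probes, 520 truth segments

probes   <- medianNormalize(dropChrY(cohortProbes(cohort)))
segments <- segmentProfile(probes, penalty = "auto")
called   <- callCohort(segments, cohortAnnotations(cohort))
called
#> CNSegments: 542 segments, 20 sample(s), 542 called
#>            sample_id chrom    start       end n_probes   log2_ratio annotation
#> 1 affymetrix_snp_001     1   100000 249100001     1231  0.003505552     normal
#> 2 affymetrix_snp_001     2   100000 243100001     1201  0.009973262     normal
#> 3 affymetrix_snp_001     3   100000  60100001      301 -0.432440730       loss
#> 4 affymetrix_snp_001     3 60300000 197900001      674  0.022950482     normal
```

The third segment is a 60 Mb 3p loss: mean log2 −0.43 is below the
Affymetrix loss cutoff −0.25, so it is called `loss`; the flanking
segments sit near 0 and stay `normal`. Arm annotation then turns called
segments into per-sample lesion flags:

```r
flags <- segmentalFlags(called)
head(flags[, c("sample_id", "loss_1p", "loss_11q", "gain_17q",
               "any_segmental", "profile_class")])
#>            sample_id loss_1p loss_11q gain_17q any_segmental profile_class
#> 1 affymetrix_snp_001   FALSE     TRUE     TRUE          TRUE     segmental
#> 4 affymetrix_snp_004    TRUE    FALSE     TRUE          TRUE     segmental

round(cohortSummary(flags)$pct_segmental_8arms, 1)
#> [1] 90
```

90% of this small cohort carries at least one of the 8 recurrent
segmental lesions (the remaining 10% are the two numerical-only
profiles). Calling *MYCN* status from locus-overlapping segments agrees
with the simulated FISH/qPCR truth on every platform:

```r
conc <- mycnConcordance(mycnCohort(called, cohortAnnotations(cohort)),
                        cohortAnnotations(cohort))
conc
#>         platform n_compared n_unknown concordance
#> 1 affymetrix_snp          5         0           1
#> 2   agilent_acgh          5         0           1
#> 3   illumina_snp          5         0           1
#> 4 nimblegen_acgh          5         0           1

st <- stratifyByFlag(flags, cohortAnnotations(cohort), "loss_11q", "OS")
round(st$logrank$p, 3)
#> [1] 0.62
```

(At n = 20 the log-rank comparison is underpowered, as the p-value
shows; the acceptance script below runs the powered version.)

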