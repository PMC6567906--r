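# ifnsig

Quantifying type I interferon pathway activity in mixed cohorts of
systemic autoimmune rheumatic disease (SARD: lupus, Sjögren's syndrome,
mixed/undifferentiated connective tissue disease, systemic sclerosis,
inflammatory myopathy). A subset of patients across all of these
diagnoses shares elevated interferon-alpha activity, and identifying that
molecular subgroup — rather than working within clinical labels — is the
analysis this package supports. It is written for clinical researchers
analysing qPCR interferon-stimulated-gene (ISG) panels, count-panel
expression, and digital-ELISA protein measurements alongside clinical and
serological metadata.

## What it computes

**Relative quantification.** Long-format Ct tables become fold changes via
ΔΔCt: `ΔCt = Ct_target − mean(Ct_ref)`, `ΔΔCt = ΔCt − ΔCt_calibrator`,
`RQ = 2^(−ΔΔCt)` (`compute_rq()`); count panels are normalised to the
geometric mean of housekeeping counts (`panel_normalize()`).

**ISG score.** For each patient, every panel gene's RQ is divided by the
healthy-control median RQ of that gene, and the score is the median fold
change over the panel (six genes by default: IFI27, IFI44L, IFIT1, ISG15,
RSAD2, SIGLEC1). Positivity is score > threshold, where the threshold is
the healthy-control mean + 2 SD (published values 2.466 for the six-gene
qPCR score, 1.642 for the 30-gene panel).

**Classification.** A two-component Gaussian mixture fitted by EM to the
bimodal log10 scores (`fit_mixture_em()`) gives an IFN-high/IFN-low call
per patient (posterior > 0.5) and a concordance table against the
threshold rule.

**Protein.** Digital single-molecule assay concentrations are handled with
a blank-run limit of detection (mean + 3 SD, published 0.23 fg/ml) and a
10 fg/ml positivity cutoff.

**Associations.** Woolf 2×2 odds ratios, logistic/linear model ladders
with Wald intervals, Mann-Whitney/Kruskal-Wallis/Dunn rank tests, Spearman
correlation matrices with significance masks, the autoantibody-count
trend, nucleic-acid-receptor (NAR) profiling with k-means subgrouping, and
a grouped baseline table (`summarize_table1()`).

**Synthetic cohorts.** `generate_cohort()` draws seeded cohorts with the
full statistical structure above (bimodal scores, back-computed Ct tables,
status-conditional clinical records, copula-linked NAR and protein
levels), so the entire pipeline is testable without any patient data;
`truth_check()` confronts the pipeline's output with the generator's
latent truth.

## Worked example

```r
library(ifnsig)

cohort   <- generate_cohort(cohort_config(seed = 1))
analysis <- run_full_analysis(cohort, seed = 1)
analysis
#> Interferon-signature analysis (panel 'qpcr6', seed 1)
#>   164 patients, 29 controls; threshold 2.466 (fixed)
#>   ISG-positive: 56/164 (34.1%)
#>   mixture discordant: 5

tidy(analysis$mixture)
#> # A tibble: 2 × 4
#>   component weight   mean    sd
#>   <chr>      <dbl>  <dbl> <dbl>
#> 1 IFN-low    0.624 -0.315 0.295
#> 2 IFN-high   0.376  0.830 0.351

analysis$concordance
#>               mixture
#> threshold      IFN-low IFN-high
#>   ISG-negative     103        5
#>   ISG-positive       0       56
#> 5 discordant of 164 samples
```

The 164-patient synthetic cohort classifies 34% ISG-positive against the
2.466 cutoff (the generator's latent positivity rate is 38.4%), the
mixture recovers the two log10-score components near their generating
values (−0.3/0.9 with weights 0.62/0.38), and the discordance between the
two classification rules is one-sided: a few borderline
threshold-negative patients are called IFN-high, while no IFN-low patient
is threshold-positive.

Published aggregate counts from the motivating cohort are bundled as
inputs, so the univariate association surface can be recomputed directly:

```r
autoantibody_odds_ratios()[2:4, ]
#> # A tibble: 3 × 7
#>   term  estimate ci_low ci_high   p_value corrected     n
#>   <chr>    <dbl>  <dbl>   <dbl>     <dbl> <lgl>     <int>
#> 1 Ro        4.47   2.20    9.08 0.0000357 FALSE       164
#> 2 La        2.92   1.18    7.23 0.0205    FALSE       164
#> 3 Smith     7.68   2.68   22.0  0.000146  FALSE       164
```

Anti-Ro carriage multiplies the odds of ISG positivity by 4.5 (95% CI
2.2–9.1); `diagnosis_odds_ratios()` gives the per-diagnosis odds versus
undifferentiated disease the same way.

## Package layout

- `R/relquant.R`, `R/scoring.R` — ΔΔCt, panel normalisation, ISG score,
  threshold calibration and classification
- `R/mixture.R` — EM mixture fit, mixture classification, concordance
- `R/protein.R` — LOD and protein positivity
- `R/associations.R`, `R/cohort-counts.R` — odds ratios, model ladders,
  rank tests, Spearman matrices, bundled cohort counts
- `R/nar.R` — NAR group tests, score correlations, k-means subgroups,
  neutrophil model ladder
- `R/synthetic.R` — cohort configuration, generator, copula utilities,
  truth checking
- `R/pipeline.R`, `R/plots.R` — end-to-end orchestration, summaries,
  ggplot2 figures
- `vignettes/interferon-signature-methods.Rmd` — the methods notes: model
  assumptions, parameter defaults and why, numerical choices, and what
  the synthetic cohorts do and do not emulate
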