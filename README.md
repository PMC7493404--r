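# plasmatrace

Tumor-informed detection and longitudinal monitoring of circulating tumor
DNA (ctDNA) from targeted-panel variant-call tables, with progression-free
survival (PFS) analysis stratified by ctDNA status.

## The problem

In advanced non-small-cell lung cancer treated with first-line
chemotherapy, rising mutation allele frequencies in serial plasma draws
can reveal disease progression months before CT imaging. Detecting that
signal is hard: the tumor-derived fraction of cell-free DNA is small, and
at allele frequencies near 0.1% true mutations are buried in sequencing
error. plasmatrace implements the tumor-informed answer: anchor monitoring
on the somatic variants already confirmed in the patient's baseline tumor
tissue, and test each plasma sample against its own error background.

## The method

Per subject, baseline tumor-tissue calls pass four post-call filters —
non-repetitive region; predicted somatic (a logistic germline classifier
over population databases and observed AF, with a hotspot-whitelist
override); ExAC population frequency < 1%; AF > 5% (> 3% for hotspot
mutations) — yielding a *tracking set* of n variants. For a plasma sample
with tracked allele frequencies a\_1..a\_n (absent variants count as 0),
the observed statistic is the mean ā. Each of 10,000 Monte Carlo
iterations picks n distinct *background allele alterations* (non-tracked,
germline-filtered alterations in the same sample, mostly sequencing error)
and records their mean AF; the empirical p-value is

    p = (1 + #{iteration means ≥ ā}) / (iterations + 1)

and the sample is ctDNA-positive iff p < 0.01. Downstream, total ctDNA is
quantified in mutated genome equivalents (mGE = Σaf × input mass / 3.3 pg),
molecular progression is called at the second consecutive strict AF
increase from baseline, lead time is measured against the first
radiographic PD, and PFS (diagnosis to first PD or death, censored at last
imaging) is compared between ctDNA-positive and ctDNA-negative subjects by
Kaplan–Meier, log-rank, and univariate Cox regression.

A ground-truth-labelled synthetic cohort generator
(`simulate_cohort()`) reproduces the data shape this analysis expects — 71
subjects, 2–18 serial draws, depth ~2779, overdispersed background error,
germline variants shared between tissue and plasma, survival linked to
ctDNA-bearing status with hazard ratio 2.3 — so the whole pipeline is
testable without patient data. See the vignette
(`vignettes/ctdna-monitoring.Rmd`) for models, parameters, and design
choices.

## Worked example

The published single-subject trajectory — TP53 c.712T>G at 3.0% at
diagnosis, 8.5% at day 47, 10.6% at day 68, radiographic progression at
day 159:

```r
library(plasmatrace)

trajectory <- tibble::tibble(
  day = c(0L, 47L, 68L), variant = "TP53:c.712T>G",
  af = c(0.030, 0.085, 0.106)
)
mp <- detect_molecular_progression(trajectory, k_increases = 2)
mp
#> <molecular_progression> called at day 68 (rule: any_variant , k = 2 )
timeline <- subject_timeline(
  "example_1",
  recist = tibble::tibble(day = c(0L, 159L), response = c("SD", "PD"))
)
lead_time(mp, timeline)
#> [1] 91
```

The molecular call lands on day 68 (the second consecutive rise) and
precedes radiographic progression by 91 days.

A full synthetic run, from cohort to survival stratification:

```r
cohort <- simulate_cohort(cohort_sim_config(n_subjects = 40,
                                            panel_positions = 700,
                                            seed = 99))
result <- run_pipeline(cohort, pipeline_config(iterations = 2000, seed = 1))
result
#> <ctdna_pipeline_result>
#>   tracking sets: 40 subjects
#>   detections:    186 plasma samples ( 113 positive )
#>   Cox HR (first post-treatment status): 2.48 (0.99-6.20)
glance(result$survival$first$km)
#> # A tibble: 2 × 4
#>   group              n n_events median_survival
#>   <chr>          <int>    <dbl>           <dbl>
#> 1 ctDNA_negative    14        6             291
#> 2 ctDNA_positive    26       20              77
result$survival$first$logrank
#> # A tibble: 1 × 3
#>   statistic    df p_value
#>       <dbl> <int>   <dbl>
#> 1      4.00     1  0.0454
```

Subjects whose first post-treatment draw carries ctDNA progress markedly
earlier (median PFS 77 vs 291 days here); the Cox hazard ratio of 2.48
(95% CI 0.99–6.20) brackets the generator's true value of 2.3.

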