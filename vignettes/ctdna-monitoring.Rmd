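---
title: "Tumor-informed ctDNA monitoring: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-informed ctDNA monitoring: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmatrace)
```

## The problem

In advanced non-small-cell lung cancer, tumor cells shed DNA into plasma.
Deep targeted sequencing of serial blood draws can, in principle, reveal
disease progression months before imaging: the allele frequencies (AF) of
tumor mutations in cell-free DNA (cfDNA) rise as resistant disease expands.
The difficulty is that circulating tumor DNA (ctDNA) is a small fraction of
cfDNA, and at AFs of 0.1% and below, true mutations are hard to tell from
sequencing error.

plasmatrace implements a tumor-informed monitoring workflow around that
problem:

1. **Tissue filtering.** Baseline tumor-tissue variant calls are reduced to
   a high-confidence somatic *tracking set* by four post-call filters.
2. **Germline classification.** Without a matched normal, germline
   variants are recognized from population databases plus observed AF by a
   logistic classifier.
3. **ctDNA detection.** Per plasma sample, the mean AF of the tracked
   variants is compared against a Monte Carlo null assembled from the
   sample's own background allele alterations.
4. **Quantification and progression calling.** Total ctDNA is expressed in
   mutated genome equivalents; molecular progression is called from
   consecutive AF increases, and its lead time over radiographic
   progression is reported.
5. **Survival analysis.** Progression-free survival (PFS) is stratified by
   ctDNA status (Kaplan–Meier, log-rank, univariate Cox).

Because the kind of cohort this analysis targets cannot be shared (germline
sequence is identifying), the package carries a synthetic cohort generator
with full ground-truth labels, and every claim the package makes about
itself is demonstrated on that generator.

## The detection model

For a subject with tracking set of size $n$, and a plasma sample with
observed tracked AFs $a_1,\dots,a_n$ (a tracked variant not seen in the
sample contributes $a_i = 0$; $n$ never shrinks), the observed statistic is
$\bar a = \frac1n \sum_i a_i$. The null is built from the sample's
*background allele alterations*: every non-tracked position with at least
one alternate read, after germline-predicted alterations have been removed.
Each of $B$ Monte Carlo iterations (default $B = 10{,}000$) picks $n$
distinct background alterations and records their mean AF; the empirical
p-value is

$$p = \frac{1 + \#\{\text{iteration means} \ge \bar a\}}{B + 1},$$

and the sample is called ctDNA-positive iff $p < \alpha$ with
$\alpha = 0.01$ (strict). Numerical choices, all deliberate:

- **Add-one smoothing** keeps $p > 0$ and log-scale plots finite; the
  matching exhaustive-enumeration oracle (`exhaustive_pvalue()`) uses the
  same smoothing so the two agree as $B$ grows.
- **Ties count toward the tail** (conservative).
- **Sampling without replacement** within an iteration: an iteration is a
  draw of $n$ distinct alterations. If the background is smaller than $n$
  the result is *indeterminate*, never coerced (a with-replacement fallback
  exists but is off by default).
- **Strict inequalities** at $\alpha$ and at the filter thresholds below.

One property of this design worth knowing: because the observed tracked
AFs are compared against subsets of a *finite* background pool, the test is
very slightly anti-conservative — on null simulations with a
1000-alteration pool the positive rate at $\alpha = 0.01$ measures near
0.011 rather than 0.010. This is intrinsic to the empirical-null
construction, is inside the one-sided binomial tolerance the package tests
itself against, and shrinks as the background pool grows.

The background pool is per-sample, matching the idea that each sample has
its own error profile; pooling across samples would be a possible variant
but is not implemented.

## Tissue filters and the tracking set

A tissue variant passes only if all four hold:

| criterion | rule |
|---|---|
| `repetitive_region` | position outside the repetitive-region mask (BED input, converted to 1-based closed) |
| `predicted_germline` | classified putative-somatic by the germline model |
| `pop_af_ge_1pct` | ExAC-role population frequency strictly below 1% |
| `af_below_threshold` | AF strictly above 5%, or strictly above 3% for hotspot-whitelist variants |

All four are evaluated for every variant, so `failed_criteria` is complete
and order-independent. The ExAC criterion deliberately uses only the
ExAC-role table, not the maximum over all databases. "Hotspot" is
operationalized as membership in the supplied whitelist; no canonical list
is bundled. Synonymous variants are tracked by default
(`include_synonymous`), since both synonymous and non-synonymous somatic
variants carry signal for presence testing; a flag excludes them.

## Germline classification without a matched normal

The classifier is a logistic score over: maximum population AF across
databases, number of databases carrying the variant, pooled
somatic-evidence count, observed AF, and its distances to 0.5 and 1.0 (the
heterozygous and homozygous germline expectations). Absent database
entries become zeros, never missing values. Two hard design rules sit
outside the score:

- **Whitelist override.** Hotspot variants are ruled putative-somatic
  before scoring — a well-known cancer mutation at AF 0.5 must not be
  discarded as germline. The cost is that a germline variant erroneously
  placed on a whitelist would evade filtering; whitelists must be curated
  somatic lists.
- **Monotonicity.** The `max_pop_af` coefficient is constrained
  non-negative toward the germline class, so growing population frequency
  can never flip a call from germline to somatic.

There is no allele-frequency cut-off: a 25% AF variant with no database
support is somatic; classification rests on the joint evidence. The
decision threshold defaults to 0.5 and is exposed. The model serializes to
a flat text file and reloads bit-equal.

The classifier is trained on synthetic ground truth (in production use, on
any cohort with matched-normal-resolved labels). On held-out synthetic
cohorts its label concordance exceeds 0.85, the floor the test suite
enforces; typical values are well above it. The residual errors are the
honest ones: database-absent germline variants, and somatic variants whose
AF lands near 0.5.

## Quantification, progression, lead time

Total ctDNA level is reported in mutated genome equivalents:
$\mathrm{mGE} = \left(\sum_i a_i\right) \times m / m_h$, with $m$ the cfDNA
input mass (ng) and $m_h = 0.0033$ ng the mass of one haploid genome
(3.3 pg; config-overridable). So 33 ng of input is 10,000 genome
equivalents, and one variant at 10% AF in it is 1000 mGE. The level is
additive over variants and linear in input mass.

Molecular progression is called when some tracked variant's AF rises
strictly in `k_increases = 2` consecutive inter-sample steps, with the run
anchored at baseline: the run's starting value must be at least the
variant's first-sample value. Ties break the run; fewer than
`k_increases + 1` samples can never produce a call; the earliest
qualifying sample day is the call day, and appending later samples never
changes an existing call. The default `any_variant` rule tracks each
variant separately; a `mean_af` rule (same test on the per-day mean) is
provided because the aggregation level is genuinely ambiguous in this kind
of protocol — `any_variant` is the default because the published worked
examples follow single variants. Lead time is first radiographic PD day
minus call day, reported with sign (negative when imaging came first).

## Survival analysis

PFS runs from histological diagnosis (day 0) to the first RECIST PD event
or death of any cause; otherwise it is censored at the last imaging
assessment. The stratification variable is ctDNA status at the *first*
available post-treatment plasma sample (a sensitivity variant uses the
*last*), where post-treatment means collected after the recorded treatment
start day and indeterminate detections are skipped. Model fitting is
delegated to the survival package: Kaplan–Meier curves via `survfit`,
log-rank via `survdiff`, Cox models via `coxph` with Efron tie handling
(day-resolution times tie often; the choice is stated, not inherited
silently). The reported median survival is the smallest time at which the
curve reaches 0.5 or below. Categorical covariates with more than two
levels report per-level hazard ratios against a stated reference plus one
global likelihood-ratio p-value. Non-convergence and monotone likelihood
are flagged in the output rather than silently reported.

## What the synthetic cohort generator emulates

`cohort_sim_config()` defaults encode the study conditions this pipeline
is meant for: 71 subjects; 2–18 plasma draws per subject with median 6;
mean de-duplicated depth 2779 (plasma) and 1116 (tissue); a mean of six
somatic variants per subject with tissue AFs spanning 3.29–86.82%;
germline variants at dedicated polymorphism sites with population AFs in
the databases; background error as a beta-binomial with mean rate
$10^{-4}$ and concentration 1000 (overdispersed relative to binomial, as
empirical NGS background is; the distributional form is a modeling
stand-in, as no published parameterization exists). Tumor-fraction
trajectories are piecewise-exponential per response arm — multiplicative
decline on therapy (or outright clearance, probability 0.35), regrowth
from a resistance-onset day that precedes radiographic progression by a
uniform 60–120 days. PFS is exponential with the hazard multiplied by a
true ratio of 2.3 when the first post-treatment draw carries ctDNA, with
uniform administrative censoring tuned to censor roughly 35% of subjects.
Clinical covariates (age, sex, ECOG, smoking, stage) are drawn with the
cohort's marginal frequencies, independent of outcome.

What it does **not** emulate, and hence what passing tests cannot show:
read-level artifacts (the upstream barcoding/error-suppression stack is
out of scope), position-specific error structure beyond the beta mixture,
CNVs/fusions, clonal evolution (clonal fractions are fixed per variant),
and imaging noise in RECIST reads. Recovery results on this generator
demonstrate internal consistency of the pipeline under its stated
assumptions, not clinical performance.

Determinism is a contract throughout: every stage derives its seed from a
master seed via `derive_seed(master, stage_label)`, and identical configs
give bit-identical cohorts, detections, and summaries.

## Problem sizes used in the test suite

The suite exercises the pipeline end to end on a 14-subject cohort with a
700-position panel at 2,000 Monte Carlo iterations; null calibration of
the detector uses 2,000 simulated samples; Cox coverage uses 100 replicate
cohorts of 71 subjects drawn from the generator's survival component
(the sequencing layer is irrelevant to that property, so it is not
simulated there); log-rank size uses 500 replicates. These sizes were
chosen to make the statistical assertions sharp (3-standard-error bands)
while keeping the suite quick to run; all of them are plain function
arguments, so larger experiments are one edit away.

## Worked example

```{r example, eval = FALSE}
library(plasmatrace)

# the published single-subject TP53 series
trajectory <- tibble::tibble(
  day = c(0L, 47L, 68L), variant = "TP53:c.712T>G",
  af = c(0.030, 0.085, 0.106)
)
mp <- detect_molecular_progression(trajectory, k_increases = 2)
mp$call_day                      # 68
timeline <- subject_timeline(
  "example_1",
  recist = tibble::tibble(day = c(0L, 159L), response = c("SD", "PD"))
)
lead_time(mp, timeline)          # 91 days

# a full synthetic run
cohort <- simulate_cohort(cohort_sim_config(n_subjects = 14,
                                            panel_positions = 700,
                                            seed = 314))
result <- run_pipeline(cohort, pipeline_config(iterations = 2000, seed = 1))
result$survival$first$cox
autoplot(result$survival$first$km)
```

## Known limitations

- The germline classifier is a transparent logistic stand-in for
  production classifiers trained on matched-normal corpora; its feature
  families are standard but its weights are only as good as the labeled
  training data supplied.
- Plasma-side variant calling is out of scope: plasma tables arrive
  pre-called, including sub-threshold alterations if the caller provides
  them. The quality of the background null depends on that input.
- Indel normalization trims to minimal representation; full left-alignment
  against a reference genome is not performed, so calls from different
  callers may need harmonization upstream.
- The mGE constant (3.3 pg/haploid genome) is a convention; comparisons
  across studies should confirm the same convention is in use.
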