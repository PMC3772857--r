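---
title: "Methods: from case-control odds ratios to absolute pancreatic cancer risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from case-control odds ratios to absolute pancreatic cancer risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancrisk)
```

## The model

`pancrisk` estimates the probability that an individual of known sex, age
and risk-factor profile develops pancreatic cancer over a stated age
interval, accounting for the competing risk of dying of something else
first. It does this in three stages.

**Relative risk.** Case-control status is modelled by logistic regression

$$\mathrm{logit}\, P(D = 1 \mid X) = \alpha +
\beta_{smoking}'X_{smoking} + \beta_{diabetes}'X_{diabetes} +
\beta_{famhist}'X_{famhist} + \beta_{alcohol}'X_{alcohol} +
\beta_{BMI}'X_{BMI} + \beta_{ABO}'X_{ABO} +
\beta_{1q32}X_{1q32} + \beta_{5p15}X_{5p15} + \beta_{13q22}X_{13q22} +
\beta_{age}'X_{age} + \beta_{sex}X_{sex} + \beta_{study}'X_{study}$$

with every risk factor categorical (indicator vectors; a former smoker has
$X_{smoking} = (1,0,0)^T$, a never smoker $(0,0,0)^T$) and the three SNPs
coded as risk-allele counts 0–2. Three coding rules matter:

* *Missing-indicator coding.* Each covariate with unobtainable values
  carries its own "missing" level with its own coefficient, so incomplete
  records stay in the fit. Prediction is a different matter — see below.
* *Design-stratified diabetes.* Long-standing (>3 y) diabetes behaves
  differently in retrospective case-control studies than in prospective
  nested case-control (cohort) studies — recall and reverse-causation
  pressures differ — so the diabetes terms are estimated separately per
  design stratum (four terms in all).
* *ABO as diplotype.* The ABO genotype enters as five indicators against
  the OO reference, not as allele counts, because the non-O genotypes do
  not act additively. The diplotype is derived deterministically from the
  two tag SNPs (`derive_abo`): rs505922 counts O haplotypes, rs8176746
  counts B haplotypes, A is the remainder; a combined count above 2 is an
  inconsistency error.

The relative risk of a profile is
$RR(X) = \exp(\sum \text{selected non-nuisance terms})$, the all-baseline
profile mapping to exactly 1. Age, sex and study coefficients are
estimated but quarantined as nuisance: the absolute-risk stage anchors age
and sex to population rates, so including them in $RR$ would double-count.

**Calibration.** Population incidence $I_{sex}(t)$ (SEER-style, per
100,000 person-years, converted to per-person-year hazards) is an average
over everyone, including people with risk factors. The baseline
(all-reference-level) hazard is therefore

$$\rho_{sex}(t) = \frac{I_{sex}(t)}{\overline{RR}_{sex}}, \qquad
\overline{RR}_{sex} = \text{mean } RR \text{ over complete-data controls},$$

a single sex-specific scalar applied at every age. This makes the
calibration identity exact by construction: the average predicted hazard
over the calibration controls equals the population rate at every age (the
suite checks it to 1e-12). Controls with any missing covariate level are
refused here — the protocol restricts calibration to complete data.

**Accumulation.** With $h(t) = \rho_{sex}(t)RR(X)$ and all-cause mortality
$m(t)$, both piecewise-constant over one-year ages, the risk over the
half-open interval $[a_1, a_2)$ is

$$\sum_{t=a_1}^{a_2-1} \frac{h(t)}{h(t)+m(t)}
\left(1 - e^{-(h(t)+m(t))}\right)
\prod_{u=a_1}^{t-1} e^{-(h(u)+m(u))}.$$

Within each year the exact exponential split between the two competing
hazards is used rather than the first-order product
$h(t)\prod(1-h-m)$; the two agree to first order but the exact form makes
the three-way decomposition (disease + other-cause death + survive both)
sum to 1 identically, which the suite asserts to 1e-9. A year with
$h+m=0$ contributes 0 by the limit convention. "Lifetime" risk is the
interval risk to a horizon age, default 85 and configurable; the start age
is a **required** argument, because whether accumulation begins at birth
or at cohort entry is an analysis decision the data do not make for you.

## Evaluation metrics

* `auroc` computes the Mann-Whitney AUC via midranks, ties counting half
  (the standard convention; the method the model mimics does not specify a
  tie rule). Its variance is the DeLong placement-value estimate, and the
  95% CI is a clipped normal approximation on the AUC scale.
* `delong_compare` uses the structural-component covariance for the paired
  AUC difference; comparing a model with itself gives exactly zero.
* `reclassify`/`nri` implement the two-category net reclassification
  improvement at a risk threshold, conventionally twice the average
  lifetime risk. "High risk" is *strictly greater than* the threshold —
  fixed, documented, and matched to the published table layout. The NRI
  variance is the standard binomial-movement (Pencina) form; the primary
  p-value is one-sided for improvement, with the two-sided value also
  reported.

## Winner's-curse adjustment

Per-allele estimates discovered in the same scan that reported them are
inflated by selection at the significance threshold. `conditional_mle`
maximizes the likelihood of the observed estimate conditional on selection,
$\phi((\hat\beta-\beta)/se) / [\Phi(-c+\beta/se) + \Phi(-c-\beta/se)]$
with $c = \Phi^{-1}(1-\alpha/2)$, by golden-section search on
$[0, |\hat\beta|]$ (the conditional MLE always shrinks toward zero; the
suite checks the maximizer against a dense grid search to 1e-6). The
conditional MLE systematically overcorrects near the threshold, so
`wc_adjust` also reports the combined estimator
$w\hat\beta + (1-w)\hat\beta_{cMLE}$ and uses it downstream. The weight
defaults to $w = 0.5$ but is exposed as a parameter: the weighting in the
cited correction is a method choice, not something this package should
hard-code silently. The discovery threshold defaults to genome-wide
significance, $\alpha = 5\times10^{-8}$, also configurable. When
demonstrating the adjustment on published odds ratios, `se_from_ci`
back-derives the standard error from the Wald interval,
$(\log U - \log L) / (2 \times 1.959964)$ — a documented approximation,
since discovery-stage standard errors are rarely printed.

## The synthetic-data generator

No individual-level consortium data are deposited anywhere this package
could fetch them, so `simulate_population` generates datasets with the
marginal structure the analysis assumes:

* Covariate categories are drawn independently per subject from the
  published pooled control-group frequencies (`default_covariate_freqs`);
  e.g. 8.2% current smokers, 6.9% long-standing diabetes, 3.8% family
  history, 17.5% obese.
* SNP genotypes are binomial(2, p) — exact Hardy-Weinberg — with
  control-estimated risk-allele frequencies 0.754 (1q32), 0.446 (5p15),
  0.368 (13q22). ABO diplotypes are unordered pairs of O/A/B haplotypes
  (frequencies 0.653/0.267/0.080, obtained by direct allele counting over
  the published control diplotype counts, which is exact because the two
  tag SNPs determine the diplotype without phase ambiguity), so emitted
  tag-SNP counts are consistent with the diplotype by construction.
* Disease status is Bernoulli with $\mathrm{logit} = \alpha + \beta'X$
  under a caller-supplied truth (default: the packaged published
  coefficients). No baseline prevalence is published, so the intercept is
  tuned by bisection until the expected case yield in the source pool
  comfortably exceeds the request; the requested numbers of cases and
  controls are then sampled without replacement.
* Missingness is masked in *after* status assignment
  (missing-completely-at-random), per covariate and per design stratum,
  with default rates transcribed from the published control "missing"
  rows. Masking after assignment means the induced missing-indicator
  coefficients are null — the generator emulates the published
  missing-data *pattern*, not the (unknown) missing-data *mechanism* that
  produced coefficients like the large cohort "diabetes unknown" effect.

What the generator deliberately does **not** emulate: correlations between
risk factors (only marginal frequencies are published; smoking and alcohol
are surely correlated in reality), linkage disequilibrium beyond the two
ABO tag SNPs, population stratification, and secular or study-level
covariate differences beyond the design-stratum split. Passing
parameter-recovery tests on these data therefore demonstrates correctness
of the estimation machinery under the model's own assumptions, not
robustness to the confounding structure of real consortium data.

`simulate_life_table` provides the SEER-like per-sex rate fixture:
Gompertz-like incidence, zero below an onset age (default 30) and
$r_{50}e^{s(t-50)}$ per 100,000 above it, with Gompertz all-cause
mortality. Defaults ($r_{50} = 14.5$ male / 11.3 female, $s = 0.068$,
mortality $e^{-9.8+0.085t}$ male / $e^{-10.4+0.088t}$ female, ages 0–89)
were fixed once so that the tables integrate to population lifetime risks
of about 1.50% (men) and 1.31% (women) — the familiar magnitudes for this
disease — and so that twice the average simulated-control lifetime risk
lands near the 2.9%/2.6% high-risk thresholds the reclassification
analysis uses. Note that the *baseline-profile* lifetime risk is much
smaller (about 0.45% for men): the mean control RR is around 3.4, mostly
because the 1q32 risk allele is the major allele, so almost nobody sits at
the zero-risk-allele baseline.

## Numerical choices

* Logistic fitting is IRLS (`stats::glm.fit`) run to relative deviance
  change below 1e-12 with an iteration cap of 200; the observed-information
  covariance is $(X'WX)^{-1}$ at the solution. Constant design columns
  (unobserved levels, e.g. the "missing" indicators when no data are
  masked) are dropped and recorded in `meta$dropped_terms`; genuine
  collinearity among varying columns is an error naming the terms, as is a
  coefficient exceeding 15 in magnitude (the separation diagnostic).
* The complete-case rule for genetic markers is applied at fit time: any
  record missing a genotype is excluded from models containing genetic
  terms, with the count recorded.
* Prediction (`relative_risk`) rejects profiles containing a
  missing/unknown level by default — a person using a risk calculator
  knows their own covariates — while `missing_action = "indicator"`
  restores fit-parity scoring for internal validation.
* Five-year life-table bands are expanded to constant per-year hazards, so
  the band mean is conserved exactly. All ages are integer attained ages;
  intervals are half-open $[a_1, a_2)$.
* All-cause mortality is used without decrementing the disease's own
  deaths; at an incidence of order 10–100 per 100,000 the double counting
  is far below every tolerance used here.
* The conditional-MLE search uses `stats::optimize` with tolerance 1e-10
  on the bracket $[0, |\hat\beta|]$.

## Problem sizes in the test suite

The suite exercises the pipeline at sizes chosen to keep Monte-Carlo noise
well below the assertion bands while running in seconds: consortium-scale
simulation-and-refit (3,349 + 3,654) over 20 seeds for the recovery
checks, 24 replicates at 1,200 + 1,200 for the per-term consistency band
(a simultaneous 3.2-SE band across ~20 jointly tested terms), 50,000
subjects for the Hardy-Weinberg goodness-of-fit (α = 0.001), 9,000
subjects for the lifetime-risk tail-share echo, and 1,000 replicates for
the winner's-curse selection-bias simulation.

## Known limitations

* The packaged published coefficient set has no age/sex/study terms (none
  are published), so it supports relative- and absolute-risk prediction
  but not likelihood evaluation or refitting-free comparisons.
* Published odds ratios differ slightly between the final-model table and
  the running text (e.g. heavy alcohol 1.45 vs 1.37); the packaged set
  follows the final-model table throughout.
* Absolute risks carry no confidence intervals (none are defined for the
  published pipeline being mirrored).
* The model is built on, and only applicable to, populations of European
  ancestry; the eligibility filter enforces the matching restriction.
* High-penetrance variants (BRCA2, PALB2, ...) and family-based
  conditioning are out of scope; individuals with strong family histories
  need family-based models, not this one.
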