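---
title: "Allelic-series Mendelian randomization: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allelic-series Mendelian randomization: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seriesmr)
```

## What the package computes

`seriesmr` estimates the causal effect of lowering an enzyme's activity
on disease risk using naturally occurring activity-lowering alleles of
the encoding gene as instruments, and expresses every instrument — and a
pharmacological comparator — on one reference scale. The pipeline has
five stages: simulate (or load) individual-level study cohorts, estimate
per-study genetic associations with activity and disease, pool them by
fixed-effect meta-analysis, rescale with single-instrument Wald ratios,
and compute power. The defaults describe the Lp-PLA2 (*PLA2G7*) allelic
series and coronary heart disease; everything is parameterized, so other
gene–biomarker–disease triples fit the same machinery.

## The data-generating model

The generator realizes the assumptions the estimators make, nothing
more.

**Genotypes.** Each variant is drawn independently as Binomial(2, *f*),
i.e. Hardy–Weinberg equilibrium at effect-allele frequency *f*; the
effect allele is always the activity-lowering allele. Frequencies are
ancestry-specific (`pla2g7_variants()` carries the defaults: the four
rare loss-of-function alleles at 0.005%–0.04% in Europeans/South Asians,
Val279Phe at 15% in East Asians, Val379Ala at 80%). With
`forbid_multi_lof` (the default in cohort simulation), individuals
carrying two distinct loss-of-function variants are redrawn, reproducing
the observed mutual exclusivity of carriers; at the default frequencies
this constraint binds almost never and leaves marginal frequencies
essentially untouched.

**Activity.** Individual activity is `baseline * prod_j m_j(g_j) + e`,
where `m_j` is variant *j*'s genotype-class multiplier vector
`(1, m1, m2)` and `e ~ Normal(0, (sigma * baseline)^2)` is homoscedastic
within-class noise. Class multipliers for Val279Phe are (1, 0.55, 0.06)
— heterozygotes 45% lower, homozygotes 94% lower — and rare
loss-of-function carriers are modelled at 0.36 (64% lower).
Multi-variant effects multiply; at the default frequencies double
carriers essentially never occur, so this convention only needs to be
well defined.

**Disease.** Case-control status follows an additive logistic model,
`logit P(D) = a0 + sum_j g_j logOR_j`, with the intercept centred so the
population prevalence is the configured value (default 5%). Case-control
studies are sampled retrospectively — cases and controls drawn without
replacement from a large source population — because that sampling
scheme preserves the odds ratio, the quantity the association stage
estimates. Between-study heterogeneity, when requested, adds one
`Normal(0, tau^2)` deviate per study to all of its true log odds ratios.

## Calibrating the noise level

The only free parameter of the activity model is the noise SD `sigma`
(as a fraction of baseline). It is fixed by the published standardized
effects rather than guessed: with class probabilities `p_c`, class means
`m_c` and dose `d_c`, the raw regression slope is
`b = cov(d, m) / var(d)` and the total variance is the between-class
variance `V_b` plus `sigma^2`, so the standardized slope is
`|b| / sqrt(V_b + sigma^2)` and

```
sigma = sqrt((b / target)^2 - V_b)
```

(`calibrate_noise()`; an error if the target exceeds the zero-noise
limit). The package defaults are the two solutions of this equation:

```{r}
calibrate_noise(c(1, 0.55, 0.06), freq = 0.15, target_sd_effect = 1.59)
calibrate_noise(c(1, 0.36), freq = 0.0022, target_sd_effect = 2.25)
```

rounded to `sigma = 0.171` (East Asian per-allele design, 1.59 SD) and
`sigma = 0.283` (European carrier contrast, 2.25 SD). The corresponding
implied SD-to-mean ratios differ slightly between the two designs; the
package deliberately treats `sigma` as a per-design calibration rather
than forcing one global value, since the source estimates themselves
imply slightly different ratios (0.281–0.288).

**Why the noise is not truncated at zero by default.** Measured activity
is non-negative, and `simulate_activity(truncate = TRUE)` can left-censor
at zero. But the closed-form calibration above — and the genotype-class
means it guarantees — hold for *untruncated* Gaussian noise. For the
Val279Phe homozygote class (mean 0.06, sigma 0.171) censoring would
inflate the class mean to about 0.10 and shrink the recovered homozygote
deficit from 94% to about 90%, silently de-calibrating the generator.
The default is therefore `truncate = FALSE`: a small fraction of
negative "measured" values is accepted as part of the Gaussian
measurement-error idealization. Truncation remains available for
workflows that need strictly non-negative values and can tolerate the
bias in near-zero classes.

## Association estimation

Activity is standardized with the unbiased SD of a reference group:
everyone in cohort studies, controls only in case-control studies (cases
are enriched by design, and using them would distort the SD unit).
Per-allele and per-carrier effects come from ordinary least squares with
classical standard errors; genotype-class percent deficits
(`genotype_class_effects()`) are computed on the raw scale as
`100 (1 - mean_class / mean_noncarrier)` with a delta-method standard
error — percent and SD scales are never mixed inside one estimate.

Disease associations use maximum-likelihood logistic regression
(IRLS, tolerance 1e-10, at most 50 iterations), with Wald standard
errors. Complete or quasi-complete separation is detected and raised as
a typed error (`seriesmr_separation`); callers may opt into the
auditable fallback — collapse to the carrier-by-status 2x2 table, add
0.5 to every cell — which is returned flagged as
`continuity_corrected`. We chose the continuity correction over
penalized likelihood because the resulting estimate is a closed form the
reader can recompute by hand. A variant that is monomorphic in a given
study yields a flagged `NA` row from `assoc_study()`, not an error: in a
multi-study analysis a locally absent allele is expected, not
exceptional.

The rare-allele analysis collapses loss-of-function variants into a
per-individual damaging-allele count. Reported effects use the carrier
indicator (at the default frequencies nobody carries two alleles, so the
two codings coincide); the cross-study test exchanges per-study score
statistics: `U = sum_i b_i (y_i - yhat_i)` and its null variance `V`
from the covariate-only logistic null model, combined as
`(sum U)^2 / sum V ~ chi-square(1)`. This is the summary-statistic form
that lets studies contribute without sharing individual-level data.

## Meta-analysis and rescaling

Pooling is fixed-effect inverse-variance only — matching the assumption
that each variant has one common effect across studies — with Cochran's
Q, its chi-square p-value, and `I² = max(0, (Q-df)/Q) * 100` (truncated
at zero by the standard convention; a single study reports heterogeneity
as absent, not zero). Random-effects pooling is deliberately out of
scope.

The causal stage divides the pooled log odds ratio *and both confidence
limits* by the instrument's activity effect and multiplies by the
reference effect (2.26 SD = 65%). Transforming the bounds directly,
rather than recomputing a delta-method standard error, keeps published
asymmetric intervals exactly proportional on the log scale; for scale
factors near one the two approaches coincide, and for large factors
(weak instruments such as Val379Ala, 0.096 SD) direct transformation is
what makes the very wide intervals honest. Odds ratios are interpreted
as risk ratios throughout — the rare-disease approximation. A
non-positive instrument effect is an error, never a silent sign flip:
a wrong-signed instrument means the orientation convention was violated
upstream. For display the package rounds half away from zero to two
decimals, matching printed-table style; full precision is preserved in
all TSV/JSON artifacts (serialized at 17 significant digits).

## Power

`analytic_power()` uses the standard inverse-variance approximation for
a per-allele log odds ratio under Hardy–Weinberg equilibrium and
independent alleles, `var = 1/(2 N_case f(1-f)) + 1/(2 N_ctrl f(1-f))`,
and two-sided normal power. The approximation ignores case-control
imbalance in genotype frequencies under the alternative — adequate for
the modest per-allele effects relevant here. `simulated_power()`
cross-checks it end to end through the generator and estimator, refusing
fewer than 100 replicates (the Monte-Carlo interval would be
uninformative). The two agree within Monte-Carlo error across the
designs exercised in the test suite. Target causal effects convert to
per-allele effects by the inverse Wald map,
`exp(log(target) * instrument_sd / reference_sd)`: a 20% risk reduction
per 2.26 SD corresponds to a per-allele risk ratio of about 0.855
through a 1.59 SD instrument.

## Determinism and seeds

Every stochastic function takes a seed and is fully reproducible given
it. Study sets derive per-study seeds as `master seed + study index` —
any fixed scheme would do; this one is documented and stable across
runs. Pipeline artifacts are byte-identical across re-runs with the same
configuration.

## Problem sizes

The simulated-cohort analyses in the tests and the acceptance script use
n = 20,000 for the East Asian cohort (about 5,100 heterozygotes and 450
homozygotes at frequency 0.15) and n = 100,000 for the European rare
loss-of-function cohort (about 220 carriers at aggregate frequency
0.22%) — sizes at which the Monte-Carlo error of the recovered effects
(roughly ±0.01 SD and ±0.07 SD respectively) is well inside the
tolerances being checked, while a full run stays within a coffee break.
Null-calibration checks use 200–400 replicate studies.

## What the synthetic data do and do not show

The generator emulates: Hardy–Weinberg genotypes at realistic
frequencies, mutually exclusive rare loss-of-function carriers,
genotype-class biomarker means with calibrated Gaussian noise, additive
log-odds disease risk, retrospective sampling, and optional between-study
heterogeneity. It does not emulate linkage disequilibrium (variants are
independent; proxy variants are supported only as name aliases, not by
LD imputation), relatedness or population stratification (cohorts are
unrelated by construction; the mixed-model machinery real consortia use
for kinship is replaced by plain logistic regression with optional
covariates such as supplied principal components), imputation dosages
(hard calls only), assortative mating, or selection. Passing tests
therefore demonstrate that the estimators are correct and calibrated
under the stated model — not that real cohort data are free of the
confounding structures the model excludes.

## Known limitations

* Single-instrument Wald ratios only; multi-instrument MR estimators
  (IVW, Egger, weighted median) and pleiotropy diagnostics are out of
  scope.
* The odds-ratio-as-risk-ratio reading requires the outcome to be rare
  in the source population.
* The homoscedastic Gaussian activity model is an idealization; real
  biomarker noise is typically right-skewed and heteroscedastic, which
  is one reason percent and SD effects in published data do not convert
  exactly linearly (45% pairs with 1.59 SD where the linear map gives
  1.565).
* The analytic power formula assumes the allele-count variance of an
  unselected sample in both case and control arms.
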