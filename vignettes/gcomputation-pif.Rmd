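---
title: "Estimating potential impact fractions of weight-reduction scenarios by g-computation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating potential impact fractions of weight-reduction scenarios by g-computation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimand

The potential impact fraction (PIF) is the proportional reduction in disease
cases that would occur if the population's exposure distribution were shifted
to a counterfactual one,

$$\mathrm{PIF} = 1 - \frac{P_{cf}}{P_{obs}},$$

where $P_{obs}$ is the factual disease prevalence and $P_{cf}$ the prevalence
under the intervention. It generalizes the population attributable fraction,
which assumes complete removal of the exposure — an unrealistic policy target
for adiposity. `gcompif` estimates PIFs for four weight-reduction scenarios on
binary chronic-disease outcomes (diabetes, hypertension, cardiovascular
disease, musculoskeletal disease) from cross-sectional survey data with
design weights.

Estimation is by g-computation (model-based standardization):

1. fit a survey-weighted logistic model for the outcome given the adiposity
   exposure (BMI or waist circumference, WC) and the confounder adjustment
   set;
2. predict each person's risk at their factual exposure and average with the
   survey weights, giving $P_{obs}$;
3. transform the exposure according to the scenario, leaving all covariates
   fixed;
4. predict and average again, giving $P_{cf}$;
5. report $\mathrm{PIF} = 1 - P_{cf}/P_{obs}$ and the risk difference
   $\mathrm{RD} = P_{cf} - P_{obs}$.

Using the *model-predicted* $P_{obs}$ (rather than the raw weighted
prevalence) makes the identity scenario return a PIF of exactly zero — the
same predictions enter numerator and denominator — and is the standard
g-formula plug-in. The empirical denominator is available via
`denominator = "empirical"`; for a well-calibrated logistic model the two are
nearly identical.

## The four scenarios

* **s1 — distribution shift.** Each person in the target population receives
  a counterfactual BMI drawn, with replacement and with survey weights, from
  the empirical BMI distribution of the "normal" reference pool
  ($18.5 \le \mathrm{BMI} < 25$). Draws are marginal (unconditional on
  covariates), as nothing finer is identified by the scenario definition.
  This stochastic scenario brackets what any realistic policy could achieve.
* **s2 — one BMI unit.** $\mathrm{BMI}_{cf} = \mathrm{BMI} - 1$.
* **s3 — 10 % weight loss.** At fixed height BMI is proportional to weight,
  so $\mathrm{BMI}_{cf} = 0.9\,\mathrm{BMI}$.
* **s4 — waist-to-height.** Everyone with $\mathrm{WC}/\mathrm{height} > 0.5$
  has WC lowered to height/2 (the "keep your waist below half your height"
  guideline).

Scenarios s1–s3 are evaluated for two target populations, overweight
(BMI > 25) and obesity (BMI > 30); targets use strict inequalities. s4 has
its single ratio target. Records outside the target keep their factual
exposure bit-for-bit.

**Mean exposure reduction.** The reported mean reduction is the
survey-weighted average of (factual − counterfactual) exposure *over the
target population*: under s2 this is exactly 1 BMI unit by construction,
which pins the averaging basis. A full-population basis (non-targets
contributing zero) is available via `basis = "population"`; for s3 neither
basis is asserted against published summaries because the published averaging
basis is ambiguous.

## Measurement-error correction

Self-reported weight is systematically under-reported and height
over-reported. Measured anthropometry exists only in a small examination
subsample (~4 % of records). `rf_mice_impute()` treats the measured layer as
a missing-data problem: chained-equations multiple imputation with
random-forest conditional models fills measured height, weight and WC for
everyone outside the examination arm — using the self-reported layer, all
covariates, outcomes and design variables as predictors — and fills covariate
gaps in the same chained process. Measured BMI is then *derived* from imputed
measured height and weight, never imputed directly.

Design choices a user should know (none is pinned down by published
descriptions of the approach; each is a documented default):

* **Donor rule.** For each missing cell, one tree is chosen uniformly, the
  cell is dropped to its terminal leaf, and one observed donor in that leaf
  is copied. Donor draws preserve distributional spread, where mean
  prediction would shrink it; imputed categorical values are automatically
  levels present among donors.
* **Visit order** is increasing missingness fraction; **initialization** is a
  uniform draw from observed values.
* **Split-axis sampling (`mtry`).** Because each imputation draws from a
  *single* tree's leaf, every tree must condition well on its own; the usual
  square-root `mtry` deliberately weakens single trees and, with a ~500-record
  validation subsample and ~24 predictors, leaves donors barely conditioned on
  the self-reported values — inflating the imputation noise several-fold and
  attenuating downstream effect estimates. The default is therefore adaptive:
  all predictors per split when the observed pool is small (< 2000 records,
  with the bootstrap resampling still diversifying the trees), and the ranger
  default where training records are plentiful and leaves are tight anyway.
* **Convergence.** The chain mean and SD of freshly imputed values are
  recorded per variable × iteration × imputation. `chain_converged()` turns
  the usual visual check into a rule: the absolute OLS slope of the chain
  mean over the final window must stay below half the SD of the detrended
  means (detrending is what lets a pure drift, whose raw SD is proportional
  to its own slope, be flagged).
* **Seeds.** Per-imputation seed streams are derived from the master seed by
  counter splitting, so completed dataset $j$ does not depend on $m$.

Defaults follow the published settings ($m = 10$, 500 cycles, 100 trees).
Random-forest chains equilibrate in a handful of cycles, so desk-scale runs
in this package's tests use 5–20 cycles and 30–100 trees; the validation
suite verifies at $n = 10\,000$ that the imputation removes a −2 kg
self-report bias and that chains are flat over the final 10 of 20 cycles.

## Outcome models

Survey weights enter the quasibinomial likelihood as frequency-style weights
(normalized to mean one, making coefficients invariant to the weight scale),
with a robust sandwich variance attached; the bootstrap, not the sandwich, is
the primary SE engine for PIFs. Categorical covariates use treatment coding
with the first codebook level as reference. The adjustment set contains the
socio-demographic, lifestyle and environmental confounders plus region and
survey year; metabolic factors (hypertension, hypercholesterolemia) are
mediators or colliders on the adiposity pathway and are refused.

Candidate non-linearities (squared exposure) and exposure × covariate
interactions can be screened by bidirectional stepwise AIC from the
main-effects model. The AIC uses the explicitly weighted Bernoulli
log-likelihood because the textbook binomial AIC silently rounds non-integer
weights. Odds ratios are standardized to a survey-weighted interquartile
range of the exposure, $\exp(\beta\,\mathrm{IQR})$; when selected terms
involve the exposure the main-term OR is flagged as conditional.
Discrimination is assessed by a random 70/30 train/test split and the
survey-weighted AUC, averaged over the $m$ completed datasets.

## Uncertainty: bootstrap within, Rubin's rules across

Within each completed dataset, standard errors come from a nonparametric
bootstrap (default 1000 replicates at full scale; 200 in the desk-scale
configurations). Each replicate resamples records with replacement
(cluster-within-stratum resampling is available via `boot_unit = "cluster"`;
published descriptions do not state whether the design was respected, so the
i.i.d. record bootstrap is the default), refits the outcome model, and
re-applies the scenario — including fresh s1 draws from the replicate's own
reference pool, so scenario randomness propagates into the SE. Term
selection, when requested, is performed once on the full data and the
selected term set is held fixed across replicates; refitting coefficients
per replicate captures the estimation uncertainty the SE is meant to
reflect, while re-running selection inside every replicate would mix model
uncertainty into a quantity reported for a fixed model.

Per-imputation estimates are pooled by Rubin's rules on the raw fraction
scale: pooled point $\bar Q$, within-variance $W$, between-variance $B$,
total variance $T = W + (1 + 1/m)B$ — the $(1+1/m)$ term is the finite-$m$
correction — and classical Rubin degrees of freedom. With $n \gg m$ the
Barnard–Rubin small-sample refinement is immaterial.

## The synthetic generator and its oracle

Published analyses of this kind run on access-restricted national survey
microdata, so validation rests on a synthetic generator whose truth is known.
`default_population_spec()` emulates the structure of a merged
interview/examination survey of Belgian adults:

* fourteen covariates (age, sex, education, income quintile, household type,
  smoking, indoor smoking, alcohol score 1–5, physical activity, black
  carbon, vegetation cover, road-noise indicator, region, survey year) with
  plausible marginals and confounding links (e.g. environmental exposures
  depend on region and income; BMI depends on age, sex, education and
  activity);
* true BMI with conditional SD 5.3 kg/m² given covariates and overweight
  prevalence ≈ 48 %; height by sex; weight derived so the
  weight/height²–BMI identity is exact in floating point; WC structurally
  linked to BMI (slope 2.35, residual SD 4.3 cm, implying a conditional WC SD
  of ≈ 13.2 cm);
* a self-report layer with −2 kg weight and +1 cm height bias plus noise;
  an examination arm of 4.3 % carrying the measured layer;
* four outcomes from logistic models in centered BMI and the covariates,
  calibrated to prevalences of roughly 5.5 / 30 / 7 / 40 %;
* a schematic two-stage design: stratum = region × year, 20 clusters per
  stratum, i.i.d. lognormal weights. Weights are deliberately independent of
  covariates so that the weighted estimand coincides with the generator's
  marginal truth — a replica of a national weighting procedure is neither
  public nor needed for validating the estimator;
* missing-at-random gaps in income (6 %), driven by age and sex; arbitrary
  per-variable rates are configurable.

Disease risk depends on adiposity through BMI; WC is a structural marker of
BMI. The oracle `true_pif()` therefore evaluates the WC scenario by holding
each person's WC residual fixed and lowering BMI through the inverse
structural link, while the estimator uses the fitted WC outcome model as the
analysis prescribes. The WC model integrates over the WC residual and is
thereby very mildly misspecified (≈ 1 % relative attenuation at the default
noise level) — far inside the validation tolerance, and a realistic feature:
no analyst's model is exactly the data-generating process.

What the generator does **not** emulate: informative sampling weights,
longitudinal structure, missingness that is not MAR, measurement error in
the examination instruments, spatial rasters behind the environmental
exposures, and the real covariate joint distribution. Passing tests
demonstrate estimator correctness under the stated mechanism, not calibration
to any real population.

The oracle is estimator-independent: it simulates from the specification and
evaluates the true risk model at factual and counterfactual exposures,
reporting a delta-method Monte-Carlo SE alongside.

## Numerical choices

* Bootstrap replicates refit by damped Newton iterations on the fixed design
  matrix, warm-started at the full-data coefficients; counterfactual designs
  are formed by rescaling the exposure-bearing columns (exposures are
  strictly positive), which reproduces the general model-matrix route
  bit-for-bit.
* Replicates with a single-class outcome or a failed fit are dropped and
  counted; more than 10 % dropped is an error, as is a replicate failure rate
  above 5 % in the simulation harness.
* Ties at target boundaries follow the strict inequalities of the scenario
  definitions; BMI draws and transforms never touch non-target records, so
  their exposures are bit-identical before and after.
* All randomness flows from one master seed through counter-based splitting
  (generation, per-imputation chains, per-replicate resampling, s1 draws),
  making every pipeline output byte-reproducible.
* Model export uses 17-significant-digit JSON so predictions survive a
  serialize/deserialize round trip bit-for-bit.

## Diagnostics

`positivity_overlap()` examines the experimental-treatment-assignment
assumption: a logistic membership model for the exposed class (default
BMI > 25) on the confounders, with the overlap coefficient (integrated
minimum of the two 50-bin histogram densities of predicted membership
probabilities) summarizing how much the target and reference groups share
covariate support. The coefficient is symmetric in the labels; the default
plausibility threshold of 0.2 is a convention, not an inferential cutoff.
`conditional_sd()` reports the weighted residual SD of BMI or WC given the
covariates — the natural scale against which scenario shifts are judged.
`run_simulation_study()` wraps generate → (impute) → estimate → pool and
reports bias, RMSE, empirical SE, mean bootstrap SE and CI coverage against
the oracle.

## Problem sizes used in validation

The shipped validation suite runs on one CPU: oracle recovery uses
$n = 20\,000$ records, $m = 5$ imputations (5 cycles, 30 trees), 200
bootstrap replicates and two outcomes across the four scenarios; coverage
uses 200 simulation replicates at $n = 2\,000$ with 200 bootstrap replicates;
bias-recovery uses $n = 10\,000$ with a 5 % examination arm, $m = 5$, 20
cycles and 50 trees. The published full-scale settings remain one
configuration object away.

## Known limitations

* Cross-sectional data cannot establish temporal ordering; the package
  quantifies the estimand under the stated causal assumptions, it does not
  test them.
* s1/s4 are strongly counterfactual; positivity should be inspected with
  `positivity_overlap()` before interpreting their PIFs causally.
* The i.i.d. bootstrap ignores any design effect of clustering unless
  `boot_unit = "cluster"` is chosen.
* PIFs are pooled on the raw fraction scale; a logit-scale pooling option
  would be preferable only for PIFs near the boundaries.
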