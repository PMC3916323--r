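---
title: "Scoring diet quality and modelling anthropometric change with pnnsgs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring diet quality and modelling anthropometric change with pnnsgs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnnsgs)
```

## The problem

The French Programme National Nutrition Santé (PNNS) publishes quantitative
diet and physical-activity guidelines. The PNNS Guideline Score (PNNS-GS)
summarizes adherence to them as a 13-component index ranging from 0 to 15
points: eight components reward meeting food-serving recommendations (fruits
and vegetables, starches, whole grains, dairy, meat/fish/eggs, seafood,
vegetable fat, water over soda), four penalize overconsumption of foods to be
limited (added fat, added sugar, alcohol, salt), and one covers physical
activity. A dietary-only variant, the mPNNS-GS, drops the activity component
(maximum 13.5 points). `pnnsgs` implements the complete computational chain
used in nutritional-epidemiology cohorts: repeated 24-h dietary records are
validated and averaged into habitual intake, the score and its
energy-adequacy penalty are computed, and six-year percent changes in weight
and waist circumference are compared across score categories with ANCOVA
least-squares means.

Because individual-level data from the cohort that motivated this pipeline
are not publicly deposited, the package ships a synthetic-cohort generator
with the same tabular structure, so every stage is testable end to end and
effect sizes can be injected and recovered.

## Scoring rules

Component cutoffs live in a single configuration object
(`default_score_config()`, also shipped as
`inst/extdata/pnnsgs-config.yaml`). Conventions that required a decision:

* **Interval endpoints.** The printed cutoff table uses overlapping brackets
  (e.g. `[3.5–5]` followed by `[5–7.5]`). We implement half-open intervals
  `[a, b)` with the upper row winning at its lower bound, so the partition is
  well-defined; five servings of fruits and vegetables score 1 point, not
  0.5. Bands whose successor row is printed with a strict `>` (dairy, meat)
  are closed at the top: 3.5 dairy servings still score the full point.
  The salt cutpoints are right-closed as printed (`≤ 6 g/d` scores 1.5).
  An alternate convention is a one-file YAML edit.
* **Reference-sourced cells.** The intermediate starch, meat and salt bands
  follow the original score definition (Estaquio et al. 2009) and are flagged
  `source: "reference"` in the configuration.
* **Dairy age bands.** The recommended band widens from `[2.5, 3.5]` to
  `[2.5, 4.5]` servings/day at age ≥ 55 at baseline.
* **Alcohol.** Abstainers and irregular consumers (< once a week) score the
  full point; drinkers within the sex-specific ethanol thresholds (20 g/d
  women, 30 g/d men, inclusive) score 0.8; above them, 0.
* **Questionnaire components.** Alcohol and seafood come from questionnaire
  fields of the participant table, never from the 24-h records, matching how
  such cohorts collect them.

The configuration is validated at load: component maxima must sum to 15
overall and 13.5 over the twelve dietary components.

## Energy-adequacy penalty

Energy needs are Schofield basal metabolic rate (sex/age-band linear
equations in weight; the standard 1985 coefficients ship as data) multiplied
by a physical-activity-level factor (1.55 / 1.70 / 1.85 for the low / medium
/ high activity classes). If reported energy intake exceeds needs by a
fraction f > 5 %, the same fraction is deducted: a raw score of 7 with
f = 10 % becomes 6.3. Two corners the source rules leave open: exactly 5 %
overconsumption is tolerated (the rule is strict), and non-positive raw
totals are never penalized further (a proportional deduction on a negative
score would otherwise *raise* it). Both penalized and unpenalized totals are
always retained; `penalize = FALSE` reproduces the unpenalized sensitivity
analysis.

## Physical activity

Weekly MET-hours are summed over leisure activities practised at least 10
times a year with sessions of at least 10 minutes, using a configurable
intensity table in which brisk walking is 6.5 MET — this keeps the anchor
"30 min/day on 5 days/week ≡ 16.25 MET-h/week" exact. MET-hours convert to a
minutes-of-walking equivalent through that anchor and then to the 0 / 1 / 1.5
point classes at 30 and 60 min/day. When the activity questionnaire is
missing, two fallback items classify the extremes (no regular activity →
low; regular activity equivalent to ≥ 1 h walking/day → high); the remaining
subjects are assigned low or medium by deterministic regression imputation
(`regression_impute()`, highest-probability class, no stochastic draw), as
the field's convention for this questionnaire gap.

## Record validity and participant selection

Records under 100 or over 6000 kcal/day are implausible (strict
inequalities; the boundary values are retained). Participants are excluded,
in a fixed logged order, for: baseline age outside 45–60, missing or < 25
measured baseline BMI, fewer than three valid records, habitual low-energy
reporting (more than one third — strictly — of records below 800 kcal/day for
men or 500 for women), incomplete covariates, and incident disease. Each
exclusion is logged once with a stable rule code, so inclusion + exclusions
always reconstruct the input. The denominator of the low-energy rule is
ambiguous in the source description; we default to records surviving the
validity filter and expose `count_basis = "all"` as the alternative.

## Under-reporting (Goldberg/Black)

The sensitivity analysis excludes subjects whose mean EI:BMR falls below the
Black (2000) lower cutoff `PAL × exp(−2 S/100)` with
`S = sqrt(cv_EI²/n + cv_BMR² + cv_PAL²)`, n the subject's record count and
CV defaults 23 / 8.5 / 15 %. The PAL factors are the same 1.55 / 1.70 / 1.85
set used for energy needs (the two tables share one configuration entry by
default). The CV values and the one-sided −2 multiplier are the method's
canonical parameterization, stated here as package assumptions — they are
config-exposed, not facts inherited from any particular cohort.

## Statistical models

Outcomes are exact percent changes `(follow-up − baseline)/baseline × 100`
(absolute weight change is retained for a transformation-robustness check).
Three ANCOVA models per sex stratum: A crude; B adds baseline age and energy
intake (and, for the mPNNS-GS, a binary < 30 vs ≥ 30 min/day activity
indicator); C adds supplementation arm, number of records, baseline height,
education and smoking, plus menopausal status in all-female strata.
Education and smoking are unordered factors; age and record count are
continuous (the source is silent; these are the package defaults).

Least-squares means are evaluated at the covariate means of the analysed
stratum, averaging factor covariates with their observed frequencies. The
low-vs-high and medium-vs-high contrasts use the Dunnett many-to-one
adjustment computed from the multivariate t distribution with the estimated
contrast correlation (via `emmeans`, `adjust = "mvt"`); the same critical
value furnishes the confidence intervals of all three category means,
including the reference. The overall p-value is the F-test of the category
factor; the category-by-sex interaction is the F-test of the product terms
in the pooled model. All tests are two-sided. The multivariate-t integration
is quasi-random; its RNG is fixed internally so identical inputs give
bit-identical output (and a weighted fit with unit weights reproduces the
unweighted fit exactly).

The inverse-probability-weighting reanalysis fits a logistic inclusion model
on baseline characteristics of the parent cohort (missing predictors first
resolved by deterministic regression imputation), weights included subjects
by the inverse fitted probability, refits the ANCOVA, and reports weight
diagnostics; an error is raised if an included subject has fitted inclusion
probability 0.

## The synthetic cohort

Each subject carries a latent diet-quality level q. We draw q from a
symmetric Beta(5, 5): with the monotone component maps this centres realized
PNNS-GS near 7.4 points with SD ≈ 2.9 and populates all three categories
(roughly 31 / 40 / 29 %), a reasonable image of a middle-aged overweight
cohort in which the validation-sample score was about 7.5 ± 1.9. All
food-group servings, nutrient shares, beverages, salt, alcohol and MET-hours
are monotone affine functions of q plus subject- and day-level noise;
records-per-subject follow a discretized mixture on 3–20 with mean ≈ 10.5
and mode 13. Reported energy scatters (within-subject CV 20 %) around a true
energy tied to Schofield needs, with overconsumption decreasing in q from
about +18 % to −10 %. Day-to-day variance is config-exposed
(`within_sd_scale`) because the source material gives no within-subject
variance estimates.

Follow-up weight is baseline weight ×
`(1 + (g(category) + bmi_slope·(BMI − 27) + ε)/100)`, where `g` is the
sex-specific effect model applied to the subject's *realized* penalized
PNNS-GS category and ε is Normal with SD 4 percentage points by default. The
default `g` equals the crude (model A) published least-squares means — the
crude estimates are the right target for a generator with no model-C
covariate structure. Waist circumference is a noisy affine function of
weight, so WC analyses are exercisable; it emulates no real WC biology.
Missingness can be injected completely at random or BMI-dependently (for IPW
validation), and energy under-reporting scales a random fraction of
subjects' reported record energies while the truth table keeps complete
values.

What passing tests therefore show: the scoring rules, filters, penalty, and
the estimation machinery recover injected truths under a well-specified
generative model with exchangeable records. What they cannot show: behaviour
under real food-composition structure, seasonal/weekday record patterns,
differential measurement error, or misspecified selection models.

## Numerical choices and problem sizes

* Category breakpoints are half-open everywhere (6/9 for PNNS-GS, 5.5/8.5
  for mPNNS-GS): 8.999 points is "medium", 9.0 is "high".
* Parameter-recovery checks run 50 replicate cohorts of 3200 subjects
  (≈ 1000 per category) with injected male means 3.6 / 2.5 / 2.1 % and SD 4;
  crude LS-means are required within 3 SE of the injected values and the
  low-vs-high Dunnett test must reject in at least 80 % of replicates.
* The Dunnett p-value is cross-checked against a 10⁶-replicate Monte-Carlo
  max-|t| oracle simulated directly from the shared-control construction
  (tolerance 0.005 on the 3-group, n = 20/group fixture).
* The IPW property uses 100 replicate cohorts of 900 subjects with a
  BMI-dependent outcome (slope 0.5 %/BMI unit) under logistic BMI-dependent
  selection and under MCAR.
* Degenerate inputs: empty cohorts are valid; a single non-empty category,
  unknown sex, rank-deficient designs, non-positive energy needs and
  all-missing predictors raise typed errors naming the offender.

## Known limitations

Serving-size definitions (grams per serving) are upstream of this package:
inputs are already servings/day. Food-composition modelling, multiple
imputation, longitudinal mixed models and causal mediation are out of scope.
The generator treats records as exchangeable; it does not emulate the
designed weekday/season balance of real record schedules.
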