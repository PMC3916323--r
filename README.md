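# pnnsgs

Diet-quality scoring and anthropometric-change analysis with the French
PNNS Guideline Score.

Nutritional epidemiologists studying secondary obesity prevention need to
turn repeated 24-h dietary records into an a-priori diet-quality index and
relate it to long-term anthropometric change. `pnnsgs` implements that chain
for the Programme National Nutrition Santé Guideline Score (PNNS-GS): a
13-component index (0–15 points) of adherence to French diet and
physical-activity recommendations, and its dietary-only variant, the
mPNNS-GS (0–13.5 points).

The pipeline covers:

* **Record handling** — validity filtering (records < 100 or > 6000 kcal/d
  are implausible), sex-specific habitual low-energy-reporter exclusion
  (> 1/3 of records below 800 kcal/d for men, 500 for women), participant
  selection (age 45–60, measured BMI ≥ 25, ≥ 3 valid records, complete
  covariates, no incident disease) with a one-row-per-exclusion log, and
  averaging of valid records into habitual intake.
* **Scoring** — all 13 components from a single editable configuration
  (`inst/extdata/pnnsgs-config.yaml`), Schofield BMR × PAL energy needs, and
  the energy-adequacy penalty: if energy intake EI exceeds needs N by
  f = (EI − N)/N > 5 %, the score S becomes S·(1 − f); a raw score of 7 at
  10 % overconsumption becomes 6.3. Categories: PNNS-GS < 6 low, [6, 9)
  medium, ≥ 9 high; mPNNS-GS at 5.5/8.5.
* **Physical activity** — MET-hours/week from leisure activities
  (16.25 MET-h/week ≡ 30 min/day of brisk walking at 6.5 MET), fallback
  questionnaire items, deterministic regression imputation of unresolved
  cases.
* **Under-reporting** — Goldberg/Black lower cutoff
  PAL·exp(−2·S/100), S = √(cv²_EI/n + cv²_BMR + cv²_PAL), for the severe
  sensitivity analysis.
* **Inference** — ANCOVA least-squares means of percent weight / waist
  change by score category (crude A, adjusted B, fully adjusted C models,
  stratified by sex) with Dunnett many-to-one adjustment (multivariate t),
  score-by-sex interaction test, Kruskal-Wallis/χ² descriptive tables, and
  an inverse-probability-weighting reanalysis for selection bias.
* **Synthetic cohorts** — a generator with a latent diet-quality factor,
  configurable score-category → weight-change effects, missingness (MCAR or
  BMI-dependent) and energy under-reporting, so the whole pipeline is
  testable without access to cohort data.

## Worked example

Score one participant's habitual intake:

```r
library(pnnsgs)
library(tibble)

intake <- tibble(
  participant_id = "p1", n_valid_records = 11, energy_kcal = 2600,
  fruit_veg_serv = 4.2, starch_serv = 3.1, wholegrain_frac = 0.4,
  dairy_serv = 2.8, meat_serv = 1.6, seafood_serv_week = 2.5,
  addedfat_pct_ei = 14, vegfat_ratio = 0.6, sugar_pct_ei = 11,
  water_ml = 1100, soda_ml = 100, salt_g = 7.5,
  alcohol_g_day = 18, alcohol_freq_week = 4)
participant <- tibble(
  participant_id = "p1", sex = "M", age = 52, height_cm = 176,
  weight_baseline_kg = 86,
  pa_class = factor("medium", c("low", "medium", "high")), pa_points = 1)

compute_scores(intake, participant)
#>   raw_total energy_needs overconsumption_fraction pnns_gs m_pnns_gs pnns_category
#> 1      11.8         3190                        0    11.8      10.8          high
```

The 13 components sum to 11.8 points (e.g. 4.2 fruit/vegetable servings →
0.5, alcohol 18 g/d ≤ 30 for a man → 0.8, salt 7.5 g/d → 1); energy intake
(2600 kcal/d) is below the estimated needs (Schofield BMR × PAL 1.70 =
3190 kcal/d), so no penalty applies, and 11.8 ≥ 9 puts the subject in the
high category.

Run the full synthetic study — simulate, filter, score, model:

```r
run <- run_pipeline(cohort_spec(n_participants = 2000, seed = 42),
                    models = "A", scores = "pnns")
run
#> <pnns_run> seed 42
#>   2000 generated, 1968 included (1968 analysed)
#>   exclusions: AGE=0, BMI=0, MIN_RECORDS=0, LOW_ENERGY_REPORTER=0,
#>               MISSING_COVARIATES=0, INCIDENT_DISEASE=32
#>   contrasts (men):
#>   category   n ls_mean ci_low ci_high p_vs_ref
#>   low      477    3.36   2.96    3.76  1.9e-07
#>   medium   521    2.44   2.05    2.82  0.075
#>   high     380    1.89   1.44    2.34       NA
```

The crude least-squares means in men recover the generator's default
injected effects (low 3.35 %, medium 2.23 %, high 1.76 % six-year weight
gain) within sampling error; the Dunnett-adjusted low-vs-high p-value is
1.9 × 10⁻⁷. `tidy()` on any fit returns the contrast table as a tibble;
`autoplot()` draws the forest plot; `glance()` gives the overall F-test.

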