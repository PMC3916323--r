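Package: pnnsgs
Title: Diet-Quality Scoring and Anthropometric-Change Analysis with the
    French PNNS Guideline Score
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the 13-component Programme National Nutrition Sante
    Guideline Score (PNNS-GS) and its dietary-only variant (mPNNS-GS) from
    repeated 24-h dietary records, including the energy-overconsumption
    penalty based on Schofield basal metabolic rate and physical activity
    level, MET-hour quantification of leisure activity, record-validity and
    low-energy-reporter exclusion rules, and Goldberg/Black under-reporter
    flagging.  Provides ANCOVA least-squares means of six-year percent
    anthropometric change by score category with Dunnett many-to-one
    adjustment, a score-by-sex interaction test, Kruskal-Wallis/chi-squared
    descriptive tables, deterministic regression imputation, and an
    inverse-probability-weighting reanalysis for selection bias.  A
    synthetic-cohort generator with configurable score-outcome effects,
    missingness and energy under-reporting makes the full pipeline testable
    without access to the original cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
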