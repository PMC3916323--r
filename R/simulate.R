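#' Specification of a synthetic cohort
#'
#' Collects every knob of the synthetic-cohort generator: cohort size and
#' composition, the records-per-subject distribution (integers on 3-20 with
#' mean close to 10), the score-category effect model for percent weight
#' change, missingness, and energy under-reporting.
#'
#' Default effect model: the sex-specific crude least-squares means of
#' six-year percent weight change by PNNS-GS category (men 3.35 / 2.23 /
#' 1.76 %, women 1.70 / 2.63 / 3.58 % for low / medium / high) with residual
#' standard deviation 4 percentage points.
#'
#' @param n_participants Number of subjects.
#' @param sex_ratio Fraction male, in `[0, 1]`.
#' @param age_range Baseline age window, years.
#' @param bmi_min Minimum baseline BMI, kg/m2; every generated subject is at
#'   or above it.
#' @param records_dist Named numeric vector of probabilities over record
#'   counts (names are the counts, support within 1-30).  `NULL` uses the
#'   default mixture on 3-20 with mean about 10 and mode 13.
#' @param effect_model List with numeric vectors `M` and `F` (named low /
#'   medium / high: mean percent weight change per realized PNNS-GS
#'   category), `sd` (residual SD, percentage points, > 0) and `bmi_slope`
#'   (additional percent change per BMI unit above 27; default 0).
#' @param missingness List with `probs` (named per-field missing
#'   probabilities), `mechanism` (`"MCAR"` or `"bmi"`) and `bmi_coef`
#'   (log-odds of missingness per BMI unit, used by the `"bmi"` mechanism).
#' @param underreport List with `fraction` (share of subjects whose reported
#'   energies are scaled down) and `factor` (the scaling, < 1).
#' @param maq_missing_prob Share of subjects whose activity questionnaire is
#'   missing (routed to the fallback items / imputation path).
#' @param within_sd_scale Multiplier on the within-subject day-to-day SDs.
#' @param seed RNG seed (integer).
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 1000,
                        sex_ratio = 0.7,
                        age_range = c(45, 60),
                        bmi_min = 25,
                        records_dist = NULL,
                        effect_model = list(
                          M = c(low = 3.35, medium = 2.23, high = 1.76),
                          F = c(low = 1.70, medium = 2.63, high = 3.58),
                          sd = 4, bmi_slope = 0),
                        missingness = list(probs = NULL, mechanism = "MCAR",
                                           bmi_coef = 0.4),
                        underreport = list(fraction = 0, factor = 0.7),
                        maq_missing_prob = 0.14,
                        within_sd_scale = 1,
                        seed = 1L) {
  if (is.null(records_dist)) records_dist <- default_records_dist()
  spec <- list(n_participants = n_participants, sex_ratio = sex_ratio,
               age_range = age_range, bmi_min = bmi_min,
               records_dist = records_dist, effect_model = effect_model,
               missingness = missingness, underreport = underreport,
               maq_missing_prob = maq_missing_prob,
               within_sd_scale = within_sd_scale, seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

#' Default records-per-subject distribution
#'
#' Probabilities over 3-20 records from a two-component discretized normal
#' mixture (bulk centred near 12.5 days, a smaller early-dropout mode near
#' 5), giving mean close to 10 and mode 13.
#' @return Named probability vector over `3:20`.
#' @export
default_records_dist <- function() {
  k <- 3:20
  w <- 0.62 * stats::dnorm(k, 12.9, 1.2) + 0.38 * stats::dnorm(k, 5.2, 2.8)
  stats::setNames(w / sum(w), k)
}

validate_cohort_spec <- function(spec) {
  fail <- function(field, why) {
    abort(sprintf("invalid cohort_spec field '%s': %s", field, why),
          class = "pnnsgs_error_spec")
  }
  if (!is.numeric(spec$n_participants) || spec$n_participants < 0 ||
      spec$n_participants != round(spec$n_participants)) {
    fail("n_participants", "must be a non-negative integer")
  }
  if (spec$sex_ratio < 0 || spec$sex_ratio > 1) {
    fail("sex_ratio", "must lie in [0, 1]")
  }
  if (spec$bmi_min <= 0) fail("bmi_min", "must be positive")
  rd <- spec$records_dist
  support <- as.integer(names(rd))
  if (anyNA(support) || any(support < 1 | support > 30)) {
    fail("records_dist", "support must be integers within 1..30")
  }
  if (any(rd < 0) || abs(sum(rd) - 1) > 1e-8) {
    fail("records_dist", "probabilities must be non-negative and sum to 1")
  }
  em <- spec$effect_model
  if (is.null(em$sd) || em$sd <= 0) fail("effect_model$sd", "must be > 0")
  for (s in c("M", "F")) {
    if (!all(c("low", "medium", "high") %in% names(em[[s]]))) {
      fail(paste0("effect_model$", s),
           "needs named means for low, medium and high")
    }
  }
  pr <- spec$missingness$probs
  if (!is.null(pr) && (any(pr < 0) || any(pr > 1))) {
    fail("missingness$probs", "probabilities must lie in [0, 1]")
  }
  ur <- spec$underreport
  if (ur$fraction < 0 || ur$fraction > 1) {
    fail("underreport$fraction", "must lie in [0, 1]")
  }
  if (ur$factor <= 0 || ur$factor > 1) {
    fail("underreport$factor", "must lie in (0, 1]")
  }
  if (spec$maq_missing_prob < 0 || spec$maq_missing_prob > 1) {
    fail("maq_missing_prob", "must lie in [0, 1]")
  }
  invisible(spec)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# subject-level mean dietary behaviour as a monotone map of latent quality q
latent_to_means <- function(q, sex) {
  tibble(
    fruit_veg_serv = 1.8 + 7.5 * q,
    starch_serv = 1.3 + 3.2 * q,
    wholegrain_frac = clamp(0.08 + 0.85 * q, 0, 1),
    dairy_serv = 0.7 + 2.6 * q,
    meat_serv = 2.55 - 1.4 * q,
    addedfat_pct_ei = 21.5 - 9 * q,
    vegfat_ratio = clamp(0.28 + 0.65 * q, 0, 1),
    sugar_pct_ei = 20.5 - 12 * q,
    water_ml = 520 + 950 * q,
    soda_ml = pmax(420 * (1 - q) - 60, 0),
    salt_g = 12.2 - 7 * q
  )
}

#' Generate a synthetic cohort
#'
#' Draws a cohort with the statistical structure the analysis pipeline
#' assumes.  Each subject carries a latent diet-quality level on `[0, 1]`
#' that drives all food-group servings, nutrient shares, beverages, salt,
#' alcohol and physical activity monotonically, so realized PNNS-GS values
#' span the low / medium / high categories.  Reported record energy scatters
#' around a subject-level true energy tied to Schofield-based needs, with
#' overconsumption decreasing in diet quality.  Follow-up weight is baseline
#' weight times `1 + (g(category) + bmi_slope * (BMI - 27) + e) / 100`, where
#' `g` is the effect model for the subject's realized (penalized) PNNS-GS
#' category and `e` is Normal with the configured residual SD.  Waist
#' circumference is a noisy affine function of weight.
#'
#' The generator is deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort`: `participants` (one row per
#'   subject), `records` (one row per 24-h record) and `truth` (latent
#'   quality, true energy, true activity class, realized categories and
#'   injected means; never read by the pipeline).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n_participants
  if (n == 0) {
    return(empty_cohort(spec))
  }
  id <- sprintf("P%05d", seq_len(n))
  sex <- ifelse(runif(n) < spec$sex_ratio, "M", "F")
  age <- round(runif(n, spec$age_range[1], spec$age_range[2]), 1)
  # latent diet quality: bell-shaped on [0,1] so realized scores centre near
  # 7.5 points with SD about 2 and all three categories populated
  q <- stats::rbeta(n, 5, 5)

  height_cm <- round(ifelse(sex == "M", rnorm(n, 175, 6.5),
                            rnorm(n, 162, 6)), 1)
  bmi <- spec$bmi_min + stats::rgamma(n, shape = 2, scale = 1.4)
  weight0 <- round(bmi * (height_cm / 100)^2, 1)
  # rounding must not push BMI below the configured floor
  weight0 <- pmax(weight0,
                  ceiling(spec$bmi_min * (height_cm / 100)^2 * 10) / 10)
  bmi <- weight0 / (height_cm / 100)^2

  # physical activity: MET-hours increasing in q; some MAQ questionnaires
  # missing -> fallback items only
  met_true <- pmax(q * 32 + rnorm(n, 0, 5), 0)
  true_minutes <- met_true / 16.25 * 30
  true_pa <- cut(true_minutes, c(-Inf, 30, 60, Inf),
                 labels = c("low", "medium", "high"), right = FALSE)
  maq_missing <- runif(n) < spec$maq_missing_prob
  met_hours_week <- ifelse(maq_missing, NA_real_, met_true)
  pa_regular <- ifelse(maq_missing, met_true > 3, NA)
  pa_walk_1h <- ifelse(maq_missing, true_minutes >= 60, NA)

  # energy: needs from Schofield x PAL at the true activity class;
  # overconsumption shrinks with diet quality
  bmr <- schofield_bmr(sex, age, weight0)
  needs <- estimate_energy_needs(bmr, true_pa)
  true_energy <- needs * (1.18 - 0.28 * q + rnorm(n, 0, 0.05))

  # questionnaire items
  abstainer <- runif(n) < 0.12
  alcohol_g_day <- ifelse(abstainer, 0,
                          pmax((1 - q) * ifelse(sex == "M", 45, 26) +
                                 rnorm(n, 0, 8), 0))
  alcohol_freq_week <- ifelse(abstainer, 0,
                              pmax(round((1 - q) * 6 + rnorm(n, 0, 1.5)), 1))
  seafood_serv_week <- pmax(0.3 + 3 * q + rnorm(n, 0, 0.8), 0)

  education <- sample(c("primary", "secondary", "university"), n,
                      replace = TRUE, prob = c(0.28, 0.37, 0.35))
  smoking <- sample(c("never", "former", "current"), n, replace = TRUE,
                    prob = c(0.41, 0.48, 0.11))
  supplementation <- sample(c("placebo", "antioxidant"), n, replace = TRUE)
  menopause <- ifelse(sex == "F", runif(n) < 0.52, NA)
  incident_disease <- runif(n) < 0.02

  # 24-h records
  k <- sample(as.integer(names(spec$records_dist)), n, replace = TRUE,
              prob = spec$records_dist)
  subj_means <- latent_to_means(q, sex)
  idx <- rep(seq_len(n), k)
  m <- subj_means[idx, ]
  ws <- spec$within_sd_scale
  nr <- length(idx)
  records <- tibble(
    participant_id = id[idx],
    record_index = unlist(lapply(k, seq_len)),
    energy_kcal = pmax(true_energy[idx] * (1 + rnorm(nr, 0, 0.20 * ws)), 60),
    fruit_veg_serv = pmax(m$fruit_veg_serv + rnorm(nr, 0, 1.6 * ws), 0),
    starch_serv = pmax(m$starch_serv + rnorm(nr, 0, 1.0 * ws), 0),
    wholegrain_frac = clamp(m$wholegrain_frac + rnorm(nr, 0, 0.15 * ws), 0, 1),
    dairy_serv = pmax(m$dairy_serv + rnorm(nr, 0, 0.9 * ws), 0),
    meat_serv = pmax(m$meat_serv + rnorm(nr, 0, 0.8 * ws), 0),
    addedfat_pct_ei = clamp(m$addedfat_pct_ei + rnorm(nr, 0, 4 * ws), 0, 100),
    vegfat_ratio = clamp(m$vegfat_ratio + rnorm(nr, 0, 0.12 * ws), 0, 1),
    sugar_pct_ei = clamp(m$sugar_pct_ei + rnorm(nr, 0, 4 * ws), 0, 100),
    water_ml = pmax(m$water_ml + rnorm(nr, 0, 250 * ws), 0),
    soda_ml = pmax(m$soda_ml + rnorm(nr, 0, 90 * ws), 0),
    salt_g = pmax(m$salt_g + rnorm(nr, 0, 2 * ws), 0.5)
  )

  participants <- tibble(
    participant_id = id, sex = sex, age = age, height_cm = height_cm,
    weight_baseline_kg = weight0, alcohol_g_day = alcohol_g_day,
    alcohol_freq_week = alcohol_freq_week,
    seafood_serv_week = seafood_serv_week,
    met_hours_week = met_hours_week, pa_regular = pa_regular,
    pa_walk_1h = pa_walk_1h, education = education, smoking = smoking,
    supplementation = supplementation, menopause = menopause,
    incident_disease = incident_disease, n_records = k
  )

  # realized score category (penalized PNNS-GS) using the true activity class
  intake <- average_records(records, participants, on_empty = "drop")
  scoring_p <- participants |>
    mutate(pa_class = factor(true_pa, levels = c("low", "medium", "high")),
           pa_points = unname(default_score_config()$pa_points[
             as.character(true_pa)]))
  scores <- compute_scores(intake, scoring_p)
  cat_pnns <- scores$pnns_category[match(id, scores$participant_id)]
  cat_mpnns <- scores$mpnns_category[match(id, scores$participant_id)]

  em <- spec$effect_model
  g <- ifelse(sex == "M", em$M[as.character(cat_pnns)],
              em$F[as.character(cat_pnns)])
  bmi_slope <- em$bmi_slope %||% 0
  eps <- rnorm(n, 0, em$sd)
  delta_pct <- g + bmi_slope * (bmi - 27) + eps
  weight1 <- round(weight0 * (1 + delta_pct / 100), 2)
  wc0 <- round(45 + 0.58 * weight0 + rnorm(n, 0, 3), 1)
  wc1 <- round(wc0 * (1 + (0.6 * delta_pct + rnorm(n, 0, 1.5)) / 100), 1)

  participants$weight_followup_kg <- weight1
  participants$wc_baseline_cm <- wc0
  participants$wc_followup_cm <- wc1

  truth <- tibble(
    participant_id = id, latent_quality = q, true_energy = true_energy,
    true_pa_class = factor(true_pa, levels = c("low", "medium", "high")),
    pnns_category = cat_pnns, mpnns_category = cat_mpnns,
    injected_mean = unname(g), injected_delta_pct = delta_pct,
    underreporter = FALSE, underreport_factor = 1
  )

  structure(list(participants = participants, records = records,
                 truth = truth, spec = spec),
            class = "synthetic_cohort")
}

empty_cohort <- function(spec) {
  skel <- generate_cohort_impl(utils::modifyList(spec, list(
    n_participants = 2L)))
  structure(list(participants = skel$participants[0, ],
                 records = skel$records[0, ], truth = skel$truth[0, ],
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$participants), "participants,",
      nrow(x$records), "records\n")
  invisible(x)
}

#' Inject missing values into a cohort
#'
#' Sets fields of the participant or record tables to `NA`, either completely
#' at random (`mechanism = "MCAR"`) or with probability depending on declared
#' baseline BMI (`mechanism = "bmi"`: log-odds shifted by
#' `bmi_coef * (BMI - mean BMI)`, so the marginal rate stays close to the
#' nominal probability).  The truth table and the stashed complete copies are
#' untouched, so inverse-probability-weighting analyses can be validated
#' against full data.
#'
#' @param cohort A `synthetic_cohort`.
#' @param spec Optional [cohort_spec()]; defaults to the cohort's own.  Its
#'   `missingness` element supplies `probs` (named per-field probabilities),
#'   `mechanism` and `bmi_coef`.
#' @return The cohort with `NA`s injected and `participants_complete` /
#'   `records_complete` stashed (first call only).
#' @export
inject_missingness <- function(cohort, spec = cohort$spec) {
  ms <- spec$missingness
  probs <- ms$probs
  if (is.null(probs) || length(probs) == 0) return(cohort)
  if (any(probs < 0 | probs > 1)) {
    abort("invalid cohort_spec field 'missingness$probs': must lie in [0, 1]",
          class = "pnnsgs_error_spec")
  }
  if (is.null(cohort$participants_complete)) {
    cohort$participants_complete <- cohort$participants
    cohort$records_complete <- cohort$records
  }
  mechanism <- ms$mechanism %||% "MCAR"
  bmi <- cohort$participants$weight_baseline_kg /
    (cohort$participants$height_cm / 100)^2
  bmi_c <- bmi - mean(bmi, na.rm = TRUE)
  withr::with_seed(spec$seed + 1L, {
    for (field in names(probs)) {
      p0 <- probs[[field]]
      target <- if (field %in% names(cohort$participants)) "participants"
                else if (field %in% names(cohort$records)) "records"
                else NULL
      if (is.null(target)) {
        abort(sprintf("missingness field '%s' not found in cohort", field),
              class = "pnnsgs_error_spec")
      }
      tab <- cohort[[target]]
      if (mechanism == "bmi" && p0 > 0 && p0 < 1) {
        pr <- plogis(qlogis(p0) + (ms$bmi_coef %||% 0.4) * bmi_c)
        if (target == "records") {
          pr <- pr[match(tab$participant_id,
                         cohort$participants$participant_id)]
        }
      } else {
        pr <- rep(p0, nrow(tab))
      }
      hit <- runif(nrow(tab)) < pr
      tab[[field]][hit] <- NA
      cohort[[target]] <- tab
    }
  })
  cohort
}

#' Scale down reported energies for a fraction of subjects
#'
#' Marks a random fraction of subjects as energy under-reporters and
#' multiplies the reported energy of every one of their 24-h records by
#' `factor` (< 1).  True energy in the truth table is preserved, so
#' [flag_underreporters()] can be validated for sensitivity and specificity.
#'
#' @param cohort A `synthetic_cohort`.
#' @param spec Optional [cohort_spec()]; its `underreport` element supplies
#'   `fraction` and `factor`.
#' @return The cohort with scaled record energies and updated truth flags.
#' @export
apply_underreporting <- function(cohort, spec = cohort$spec) {
  ur <- spec$underreport
  if (ur$fraction == 0 || nrow(cohort$participants) == 0) return(cohort)
  withr::with_seed(spec$seed + 2L, {
    hit <- runif(nrow(cohort$participants)) < ur$fraction
  })
  ids <- cohort$participants$participant_id[hit]
  sel <- cohort$records$participant_id %in% ids
  cohort$records$energy_kcal[sel] <- cohort$records$energy_kcal[sel] *
    ur$factor
  cohort$truth$underreporter <- cohort$truth$participant_id %in% ids
  cohort$truth$underreport_factor <- ifelse(cohort$truth$underreporter,
                                            ur$factor, 1)
  cohort
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `participants.csv`, `records.csv` and `truth.csv` under `dir`.
#' The truth table is written for auditing only and is never read by the
#' pipeline.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$participants, file.path(dir, "participants.csv"),
            row.names = FALSE)
  write.csv(cohort$records, file.path(dir, "records.csv"), row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
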