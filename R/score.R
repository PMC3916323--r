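#' Names of the 13 score components
#' @return Character vector in score order; component 13 is physical activity.
#' @export
component_names <- function() {
  c("fruit_veg", "starch", "wholegrain", "dairy", "meat", "seafood",
    "added_fat", "veg_fat", "sugar", "beverages", "alcohol", "salt",
    "activity")
}

# columns each component reads from the intake/participant table
component_fields <- function() {
  list(fruit_veg = "fruit_veg_serv", starch = "starch_serv",
       wholegrain = "wholegrain_frac", dairy = "dairy_serv",
       meat = "meat_serv", seafood = "seafood_serv_week",
       added_fat = "addedfat_pct_ei", veg_fat = "vegfat_ratio",
       sugar = "sugar_pct_ei", beverages = c("water_ml", "soda_ml"),
       alcohol = c("alcohol_g_day", "alcohol_freq_week"), salt = "salt_g",
       activity = "pa_points")
}

interval_points <- function(x, breaks, points) {
  idx <- findInterval(x, breaks)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx) & idx >= 1
  out[ok] <- points[idx[ok]]
  out
}

#' Points for one PNNS-GS component
#'
#' Evaluates a single component of the guideline score for each row of an
#' intake table.  Interval components use half-open `[a, b)` bands (the band
#' starting at `a` wins at exactly `a`); the salt cutpoints are right-closed
#' as printed (`<= 6 g/d` earns the maximum); the dairy bands widen at the
#' configured age threshold (55 years); the alcohol component uses
#' sex-specific ethanol thresholds (20 g/d women, 30 g/d men) and awards the
#' full point to abstainers and irregular consumers (less than once a week).
#'
#' @param intake A data frame of habitual intake (one row per participant)
#'   carrying the fields the component needs; see [average_records()].
#' @param component Component id 1-13 or name (see [component_names()]).
#' @param age,sex Optional vectors overriding `age` / `sex` columns of
#'   `intake`; required by the dairy and alcohol components.
#' @param config A `pnns_config` list.
#' @return Numeric vector of points, `NA` where an input value is missing.
#' @examples
#' score_component(data.frame(fruit_veg_serv = 8), "fruit_veg")
#' @export
score_component <- function(intake, component, age = NULL, sex = NULL,
                            config = default_score_config()) {
  nms <- component_names()
  if (is.numeric(component)) component <- nms[component]
  if (is.na(component) || !component %in% nms) {
    abort("score_component: unknown component", class = "pnnsgs_error_input")
  }
  fields <- component_fields()[[component]]
  missing_cols <- setdiff(fields, names(intake))
  if (component == "activity" && "pa_class" %in% names(intake)) {
    missing_cols <- character(0)
  }
  if (length(missing_cols) > 0) {
    abort(sprintf("component '%s': missing field(s) %s", component,
                  paste(missing_cols, collapse = ", ")),
          class = "pnnsgs_error_missing_field")
  }
  cc <- config$components[[component]]
  switch(component,
    fruit_veg = interval_points(intake$fruit_veg_serv, cc$breaks, cc$points),
    starch = interval_points(intake$starch_serv, cc$breaks, cc$points),
    wholegrain = interval_points(intake$wholegrain_frac, cc$breaks, cc$points),
    dairy = {
      age <- age %||% (if ("age" %in% names(intake)) intake$age)
      if (is.null(age)) {
        abort("component 'dairy': missing field(s) age",
              class = "pnnsgs_error_missing_field")
      }
      x <- intake$dairy_serv
      upper <- ifelse(age >= cc$age_threshold, cc$upper[["over"]],
                      cc$upper[["under"]])
      pts <- interval_points(x, cc$breaks, cc$points)
      ifelse(!is.na(x) & x > upper, cc$over_points, pts)
    },
    meat = {
      x <- intake$meat_serv
      dplyr::case_when(
        is.na(x) ~ NA_real_,
        x == 0 ~ cc$zero_points,
        x > cc$band[2] ~ cc$over_points,
        x >= cc$band[1] ~ cc$band_points,
        TRUE ~ cc$low_points
      )
    },
    seafood = ifelse(intake$seafood_serv_week >= cc$threshold,
                     cc$at_or_above, cc$below),
    added_fat = ifelse(intake$addedfat_pct_ei <= cc$threshold,
                       cc$at_or_below, cc$above),
    veg_fat = {
      # NA / NaN ratio encodes "no use of added fats" (scores the point)
      r <- intake$vegfat_ratio
      ifelse(is.na(r) | is.nan(r), cc$favourable,
             ifelse(r > cc$ratio_threshold, cc$favourable, cc$unfavourable))
    },
    sugar = {
      x <- intake$sugar_pct_ei
      dplyr::case_when(
        is.na(x) ~ NA_real_,
        x >= cc$high ~ cc$points[["above_high"]],
        x >= cc$low ~ cc$points[["mid"]],
        TRUE ~ cc$points[["below_low"]]
      )
    },
    beverages = {
      w <- intake$water_ml >= cc$water_ml
      s <- intake$soda_ml <= cc$soda_ml
      dplyr::case_when(
        is.na(w) | is.na(s) ~ NA_real_,
        w & s ~ cc$points[["high_water_low_soda"]],
        !w & s ~ cc$points[["low_water_low_soda"]],
        w & !s ~ cc$points[["high_water_high_soda"]],
        TRUE ~ cc$points[["low_water_high_soda"]]
      )
    },
    alcohol = {
      sex <- sex %||% (if ("sex" %in% names(intake)) intake$sex)
      if (is.null(sex)) {
        abort("component 'alcohol': missing field(s) sex",
              class = "pnnsgs_error_missing_field")
      }
      g <- intake$alcohol_g_day
      freq <- intake$alcohol_freq_week
      thr <- unname(cc$threshold[as.character(sex)])
      irregular <- (!is.na(freq) & freq < cc$irregular_freq_per_week) |
        (is.na(freq) & !is.na(g) & g == 0)
      dplyr::case_when(
        irregular ~ cc$abstainer,
        is.na(g) | is.na(thr) ~ NA_real_,
        g <= thr ~ cc$compliant,
        TRUE ~ cc$over
      )
    },
    salt = {
      x <- intake$salt_g
      idx <- pmax(findInterval(x, cc$breaks, left.open = TRUE), 1)
      out <- rep(NA_real_, length(x))
      ok <- !is.na(x)
      out[ok] <- cc$points[idx[ok]]
      out
    },
    activity = {
      if ("pa_points" %in% names(intake)) {
        intake$pa_points
      } else {
        unname(config$pa_points[as.character(intake$pa_class)])
      }
    }
  )
}

#' Energy-overconsumption penalty
#'
#' When reported energy intake exceeds estimated energy needs by more than
#' the tolerance (5 %), the same fraction is deducted from the score: a raw
#' score of 7 with intake 10 % above needs becomes 7 x (1 - 0.10) = 6.3
#' points.  Overconsumption at or below the tolerance leaves the score
#' unchanged.  Non-positive raw totals are never penalized further.
#'
#' @param raw_total Numeric vector of raw (unpenalized) scores.
#' @param energy_intake Numeric vector, kcal/day.
#' @param energy_needs Numeric vector, kcal/day; must be positive.
#' @param tolerance Overconsumption fraction below which no penalty applies.
#' @return A tibble with columns `score` (penalized) and
#'   `overconsumption_fraction` (`max((EI - needs)/needs, 0)`).
#' @examples
#' apply_penalty(7, 2200, 2000)
#' @export
apply_penalty <- function(raw_total, energy_intake, energy_needs,
                          tolerance = 0.05) {
  n <- max(length(raw_total), length(energy_intake), length(energy_needs))
  raw_total <- rep_len(raw_total, n)
  energy_intake <- rep_len(energy_intake, n)
  energy_needs <- rep_len(energy_needs, n)
  if (any(!is.na(energy_needs) & energy_needs <= 0)) {
    abort("apply_penalty: energy_needs must be positive",
          class = "pnnsgs_error_input")
  }
  f <- (energy_intake - energy_needs) / energy_needs
  over <- pmax(f, 0)
  score <- ifelse(is.na(f), NA_real_,
                  ifelse(f > tolerance & raw_total > 0,
                         raw_total * (1 - f), raw_total))
  tibble(score = score, overconsumption_fraction = over)
}

#' Score category from breakpoints
#'
#' Half-open categorization: `score < low` is "low", `low <= score < high`
#' is "medium", `score >= high` is "high".
#'
#' @param score Numeric vector.
#' @param cutoffs Named vector with elements `low` and `high` (defaults 6, 9,
#'   the PNNS-GS breakpoints; the mPNNS-GS uses 5.5 and 8.5).
#' @return Factor with levels low/medium/high.
#' @examples
#' score_category(c(5.9, 6, 8.999, 9))
#' @export
score_category <- function(score, cutoffs = c(low = 6, high = 9)) {
  cut(score, breaks = c(-Inf, cutoffs[["low"]], cutoffs[["high"]], Inf),
      labels = c("low", "medium", "high"), right = FALSE)
}

#' Full PNNS-GS and mPNNS-GS score breakdown
#'
#' Evaluates all 13 components, sums them, applies the energy-overconsumption
#' penalty using Schofield BMR x PAL energy needs, and assigns the score
#' categories (PNNS-GS breakpoints 6/9; mPNNS-GS breakpoints 5.5/8.5).  The
#' mPNNS-GS is the penalized sum of the 12 dietary components (activity
#' excluded, maximum 13.5 points); the unpenalized totals are retained for
#' sensitivity analyses.
#'
#' @param intake Habitual-intake table from [average_records()] (one row per
#'   participant, including questionnaire alcohol and seafood fields).
#' @param participants Participant table with `participant_id`, `age`, `sex`,
#'   `weight_baseline_kg` and the physical-activity columns added by
#'   [pa_category()] (`pa_class`, `pa_points`).
#' @param config A `pnns_config` list.
#' @param penalize If `FALSE`, the penalty is skipped and the reported scores
#'   equal the raw totals (the unpenalized-score sensitivity mode).
#' @return A tibble (one row per participant): the 13 `points_*` columns,
#'   `raw_total`, `energy_intake`, `energy_needs`,
#'   `overconsumption_fraction`, `pnns_gs`, `pnns_gs_unpenalized`,
#'   `m_pnns_gs`, `m_pnns_gs_unpenalized`, `pnns_category`,
#'   `mpnns_category`.
#' @export
compute_scores <- function(intake, participants,
                           config = default_score_config(),
                           penalize = TRUE) {
  keep <- intersect(c("participant_id", "age", "sex", "weight_baseline_kg",
                      "pa_class", "pa_points"), names(participants))
  d <- as_tibble(intake) |>
    inner_join(as_tibble(participants)[keep], by = "participant_id")
  nms <- component_names()
  pts <- lapply(nms, function(nm) {
    score_component(d, nm, age = d$age, sex = d$sex, config = config)
  })
  names(pts) <- paste0("points_", nms)
  out <- bind_cols(tibble(participant_id = d$participant_id), as_tibble(pts))
  out$raw_total <- rowSums(as.matrix(as_tibble(pts)))
  dietary <- out$raw_total - out$points_activity
  bmr <- schofield_bmr(d$sex, d$age, d$weight_baseline_kg, config)
  needs <- estimate_energy_needs(bmr, d$pa_class, config)
  out$energy_intake <- d$energy_kcal
  out$energy_needs <- needs
  pen <- apply_penalty(out$raw_total, out$energy_intake, needs,
                       config$penalty_tolerance)
  pen_m <- apply_penalty(dietary, out$energy_intake, needs,
                         config$penalty_tolerance)
  out$overconsumption_fraction <- pen$overconsumption_fraction
  out$pnns_gs_unpenalized <- out$raw_total
  out$m_pnns_gs_unpenalized <- dietary
  out$pnns_gs <- if (penalize) pen$score else out$raw_total
  out$m_pnns_gs <- if (penalize) pen_m$score else dietary
  out$pnns_category <- score_category(out$pnns_gs, config$categories$pnns)
  out$mpnns_category <- score_category(out$m_pnns_gs, config$categories$mpnns)
  out
}
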