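#' Parameters of the Goldberg/Black under-reporting cutoff
#'
#' @param pal_by_activity Named PAL multipliers by activity class.
#' @param cv_ei Within-subject coefficient of variation of reported energy
#'   intake, percent (default 23).
#' @param cv_bmr Coefficient of variation of estimated BMR, percent
#'   (default 8.5).
#' @param cv_pal Coefficient of variation of the PAL, percent (default 15).
#' @param multiplier Confidence multiplier on the aggregated CV; the default
#'   -2 gives the one-sided lower cutoff.
#' @return List of class `goldberg_params`.
#' @export
goldberg_params <- function(pal_by_activity = c(low = 1.55, medium = 1.70,
                                                high = 1.85),
                            cv_ei = 23, cv_bmr = 8.5, cv_pal = 15,
                            multiplier = -2) {
  if (any(pal_by_activity <= 1)) {
    abort("goldberg_params: PAL factors must exceed 1",
          class = "pnnsgs_error_input")
  }
  if (any(c(cv_ei, cv_bmr, cv_pal) <= 0)) {
    abort("goldberg_params: coefficients of variation must be positive",
          class = "pnnsgs_error_input")
  }
  structure(list(pal_by_activity = pal_by_activity, cv_ei = cv_ei,
                 cv_bmr = cv_bmr, cv_pal = cv_pal, multiplier = multiplier),
            class = "goldberg_params")
}

#' Lower Goldberg/Black EI:BMR cutoff
#'
#' Computes the plausibility cutoff for the ratio of mean reported energy
#' intake to basal metabolic rate, given a PAL and the number of 24-h records
#' contributing to the mean:
#' `cutoff = PAL * exp(multiplier * S / 100)` with
#' `S = sqrt(cv_ei^2 / n_days + cv_bmr^2 + cv_pal^2)`.
#' The cutoff is increasing in `n_days` and approaches the PAL as all
#' variance components vanish.
#'
#' @param params A [goldberg_params()] list.
#' @param pal PAL value (scalar or vector).
#' @param n_days Number of dietary records per subject (>= 1).
#' @return Numeric vector of EI:BMR cutoffs.
#' @examples
#' goldberg_lower_cutoff(goldberg_params(), pal = 1.55, n_days = 10)
#' @export
goldberg_lower_cutoff <- function(params = goldberg_params(), pal,
                                  n_days) {
  if (any(n_days < 1)) {
    abort("goldberg_lower_cutoff: n_days must be >= 1",
          class = "pnnsgs_error_input")
  }
  if (any(pal <= 0)) {
    abort("goldberg_lower_cutoff: pal must be positive",
          class = "pnnsgs_error_input")
  }
  s <- sqrt(params$cv_ei^2 / n_days + params$cv_bmr^2 + params$cv_pal^2)
  pal * exp(params$multiplier * s / 100)
}

#' Flag energy under-reporters
#'
#' A participant is flagged when mean reported energy intake divided by
#' Schofield BMR falls strictly below the Goldberg/Black lower cutoff for
#' their activity-class PAL and their record count.  The sensitivity pipeline
#' reruns the analysis on the unflagged subset.
#'
#' @param intake Habitual-intake table with `participant_id`, `energy_kcal`
#'   and `n_valid_records`.
#' @param participants Participant table with `participant_id`, `sex`, `age`,
#'   `weight_baseline_kg` and `pa_class`.
#' @param params A [goldberg_params()] list.
#' @param config A `pnns_config` (for the Schofield table).
#' @return Tibble with `participant_id`, `ei_bmr_ratio`, `cutoff` and logical
#'   `underreporter`.
#' @export
flag_underreporters <- function(intake, participants,
                                params = goldberg_params(),
                                config = default_score_config()) {
  d <- as_tibble(intake) |>
    inner_join(as_tibble(participants)[
      c("participant_id", "sex", "age", "weight_baseline_kg", "pa_class")],
      by = "participant_id")
  bmr <- schofield_bmr(d$sex, d$age, d$weight_baseline_kg, config)
  pal <- unname(params$pal_by_activity[as.character(d$pa_class)])
  cutoff <- goldberg_lower_cutoff(params, pal, d$n_valid_records)
  tibble(participant_id = d$participant_id,
         ei_bmr_ratio = d$energy_kcal / bmr,
         cutoff = cutoff,
         underreporter = d$energy_kcal / bmr < cutoff)
}
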