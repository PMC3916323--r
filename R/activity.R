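#' Weekly MET-hours from leisure-activity records
#'
#' Sums metabolic-equivalent-task hours per week over a participant's
#' reported leisure activities.  Only activities practised at least 10 times
#' over the past year with sessions of at least 10 minutes contribute.
#' Intensities come from `config$met_table`; an activity type absent from the
#' table is an error (`UNKNOWN_ACTIVITY`).
#'
#' @param activities A data frame with columns `activity` (character),
#'   `duration_min` (minutes per session) and either `times_per_week` or
#'   `times_per_year`; an optional `participant_id` column groups the sum.
#' @param config A `pnns_config` list.
#' @return If `participant_id` is present, a tibble with `participant_id` and
#'   `met_hours_week`; otherwise a single number (0 for an empty input).
#' @examples
#' compute_met_hours(data.frame(activity = "walking_brisk",
#'                              times_per_week = 5, duration_min = 30))
#' @export
compute_met_hours <- function(activities, config = default_score_config()) {
  grouped <- "participant_id" %in% names(activities)
  if (nrow(activities) == 0) {
    if (grouped) {
      return(tibble(participant_id = activities$participant_id[0],
                    met_hours_week = numeric(0)))
    }
    return(0)
  }
  act <- as_tibble(activities)
  if (!"times_per_week" %in% names(act)) {
    if (!"times_per_year" %in% names(act)) {
      abort("compute_met_hours: need times_per_week or times_per_year",
            class = "pnnsgs_error_input")
    }
    act$times_per_week <- act$times_per_year / (365.25 / 7)
  }
  if (!"times_per_year" %in% names(act)) {
    act$times_per_year <- act$times_per_week * (365.25 / 7)
  }
  unmapped <- setdiff(unique(act$activity), names(config$met_table))
  if (length(unmapped) > 0) {
    abort(paste0("UNKNOWN_ACTIVITY: no MET intensity for '",
                 paste(unmapped, collapse = "', '"), "'"),
          class = "pnnsgs_error_unknown_activity")
  }
  act <- act |>
    mutate(met = unname(config$met_table[.data$activity]),
           eligible = .data$times_per_year >= 10 & .data$duration_min >= 10,
           met_h = ifelse(.data$eligible,
                          .data$times_per_week * .data$duration_min / 60 *
                            .data$met, 0))
  if (grouped) {
    act |>
      group_by(.data$participant_id) |>
      summarise(met_hours_week = sum(.data$met_h), .groups = "drop")
  } else {
    sum(act$met_h)
  }
}

#' Physical-activity category and component-13 points
#'
#' Maps weekly MET-hours to a minutes-of-brisk-walking equivalent via the
#' anchor 16.25 MET-h/week = 30 min/day, then to the low (< 30 min/d),
#' medium (30-60 min/d) and high (>= 60 min/d) classes scoring 0 / 1 / 1.5
#' points.  When MET-hours are missing, two fallback questionnaire items are
#' used: subjects reporting no regular physical activity are classed low;
#' subjects reporting regular activity equivalent to at least one hour of
#' walking per day are classed high; subjects reporting regular activity
#' below that equivalent cannot be classed from the items alone and are left
#' `NA` (flagged `pa_needs_imputation`) for [regression_impute()] to resolve
#' into low or medium.
#'
#' @param participants A data frame with columns `met_hours_week` and
#'   (optionally) the logical fallback items `pa_regular` and `pa_walk_1h`.
#' @param config A `pnns_config` list.
#' @return The input with columns `pa_minutes_equiv`, `pa_class` (factor
#'   low/medium/high), `pa_points` and `pa_needs_imputation` added.
#' @examples
#' pa_category(data.frame(met_hours_week = 16.25))$pa_class
#' @export
pa_category <- function(participants, config = default_score_config()) {
  p <- as_tibble(participants)
  if (!"met_hours_week" %in% names(p)) p$met_hours_week <- NA_real_
  if (!"pa_regular" %in% names(p)) p$pa_regular <- NA
  if (!"pa_walk_1h" %in% names(p)) p$pa_walk_1h <- NA
  no_source <- is.na(p$met_hours_week) & is.na(p$pa_regular)
  if (any(no_source)) {
    abort(sprintf(
      "pa_category: %d participant(s) have neither MET-hours nor fallback items",
      sum(no_source)), class = "pnnsgs_error_input")
  }
  anchor <- config$met_anchor
  minutes <- p$met_hours_week / anchor[["met_hours"]] *
    anchor[["minutes_per_day"]]
  act <- config$components$activity
  lev <- c("low", "medium", "high")
  cls <- lev[findInterval(minutes, act$breaks)]
  # fallback items where the questionnaire is missing
  fb <- is.na(p$met_hours_week)
  cls[fb & p$pa_regular %in% FALSE] <- "low"
  cls[fb & p$pa_regular %in% TRUE & p$pa_walk_1h %in% TRUE] <- "high"
  # regular activity below the 1 h walking equivalent: to be imputed
  needs_imp <- fb & p$pa_regular %in% TRUE & !(p$pa_walk_1h %in% TRUE)
  p$pa_minutes_equiv <- minutes
  p$pa_class <- factor(cls, levels = lev)
  p$pa_points <- unname(config$pa_points[as.character(p$pa_class)])
  p$pa_needs_imputation <- needs_imp
  p
}
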