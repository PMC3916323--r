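#' Flag implausible 24-h dietary records
#'
#' A record is invalid when its reported energy is below 100 kcal/day or
#' above 6000 kcal/day (strict inequalities: 100 and 6000 kcal are retained)
#' or when energy is missing.
#'
#' @param records Dietary-record table with an `energy_kcal` column.
#' @param energy_range Length-2 numeric, the plausible energy window.
#' @return `records` with logical `valid` and character `invalid_code`
#'   (`NA`, `"MISSING_ENERGY"` or `"ENERGY_IMPLAUSIBLE"`) columns added.
#' @examples
#' validate_records(data.frame(energy_kcal = c(99, 100, 6000, 6001, NA)))
#' @export
validate_records <- function(records, energy_range = c(100, 6000)) {
  r <- as_tibble(records)
  e <- r$energy_kcal
  r$invalid_code <- dplyr::case_when(
    is.na(e) ~ "MISSING_ENERGY",
    e < energy_range[1] | e > energy_range[2] ~ "ENERGY_IMPLAUSIBLE",
    TRUE ~ NA_character_
  )
  r$valid <- is.na(r$invalid_code)
  r
}

#' Flag habitual low-energy reporters
#'
#' A participant is flagged when the proportion of their dietary records
#' below the sex-specific threshold (800 kcal/day for men, 500 kcal/day for
#' women) strictly exceeds one third.  By default the proportion is computed
#' over records surviving the 100-6000 kcal validity filter
#' (`count_basis = "valid"`); `count_basis = "all"` counts every submitted
#' record instead.
#'
#' @param records Record table (validated with [validate_records()] first if
#'   `count_basis = "valid"`; the flag column is added here when absent).
#' @param participants Participant table with `participant_id` and `sex`
#'   (`"M"`/`"F"`).
#' @param thresholds Named numeric, kcal/day per sex.
#' @param max_fraction Flag when the low-energy fraction exceeds this value
#'   (strictly).
#' @param count_basis Denominator: `"valid"` records only, or `"all"`.
#' @return Tibble with `participant_id`, `n_records`, `n_low` and logical
#'   `low_energy_reporter`.
#' @export
flag_low_energy_reporters <- function(records, participants,
                                      thresholds = c(M = 800, F = 500),
                                      max_fraction = 1 / 3,
                                      count_basis = c("valid", "all")) {
  count_basis <- match.arg(count_basis)
  p <- as_tibble(participants)
  if (!"sex" %in% names(p) || anyNA(p$sex) ||
      !all(p$sex %in% names(thresholds))) {
    abort("flag_low_energy_reporters: every participant needs a known sex",
          class = "pnnsgs_error_input")
  }
  r <- as_tibble(records)
  if (count_basis == "valid") {
    if (!"valid" %in% names(r)) r <- validate_records(r)
    r <- filter(r, .data$valid)
  }
  r |>
    inner_join(p[c("participant_id", "sex")], by = "participant_id") |>
    mutate(low = .data$energy_kcal < unname(thresholds[.data$sex])) |>
    group_by(.data$participant_id) |>
    summarise(n_records = dplyr::n(), n_low = sum(.data$low, na.rm = TRUE),
              .groups = "drop") |>
    mutate(low_energy_reporter = .data$n_low / .data$n_records > max_fraction)
}

#' Select the analysis sample and log every exclusion
#'
#' Applies the participant-level eligibility filters in a fixed order, each
#' participant leaving at the first failing rule: baseline age inside the
#' window (45-60 years); measured baseline BMI present and at least 25 kg/m2;
#' at least three valid 24-h records; not a habitual low-energy reporter
#' (sex-specific rule, see [flag_low_energy_reporters()]); complete required
#' covariates; no incident disease during the record window.
#'
#' @param participants Participant table; needs `participant_id`, `sex`,
#'   `age`, `height_cm`, `weight_baseline_kg` plus the required covariates.
#' @param records Dietary-record table.
#' @param age_range Baseline-age window, years.
#' @param bmi_min Minimum measured baseline BMI, kg/m2.
#' @param min_records Minimum number of valid records.
#' @param required_covariates Columns that must be non-missing; for women,
#'   `menopause` is additionally required when the column exists.
#' @param count_basis Passed to [flag_low_energy_reporters()].
#' @return A list: `participants` (included rows), `exclusion_log` (tibble
#'   `participant_id`, `rule`, `detail`; one row per excluded participant)
#'   and `counts` (named integer vector of exclusions by rule).
#' @export
select_analysis_sample <- function(participants, records,
                                   age_range = c(45, 60), bmi_min = 25,
                                   min_records = 3,
                                   required_covariates = c(
                                     "weight_followup_kg", "height_cm",
                                     "education", "smoking",
                                     "supplementation", "alcohol_g_day",
                                     "seafood_serv_week"),
                                   count_basis = c("valid", "all")) {
  count_basis <- match.arg(count_basis)
  p <- as_tibble(participants)
  r <- validate_records(records)
  log <- tibble(participant_id = character(0), rule = character(0),
                detail = character(0))
  drop <- function(ids, rule, detail) {
    if (length(ids) == 0) return()
    log <<- bind_rows(log, tibble(participant_id = as.character(ids),
                                  rule = rule, detail = detail))
    p <<- filter(p, !.data$participant_id %in% ids)
  }

  bad_age <- p$participant_id[is.na(p$age) | p$age < age_range[1] |
                                p$age > age_range[2]]
  drop(bad_age, "AGE",
       sprintf("baseline age outside [%g, %g]", age_range[1], age_range[2]))

  bmi <- p$weight_baseline_kg / (p$height_cm / 100)^2
  drop(p$participant_id[is.na(bmi)], "BMI", "measured baseline BMI missing")
  bmi <- p$weight_baseline_kg / (p$height_cm / 100)^2
  drop(p$participant_id[bmi < bmi_min], "BMI",
       sprintf("measured baseline BMI below %g", bmi_min))

  nval <- r |>
    filter(.data$valid, .data$participant_id %in% p$participant_id) |>
    count(.data$participant_id, name = "n_valid")
  nval <- left_join(p["participant_id"], nval, by = "participant_id") |>
    mutate(n_valid = tidyr::replace_na(.data$n_valid, 0L))
  drop(nval$participant_id[nval$n_valid < min_records], "MIN_RECORDS",
       sprintf("fewer than %d valid 24-h records", min_records))

  ler <- flag_low_energy_reporters(r, p, count_basis = count_basis)
  drop(ler$participant_id[ler$low_energy_reporter], "LOW_ENERGY_REPORTER",
       "low-energy records in more than one third of records")

  req <- intersect(required_covariates, names(p))
  if ("menopause" %in% names(p)) {
    incomplete <- !complete.cases(p[req]) |
      (p$sex == "F" & is.na(p$menopause))
  } else {
    incomplete <- !complete.cases(p[req])
  }
  drop(p$participant_id[incomplete], "MISSING_COVARIATES",
       "missing anthropometric or covariate data")

  if ("incident_disease" %in% names(p)) {
    drop(p$participant_id[p$incident_disease %in% TRUE], "INCIDENT_DISEASE",
         "incident cancer or ischemic disease during the record window")
  }

  counts <- table(factor(log$rule, levels = c(
    "AGE", "BMI", "MIN_RECORDS", "LOW_ENERGY_REPORTER",
    "MISSING_COVARIATES", "INCIDENT_DISEASE")))
  list(participants = p, exclusion_log = log,
       counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Average valid records into habitual intake
#'
#' Arithmetic mean, per participant, of every dietary quantity over the valid
#' 24-h records; alcohol (g ethanol/day, with weekly drinking frequency) and
#' seafood (servings/week) come from the questionnaire fields of the
#' participant table, never from records.  The vegetable-oil ratio is
#' averaged over days with added fat; a participant who never uses added fat
#' keeps `NA` (which the vegetable-fat component scores as favourable).
#'
#' @param records Record table ([validate_records()] is applied when the
#'   `valid` column is absent).
#' @param participants Participant table supplying `alcohol_g_day`,
#'   `alcohol_freq_week` and `seafood_serv_week`.
#' @param on_empty What to do when a participant has no valid records:
#'   `"error"` (code `NO_VALID_RECORDS`) or `"drop"`.
#' @return Habitual-intake tibble: `participant_id`, `n_valid_records`,
#'   per-field means (same column names as the record table) and the
#'   questionnaire fields.
#' @export
average_records <- function(records, participants,
                            on_empty = c("error", "drop")) {
  on_empty <- match.arg(on_empty)
  r <- as_tibble(records)
  if (!"valid" %in% names(r)) r <- validate_records(r)
  ids <- unique(r$participant_id)
  rv <- filter(r, .data$valid)
  empty <- setdiff(ids, unique(rv$participant_id))
  if (length(empty) > 0 && on_empty == "error") {
    abort(sprintf("NO_VALID_RECORDS: participant(s) %s have no valid records",
                  paste(head(empty, 5), collapse = ", ")),
          class = "pnnsgs_error_no_valid_records")
  }
  meas <- setdiff(names(rv)[vapply(rv, is.numeric, logical(1))],
                  c("record_index"))
  out <- rv |>
    group_by(.data$participant_id) |>
    summarise(n_valid_records = dplyr::n(),
              across(dplyr::all_of(meas), ~ mean(.x, na.rm = TRUE)),
              .groups = "drop")
  quest <- intersect(c("alcohol_g_day", "alcohol_freq_week",
                       "seafood_serv_week"), names(participants))
  out |>
    left_join(as_tibble(participants)[c("participant_id", quest)],
              by = "participant_id")
}
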