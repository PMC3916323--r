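#' Basal metabolic rate from the Schofield equations
#'
#' Evaluates the sex- and age-band linear Schofield (1985) equations in body
#' weight.  The coefficient table ships with [default_score_config()] and is
#' fully replaceable; the default bands are 18-30, 30-60 and 60+ years.
#' Band membership is `age_min <= age < age_max`.
#'
#' @param sex Character vector, `"M"` or `"F"`.
#' @param age Numeric vector, years; must fall inside a configured band.
#' @param weight Numeric vector, kg; must be positive.
#' @param config A `pnns_config` list.
#' @return Numeric vector of BMR in kcal/day.
#' @examples
#' schofield_bmr("M", 52, 85)
#' @export
schofield_bmr <- function(sex, age, weight,
                          config = default_score_config()) {
  n <- max(length(sex), length(age), length(weight))
  sex <- rep_len(sex, n); age <- rep_len(age, n)
  weight <- rep_len(weight, n)
  if (any(!is.na(weight) & weight <= 0)) {
    abort("schofield_bmr: weight must be positive",
          class = "pnnsgs_error_input")
  }
  tab <- config$schofield
  out <- rep(NA_real_, n)
  for (i in seq_len(nrow(tab))) {
    hit <- !is.na(sex) & !is.na(age) & sex == tab$sex[i] &
      age >= tab$age_min[i] & age < tab$age_max[i]
    out[hit] <- tab$slope[i] * weight[hit] + tab$intercept[i]
  }
  bad <- !is.na(sex) & !is.na(age) & is.na(out)
  if (any(bad)) {
    abort(sprintf("schofield_bmr: age %s outside configured bands",
                  paste(unique(age[bad]), collapse = ", ")),
          class = "pnnsgs_error_input")
  }
  out
}

#' Total energy needs from BMR and physical activity level
#'
#' Needs are BMR multiplied by the PAL factor of the subject's physical
#' activity category.  Defaults are 1.55 / 1.70 / 1.85 for the low / medium /
#' high categories.
#'
#' @param bmr Numeric vector, kcal/day; must be positive.
#' @param pa_class Character or factor vector with levels among
#'   `names(config$pal)`.
#' @param config A `pnns_config` list.
#' @return Numeric vector of estimated energy needs, kcal/day.
#' @examples
#' estimate_energy_needs(1500, "low")
#' @export
estimate_energy_needs <- function(bmr, pa_class,
                                  config = default_score_config()) {
  n <- max(length(bmr), length(pa_class))
  bmr <- rep_len(bmr, n)
  pa_class <- rep_len(as.character(pa_class), n)
  if (any(!is.na(bmr) & bmr <= 0)) {
    abort("estimate_energy_needs: bmr must be positive",
          class = "pnnsgs_error_input")
  }
  unknown <- !is.na(pa_class) & !pa_class %in% names(config$pal)
  if (any(unknown)) {
    abort(sprintf("estimate_energy_needs: unknown activity category '%s'",
                  paste(unique(pa_class[unknown]), collapse = "', '")),
          class = "pnnsgs_error_input")
  }
  bmr * unname(config$pal[pa_class])
}
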