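#' Default PNNS-GS scoring configuration
#'
#' Builds the full scoring configuration for the 13-component PNNS Guideline
#' Score: per-component cutoff tables, the age-dependent dairy bands, the
#' sex-specific alcohol thresholds, the beverage grid, the salt cutpoints,
#' the physical-activity minute cutpoints, the energy-overconsumption penalty
#' tolerance, the category breakpoints for the PNNS-GS (6 and 9 points) and
#' the mPNNS-GS (5.5 and 8.5 points), the Schofield basal-metabolic-rate
#' coefficient table, the physical-activity-level (PAL) multipliers and a
#' small MET-intensity table for leisure activities.
#'
#' Interval components use half-open intervals `[a, b)`: the row whose range
#' starts at `a` wins at exactly `a`.  Bands printed with an explicit upper
#' closure (dairy and meat, whose next row reads "> x") are closed at the top.
#' Cells whose numerals are not legible in all printings of the score table
#' (intermediate starch, meat and salt bands) follow the original score
#' definition (Estaquio et al. 2009) and are flagged `source = "reference"`.
#'
#' @return A list of class `pnns_config`.
#' @examples
#' cfg <- default_score_config()
#' cfg$pal
#' @export
default_score_config <- function() {
  cfg <- list(
    version = "pnnsgs-config-1",
    # interval components: points for [breaks[i], breaks[i+1]) , last open-ended
    components = list(
      fruit_veg = list(breaks = c(0, 3.5, 5, 7.5),
                       points = c(0, 0.5, 1, 2), source = "paper"),
      starch = list(breaks = c(0, 1, 3, 6),
                    points = c(0, 0.5, 1, 0.5), source = "reference"),
      wholegrain = list(breaks = c(0, 1 / 3, 2 / 3),
                        points = c(0, 0.5, 1), source = "paper"),
      # dairy: [0,1) 0; [1,2.5) 0.5; [2.5, upper] 1; > upper 0
      dairy = list(breaks = c(0, 1, 2.5), points = c(0, 0.5, 1),
                   upper = c(under = 3.5, over = 4.5), over_points = 0,
                   age_threshold = 55, source = "paper"),
      # meat: 0 exact -> 0; (0,1) 0.5; [1,2] 1; >2 0.5
      meat = list(zero_points = 0, low_points = 0.5, band = c(1, 2),
                  band_points = 1, over_points = 0.5, source = "reference"),
      seafood = list(threshold = 2, below = 0, at_or_above = 1,
                     source = "paper"),
      added_fat = list(threshold = 16, at_or_below = 1, above = 0,
                       source = "paper"),
      veg_fat = list(ratio_threshold = 0.5, favourable = 1, unfavourable = 0,
                     source = "paper"),
      sugar = list(high = 17.5, low = 12.5,
                   points = c(above_high = -0.5, mid = 0, below_low = 1),
                   source = "paper"),
      beverages = list(water_ml = 1000, soda_ml = 250,
                       points = c(low_water_high_soda = 0,
                                  high_water_high_soda = 0.5,
                                  low_water_low_soda = 0.75,
                                  high_water_low_soda = 1), source = "paper"),
      alcohol = list(threshold = c(F = 20, M = 30), abstainer = 1,
                     compliant = 0.8, over = 0,
                     irregular_freq_per_week = 1, source = "paper"),
      salt = list(breaks = c(0, 6, 8, 10, 12),
                  points = c(1.5, 1, 0.5, 0, -0.5),
                  closure = "right", source = "reference"),
      activity = list(breaks = c(0, 30, 60), points = c(0, 1, 1.5),
                      source = "paper")
    ),
    penalty_tolerance = 0.05,
    categories = list(pnns = c(low = 6, high = 9),
                      mpnns = c(low = 5.5, high = 8.5)),
    # Schofield (1985) BMR equations, kcal/day, weight in kg
    schofield = data.frame(
      sex = c("M", "M", "M", "F", "F", "F"),
      age_min = c(18, 30, 60, 18, 30, 60),
      age_max = c(30, 60, Inf, 30, 60, Inf),
      slope = c(15.3, 11.6, 13.5, 14.7, 8.7, 10.5),
      intercept = c(679, 879, 487, 496, 829, 596),
      stringsAsFactors = FALSE
    ),
    pal = c(low = 1.55, medium = 1.70, high = 1.85),
    # MET-h/week equivalent to 30 min/day of brisk walking
    met_anchor = c(met_hours = 16.25, minutes_per_day = 30),
    pa_points = c(low = 0, medium = 1, high = 1.5),
    # MET intensities; brisk walking 6.5 keeps the 16.25 MET-h anchor exact,
    # the rest follow the Ainsworth compendium
    met_table = c(
      walking_brisk = 6.5, walking = 3.5, cycling = 6.0, swimming = 7.0,
      running = 8.0, gardening = 4.0, tennis = 7.0, gymnastics = 4.0,
      dancing = 4.5, hiking = 6.0
    )
  )
  class(cfg) <- "pnns_config"
  validate_score_config(cfg)
  cfg
}

#' Validate a scoring configuration
#'
#' Checks the structural invariants of a [default_score_config()]-shaped
#' configuration: interval tables are strictly increasing with one point per
#' band, the component maxima sum to 15 in total and to 13.5 over the twelve
#' dietary components, PAL multipliers exceed 1, and the category breakpoints
#' are increasing.
#'
#' @param config A `pnns_config` list.
#' @return `config`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_score_config <- function(config) {
  comp <- config$components
  needed <- c("fruit_veg", "starch", "wholegrain", "dairy", "meat", "seafood",
              "added_fat", "veg_fat", "sugar", "beverages", "alcohol", "salt",
              "activity")
  missing <- setdiff(needed, names(comp))
  if (length(missing) > 0) {
    abort(paste0("score config is missing component(s): ",
                 paste(missing, collapse = ", ")),
          class = "pnnsgs_error_config")
  }
  for (nm in intersect(names(comp), c("fruit_veg", "starch", "wholegrain",
                                      "salt", "activity", "dairy"))) {
    b <- comp[[nm]]$breaks
    p <- comp[[nm]]$points
    if (length(b) != length(p) || any(diff(b) <= 0)) {
      abort(paste0("component '", nm, "': breaks must be strictly increasing ",
                   "with one point value per band"),
            class = "pnnsgs_error_config")
    }
  }
  maxima <- component_maxima(config)
  if (abs(sum(maxima) - 15) > 1e-9) {
    abort(sprintf("component maxima sum to %.3f, expected 15", sum(maxima)),
          class = "pnnsgs_error_config")
  }
  if (abs(sum(maxima[setdiff(names(maxima), "activity")]) - 13.5) > 1e-9) {
    abort("dietary component maxima must sum to 13.5",
          class = "pnnsgs_error_config")
  }
  if (any(config$pal <= 1)) {
    abort("pal: all PAL multipliers must exceed 1",
          class = "pnnsgs_error_config")
  }
  for (nm in names(config$categories)) {
    ct <- config$categories[[nm]]
    if (ct["low"] >= ct["high"]) {
      abort(paste0("categories$", nm, ": low cutoff must be below high"),
            class = "pnnsgs_error_config")
    }
  }
  invisible(config)
}

#' Maximum attainable points per component
#' @param config A `pnns_config` list.
#' @return Named numeric vector of 13 component maxima.
#' @keywords internal
component_maxima <- function(config) {
  comp <- config$components
  c(fruit_veg = max(comp$fruit_veg$points),
    starch = max(comp$starch$points),
    wholegrain = max(comp$wholegrain$points),
    dairy = max(comp$dairy$points, comp$dairy$over_points),
    meat = max(comp$meat$zero_points, comp$meat$low_points,
               comp$meat$band_points, comp$meat$over_points),
    seafood = max(comp$seafood$below, comp$seafood$at_or_above),
    added_fat = max(comp$added_fat$at_or_below, comp$added_fat$above),
    veg_fat = max(comp$veg_fat$favourable, comp$veg_fat$unfavourable),
    sugar = max(comp$sugar$points),
    beverages = max(comp$beverages$points),
    alcohol = max(comp$alcohol$abstainer, comp$alcohol$compliant,
                  comp$alcohol$over),
    salt = max(comp$salt$points),
    activity = max(comp$activity$points))
}

#' Read / write a scoring configuration as YAML
#'
#' The configuration round-trips through YAML so that an alternate interval
#' convention or cutoff set is a one-file edit.  A content hash accompanies
#' the configuration for run manifests.
#'
#' @param path File path.
#' @param config A `pnns_config` list.
#' @return `read_score_config()` returns a validated `pnns_config`;
#'   `write_score_config()` returns `path` invisibly.
#' @export
read_score_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$schofield <- as.data.frame(raw$schofield, stringsAsFactors = FALSE)
  raw$schofield$age_max[is.na(raw$schofield$age_max)] <- Inf
  for (nm in c("pal", "met_anchor", "pa_points", "met_table")) {
    raw[[nm]] <- unlist(raw[[nm]])
  }
  raw$categories <- lapply(raw$categories, unlist)
  raw$components <- lapply(raw$components, function(x) {
    lapply(x, function(v) if (is.list(v)) unlist(v) else v)
  })
  class(raw) <- "pnns_config"
  validate_score_config(raw)
  raw
}

#' @rdname read_score_config
#' @export
write_score_config <- function(config, path) {
  # yaml drops names of atomic vectors; store them as maps
  named_to_list <- function(x) {
    if (is.list(x) && !is.data.frame(x)) {
      lapply(x, named_to_list)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)
    } else {
      x
    }
  }
  out <- unclass(config)
  sch <- lapply(as.list(out$schofield), function(v) {
    if (is.numeric(v)) ifelse(is.infinite(v), NA, v) else v
  })
  out$schofield <- NULL
  out <- named_to_list(out)
  out$schofield <- sch
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.pnns_config <- function(x, ...) {
  cat("<pnns_config>", x$version, "\n")
  cat("  13 components; penalty tolerance", x$penalty_tolerance, "\n")
  cat("  PNNS-GS cutoffs:", paste(x$categories$pnns, collapse = "/"),
      " mPNNS-GS cutoffs:", paste(x$categories$mpnns, collapse = "/"), "\n")
  cat("  hash:", config_hash(x), "\n")
  invisible(x)
}

#' Content hash of a configuration (or any R object)
#' @param x An R object.
#' @return A character scalar.
#' @export
config_hash <- function(x) rlang::hash(x)
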