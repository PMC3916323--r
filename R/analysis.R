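#' Six-year anthropometric-change outcomes
#'
#' Percent changes are `(follow-up - baseline) / baseline * 100`, computed
#' exactly; the absolute weight change in kg is retained for the
#' transformation-robustness check.  Waist-circumference change is `NA` (and
#' the subject kept for the weight models) when either WC measurement is
#' missing.
#'
#' @param participants Table with `weight_baseline_kg`, `weight_followup_kg`
#'   and optionally `wc_baseline_cm`, `wc_followup_cm`.
#' @return Tibble with `participant_id`, `weight_change_pct`,
#'   `weight_change_abs` and `wc_change_pct`.
#' @examples
#' compute_outcomes(data.frame(participant_id = "a",
#'   weight_baseline_kg = 80, weight_followup_kg = 82))
#' @export
compute_outcomes <- function(participants) {
  p <- as_tibble(participants)
  if (any(!is.na(p$weight_baseline_kg) & p$weight_baseline_kg <= 0)) {
    abort("compute_outcomes: baseline weight must be positive",
          class = "pnnsgs_error_input")
  }
  if (!"wc_baseline_cm" %in% names(p)) p$wc_baseline_cm <- NA_real_
  if (!"wc_followup_cm" %in% names(p)) p$wc_followup_cm <- NA_real_
  if (any(!is.na(p$wc_baseline_cm) & p$wc_baseline_cm <= 0)) {
    abort("compute_outcomes: baseline WC must be positive",
          class = "pnnsgs_error_input")
  }
  tibble(
    participant_id = p$participant_id,
    weight_change_pct = (p$weight_followup_kg - p$weight_baseline_kg) /
      p$weight_baseline_kg * 100,
    weight_change_abs = p$weight_followup_kg - p$weight_baseline_kg,
    wc_change_pct = (p$wc_followup_cm - p$wc_baseline_cm) /
      p$wc_baseline_cm * 100
  )
}

model_covariates <- function(model, score, data) {
  model <- match.arg(model, c("A", "B", "C"))
  covs <- character(0)
  if (model %in% c("B", "C")) {
    covs <- c("age", "energy_intake")
    if (score == "mpnns") covs <- c(covs, "pa_30min")
  }
  if (model == "C") {
    covs <- c(covs, "supplementation", "n_records", "height_cm",
              "education", "smoking")
    if ("menopause" %in% names(data) && !all(is.na(data$menopause)) &&
        all(data$sex == "F", na.rm = TRUE)) {
      covs <- c(covs, "menopause")
    }
  }
  covs
}

#' ANCOVA least-squares means by diet-score category
#'
#' Fits a linear model of an anthropometric-change outcome on the score
#' category plus the covariate set of the requested model: A is crude; B adds
#' baseline age and energy intake (and, for the mPNNS-GS, the binary
#' physical-activity indicator `pa_30min`, < 30 vs >= 30 min/day of walking
#' equivalent); C further adds supplementation arm, number of dietary
#' records, baseline height, education and smoking (and menopausal status in
#' all-female strata).  Least-squares means are evaluated at the covariate
#' means of the analysed stratum (factors averaged with observed
#' frequencies).  The low-vs-high and medium-vs-high contrasts use the
#' Dunnett many-to-one adjustment computed from the multivariate t
#' distribution with the estimated contrast correlation; confidence
#' intervals for the least-squares means use the same Dunnett critical
#' value.  The overall p-value is the F-test of the category factor.
#'
#' @param data One analysis stratum (e.g. one sex): a participant-level data
#'   frame with the outcome, the category factor and the covariates.
#' @param outcome Name of the outcome column.
#' @param category Name of the category factor column (levels low / medium /
#'   high).
#' @param model `"A"`, `"B"` or `"C"`.
#' @param score `"pnns"` or `"mpnns"` (controls the physical-activity
#'   covariate in models B/C).
#' @param ref Reference category for the many-to-one contrasts.
#' @param weights Optional numeric vector of case weights (e.g. inverse
#'   probability weights).
#' @param level Confidence level.
#' @return An object of class `pnns_ancova`; see [tidy.pnns_ancova()].
#' @export
fit_ancova <- function(data, outcome = "weight_change_pct",
                       category = "pnns_category", model = "A",
                       score = c("pnns", "mpnns"), ref = "high",
                       weights = NULL, level = 0.95) {
  score <- match.arg(score)
  d <- as_tibble(data)
  d$.cat <- droplevels(factor(d[[category]]))
  if (nlevels(d$.cat) < 2) {
    abort("fit_ancova: need at least two non-empty categories",
          class = "pnnsgs_error_input")
  }
  if (!ref %in% levels(d$.cat)) {
    abort(sprintf("fit_ancova: reference category '%s' absent", ref),
          class = "pnnsgs_error_input")
  }
  covs <- model_covariates(model, score, d)
  missing_covs <- setdiff(covs, names(d))
  if (length(missing_covs) > 0) {
    abort(sprintf("fit_ancova: model %s needs covariate(s) %s", model,
                  paste(missing_covs, collapse = ", ")),
          class = "pnnsgs_error_input")
  }
  rhs <- paste(c(".cat", covs), collapse = " + ")
  d$.w <- if (is.null(weights)) 1 else weights
  d <- d[stats::complete.cases(d[c(outcome, ".cat", covs)]), ]
  fit <- lm(as.formula(paste(outcome, "~", rhs)), data = d, weights = .w)
  # collinearity check
  if (any(is.na(coef(fit)))) {
    abort(paste0("fit_ancova: rank-deficient design; collinear column(s): ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
          class = "pnnsgs_error_rank")
  }
  emm <- emmeans::emmeans(fit, ".cat", weights = "proportional")
  cont <- emmeans::contrast(emm, "trt.vs.ctrl", ref = ref)
  # mvt machinery integrates a multivariate t; fix its RNG for repeatability
  cs <- withr::with_seed(20140206L,
    summary(cont, adjust = "mvt", infer = c(TRUE, TRUE), level = level))
  es <- summary(emm, infer = c(TRUE, FALSE), level = level)
  crit <- if (nrow(cs) > 0) (cs$upper.CL[1] - cs$estimate[1]) / cs$SE[1]
          else stats::qt(1 - (1 - level) / 2, stats::df.residual(fit))
  # overall F-test for the category factor
  fit0 <- stats::update(fit, . ~ . - .cat, data = d)
  atab <- anova(fit0, fit)
  overall_p <- atab[["Pr(>F)"]][2]
  ns <- table(d$.cat)
  out <- tibble(
    category = factor(es$.cat, levels = levels(d$.cat)),
    n = as.integer(ns[as.character(es$.cat)]),
    ls_mean = es$emmean,
    se = es$SE,
    ci_low = es$emmean - crit * es$SE,
    ci_high = es$emmean + crit * es$SE,
    p_vs_ref = NA_real_,
    is_ref = as.character(es$.cat) == ref
  )
  lhs <- sub(" - .*$", "", as.character(cs$contrast))
  out$p_vs_ref[match(lhs, as.character(out$category))] <- cs$p.value
  structure(list(
    contrasts = out,
    contrast_detail = as_tibble(cs),
    overall_p = overall_p,
    fit = fit,
    outcome = outcome, model = model, score = score, ref = ref,
    level = level, crit = crit, weighted = !is.null(weights)
  ), class = "pnns_ancova")
}

#' @export
print.pnns_ancova <- function(x, ...) {
  cat(sprintf("<pnns_ancova> %s ~ category (model %s%s), ref = %s\n",
              x$outcome, x$model, if (x$weighted) ", weighted" else "",
              x$ref))
  print(as.data.frame(x$contrasts), digits = 3)
  cat(sprintf("overall F-test p = %.4g\n", x$overall_p))
  invisible(x)
}

#' Tidy an ANCOVA fit into the adjusted-contrast table
#'
#' One row per score category: least-squares mean, Dunnett-corrected
#' confidence interval, Dunnett-adjusted p-value versus the reference
#' category (`NA` for the reference itself) and the per-category n.
#'
#' @param x A `pnns_ancova` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pnns_ancova <- function(x, ...) x$contrasts

#' One-row model summary of an ANCOVA fit
#' @param x A `pnns_ancova` object.
#' @param ... Unused.
#' @return A tibble with the overall F-test p-value, n, sigma and R2.
#' @export
glance.pnns_ancova <- function(x, ...) {
  s <- summary(x$fit)
  tibble(overall_p = x$overall_p, n = sum(x$contrasts$n),
         r.squared = s$r.squared, sigma = s$sigma,
         model = x$model, outcome = x$outcome)
}

#' Test the score-category by sex interaction
#'
#' F-test of the category x sex product terms in the pooled (both-sex) model,
#' optionally including covariates.
#'
#' @param data Pooled data frame with the outcome, category and sex columns.
#' @param outcome,category As in [fit_ancova()].
#' @param sex Name of the sex column.
#' @param covariates Optional character vector of additional covariates.
#' @return A tibble with `statistic`, `df`, `df_residual` and `p_value`.
#' @export
test_interaction <- function(data, outcome = "weight_change_pct",
                             category = "pnns_category", sex = "sex",
                             covariates = character(0)) {
  d <- as_tibble(data)
  d$.cat <- droplevels(factor(d[[category]]))
  d$.sex <- droplevels(factor(d[[sex]]))
  if (nlevels(d$.sex) < 2) {
    abort("test_interaction: both sexes must be present",
          class = "pnnsgs_error_input")
  }
  if (nlevels(d$.cat) < 2) {
    abort("test_interaction: need at least two score categories",
          class = "pnnsgs_error_input")
  }
  d <- d[stats::complete.cases(d[c(outcome, ".cat", ".sex", covariates)]), ]
  rhs0 <- paste(c(".cat", ".sex", covariates), collapse = " + ")
  f0 <- lm(as.formula(paste(outcome, "~", rhs0)), data = d)
  f1 <- stats::update(f0, . ~ . + .cat:.sex, data = d)
  a <- anova(f0, f1)
  tibble(statistic = a$F[2], df = a$Df[2], df_residual = a$Res.Df[2],
         p_value = a[["Pr(>F)"]][2])
}

#' Descriptive comparison across score categories
#'
#' Medians (Q1, Q3) with Kruskal-Wallis tests for continuous variables;
#' counts (%) with chi-squared tests for categorical variables.  A variable
#' constant across the sample is skipped with a warning.
#'
#' @param data Data frame.
#' @param by Name of the grouping column (e.g. the score category).
#' @param vars Character vector of variable names to compare.
#' @return A tibble: `variable`, `group`, `level` (categorical only), `n`,
#'   `pct`, `median`, `q1`, `q3`, `p_value`, `test`.
#' @export
descriptive_table <- function(data, by, vars) {
  d <- as_tibble(data)
  g <- droplevels(factor(d[[by]]))
  rows <- list()
  for (v in vars) {
    x <- d[[v]]
    ok <- !is.na(x) & !is.na(g)
    if (length(unique(x[ok])) < 2) {
      warn(sprintf("descriptive_table: '%s' is constant; test skipped", v))
      rows[[v]] <- tibble(variable = v, group = NA_character_,
                          level = NA_character_, n = sum(ok),
                          pct = NA_real_, median = NA_real_, q1 = NA_real_,
                          q3 = NA_real_, p_value = NA_real_,
                          test = "skipped")
      next
    }
    if (is.numeric(x)) {
      p <- kruskal.test(x[ok], g[ok])$p.value
      rows[[v]] <- d[ok, ] |>
        mutate(.g = g[ok]) |>
        group_by(group = as.character(.data$.g)) |>
        summarise(n = dplyr::n(), median = median(.data[[v]]),
                  q1 = quantile(.data[[v]], 0.25),
                  q3 = quantile(.data[[v]], 0.75), .groups = "drop") |>
        mutate(variable = v, level = NA_character_, pct = NA_real_,
               p_value = p, test = "kruskal-wallis")
    } else {
      tab <- table(x[ok], g[ok])
      p <- suppressWarnings(chisq.test(tab)$p.value)
      rows[[v]] <- as_tibble(as.data.frame(tab, stringsAsFactors = FALSE)) |>
        rlang::set_names(c("level", "group", "n")) |>
        group_by(.data$group) |>
        mutate(pct = .data$n / sum(.data$n) * 100) |>
        ungroup() |>
        mutate(variable = v, median = NA_real_, q1 = NA_real_,
               q3 = NA_real_, p_value = p, test = "chi-squared")
    }
  }
  bind_rows(rows) |>
    select("variable", "group", "level", "n", "pct", "median", "q1", "q3",
           "p_value", "test")
}

#' Deterministic regression imputation
#'
#' Fits a model of the target on the predictors over complete cases and
#' replaces missing targets by the deterministic prediction (fitted value for
#' a numeric target; highest-probability class for a categorical one, via
#' logistic or multinomial regression).  No stochastic draw is added.
#' Imputed rows are flagged in a new `<target>_imputed` column.
#'
#' @param data Data frame.
#' @param target Name of the column to impute.
#' @param predictors Character vector of predictor columns (must be complete
#'   on the rows being imputed).
#' @param levels_allowed Optional subset of levels a categorical imputation
#'   may assign (e.g. low/medium only, when the questionnaire already ruled
#'   out the high class).
#' @return `data` with the target filled in and the flag column added.
#' @export
regression_impute <- function(data, target, predictors,
                              levels_allowed = NULL) {
  d <- as_tibble(data)
  for (p in predictors) {
    if (all(is.na(d[[p]]))) {
      abort(sprintf("regression_impute: predictor '%s' is entirely missing",
                    p), class = "pnnsgs_error_input")
    }
  }
  miss <- is.na(d[[target]])
  flag_col <- paste0(target, "_imputed")
  d[[flag_col]] <- miss
  if (!any(miss)) return(d)
  cc <- !miss & complete.cases(d[predictors])
  if (sum(cc) < length(predictors) + 2) {
    abort("regression_impute: too few complete cases to fit",
          class = "pnnsgs_error_input")
  }
  f <- as.formula(paste(target, "~", paste(predictors, collapse = " + ")))
  pred_rows <- miss & complete.cases(d[predictors])
  x <- d[[target]]
  if (is.numeric(x)) {
    fit <- lm(f, data = d[cc, ])
    d[[target]][pred_rows] <- predict(fit, newdata = d[pred_rows, ])
  } else {
    was_factor <- is.factor(x)
    train <- d[cc, ]
    train[[target]] <- droplevels(factor(train[[target]]))
    if (!is.null(levels_allowed)) {
      train <- train[train[[target]] %in% levels_allowed, ]
      train[[target]] <- droplevels(train[[target]])
    }
    lv <- levels(train[[target]])
    if (length(lv) == 1) {
      imputed <- rep(lv, sum(pred_rows))
    } else if (length(lv) == 2) {
      fit <- glm(f, data = train, family = binomial())
      pr <- predict(fit, newdata = d[pred_rows, ], type = "response")
      imputed <- lv[1 + (pr > 0.5)]
    } else {
      fit <- nnet::multinom(f, data = train, trace = FALSE)
      imputed <- as.character(predict(fit, newdata = d[pred_rows, ]))
    }
    if (was_factor) {
      d[[target]][pred_rows] <- factor(imputed, levels = levels(x))
    } else {
      d[[target]][pred_rows] <- imputed
    }
  }
  d
}

#' Inverse-probability-weighted reanalysis
#'
#' Estimates each parent-cohort subject's probability of inclusion in the
#' analysis sample with a logistic model on baseline characteristics (after
#' deterministic regression imputation of any missing predictor), then refits
#' the ANCOVA on the included subjects weighted by the inverse of the fitted
#' probabilities.
#'
#' @param parent Parent-cohort data frame (included and excluded subjects),
#'   carrying the outcome and category columns for the included rows.
#' @param included Logical vector (or name of a logical column of `parent`)
#'   flagging inclusion.
#' @param predictors Baseline characteristics for the inclusion model.
#' @param outcome,category,model,score,ref Passed to [fit_ancova()].
#' @param impute_with Predictors used to impute missing inclusion-model
#'   predictors (default: the complete ones among `predictors`).
#' @return A list of class `pnns_ipw`: `ancova` (the weighted `pnns_ancova`),
#'   `weights` (per included subject), `weight_range`, `inclusion_fit`.
#' @export
ipw_reanalysis <- function(parent, included, predictors,
                           outcome = "weight_change_pct",
                           category = "pnns_category", model = "A",
                           score = "pnns", ref = "high",
                           impute_with = NULL) {
  d <- as_tibble(parent)
  if (is.character(included) && length(included) == 1) {
    included <- d[[included]]
  }
  if (!is.logical(included) || length(included) != nrow(d)) {
    abort("ipw_reanalysis: 'included' must be a logical vector over parent",
          class = "pnnsgs_error_input")
  }
  d$.incl <- included
  # impute missing inclusion-model predictors on the parent cohort
  for (p in predictors) {
    if (anyNA(d[[p]])) {
      iw <- impute_with %||%
        predictors[vapply(d[predictors], function(z) !anyNA(z), logical(1))]
      iw <- setdiff(iw, p)
      if (length(iw) == 0) {
        abort(sprintf(
          "ipw_reanalysis: cannot impute '%s' (no complete predictors)", p),
          class = "pnnsgs_error_input")
      }
      d <- regression_impute(d, p, iw)
    }
  }
  if (all(d$.incl)) {
    incl_fit <- NULL
    p_hat <- rep(1, nrow(d))
  } else {
    f <- as.formula(paste(".incl ~", paste(predictors, collapse = " + ")))
    incl_fit <- glm(f, data = d, family = binomial())
    p_hat <- predict(incl_fit, newdata = d, type = "response")
  }
  if (any(d$.incl & p_hat < 1e-10)) {
    abort("ipw_reanalysis: fitted inclusion probability of 0 for an included subject",
          class = "pnnsgs_error_input")
  }
  w <- 1 / p_hat[d$.incl]
  if (max(w) / min(w) > 100) {
    warn(sprintf("ipw_reanalysis: extreme weights (min %.3g, max %.3g)",
                 min(w), max(w)))
  }
  sub <- d[d$.incl, ]
  anc <- fit_ancova(sub, outcome = outcome, category = category,
                    model = model, score = score, ref = ref, weights = w)
  structure(list(ancova = anc, weights = w,
                 weight_range = c(min = min(w), max = max(w)),
                 inclusion_fit = incl_fit),
            class = "pnns_ipw")
}

#' @export
print.pnns_ipw <- function(x, ...) {
  cat(sprintf("<pnns_ipw> weights in [%.3g, %.3g]\n",
              x$weight_range["min"], x$weight_range["max"]))
  print(x$ancova)
  invisible(x)
}

#' @rdname tidy.pnns_ancova
#' @export
tidy.pnns_ipw <- function(x, ...) tidy(x$ancova)
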