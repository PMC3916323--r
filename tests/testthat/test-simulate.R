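test_that("an empty cohort is valid and has the full schema", {
  co <- generate_cohort(cohort_spec(n_participants = 0))
  expect_equal(nrow(co$participants), 0)
  expect_equal(nrow(co$records), 0)
  expect_equal(nrow(co$truth), 0)
  expect_true(all(c("participant_id", "sex", "weight_followup_kg") %in%
                    names(co$participants)))
})

test_that("generation is deterministic given the seed", {
  s <- cohort_spec(n_participants = 200, seed = 7)
  a <- generate_cohort(s)
  b <- generate_cohort(s)
  expect_identical(a$participants, b$participants)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(cohort_spec(n_participants = 200, seed = 8))
  expect_false(identical(a$participants, c2$participants))
})

test_that("invalid spec fields are rejected by name", {
  expect_error(cohort_spec(sex_ratio = 1.5), "sex_ratio",
               class = "pnnsgs_error_spec")
  expect_error(cohort_spec(n_participants = -1), "n_participants",
               class = "pnnsgs_error_spec")
  expect_error(cohort_spec(effect_model = list(
    M = c(low = 1, medium = 1, high = 1),
    F = c(low = 1, medium = 1, high = 1), sd = -2)),
    "sd", class = "pnnsgs_error_spec")
  expect_error(cohort_spec(records_dist = c(`0` = 0.5, `10` = 0.5)),
               "records_dist", class = "pnnsgs_error_spec")
  expect_error(cohort_spec(underreport = list(fraction = 2, factor = 0.7)),
               "fraction", class = "pnnsgs_error_spec")
})

test_that("structural invariants hold: ids covered, BMI floor, record range", {
  co <- generate_cohort(cohort_spec(n_participants = 400, seed = 1))
  expect_true(all(co$records$participant_id %in%
                    co$participants$participant_id))
  expect_setequal(co$truth$participant_id, co$participants$participant_id)
  bmi <- co$participants$weight_baseline_kg /
    (co$participants$height_cm / 100)^2
  expect_true(all(bmi >= 25))
  expect_true(all(co$participants$n_records >= 3 &
                    co$participants$n_records <= 20))
  expect_true(all(co$participants$age >= 45 & co$participants$age <= 60))
  # records-per-subject distribution centres near 10
  expect_gt(mean(co$participants$n_records), 9)
  expect_lt(mean(co$participants$n_records), 11.5)
  # latent quality drives the realized score across all three categories
  expect_true(all(c("low", "medium", "high") %in%
                    as.character(co$truth$pnns_category)))
})

test_that("injected category means are recovered by direct averaging", {
  em <- list(M = c(low = 3.6, medium = 2.5, high = 2.1),
             F = c(low = 3.6, medium = 2.5, high = 2.1), sd = 4,
             bmi_slope = 0)
  co <- generate_cohort(cohort_spec(n_participants = 5000, seed = 17,
                                    effect_model = em))
  pct <- (co$participants$weight_followup_kg -
            co$participants$weight_baseline_kg) /
    co$participants$weight_baseline_kg * 100
  for (cat in c("low", "medium", "high")) {
    idx <- co$truth$pnns_category == cat
    se <- 4 / sqrt(sum(idx))
    expect_lt(abs(mean(pct[idx]) - em$M[[cat]]), 3 * se)
  }
})

test_that("missingness injection honours probabilities and keeps the truth", {
  spec <- cohort_spec(n_participants = 2000, seed = 5,
                      missingness = list(probs = NULL, mechanism = "MCAR"))
  co <- generate_cohort(spec)
  # all probabilities zero (empty): unchanged
  expect_identical(inject_missingness(co)$participants, co$participants)
  # probability one: the field is missing everywhere
  spec1 <- cohort_spec(n_participants = 100, seed = 5,
                       missingness = list(probs = c(education = 1),
                                          mechanism = "MCAR"))
  co1 <- inject_missingness(generate_cohort(spec1), spec1)
  expect_true(all(is.na(co1$participants$education)))
  expect_false(anyNA(co1$participants_complete$education))
  # MCAR 0.3: observed fraction within 3 binomial SE
  spec2 <- cohort_spec(n_participants = 2000, seed = 5,
                       missingness = list(probs = c(education = 0.3),
                                          mechanism = "MCAR"))
  co2 <- inject_missingness(generate_cohort(spec2), spec2)
  frac <- mean(is.na(co2$participants$education))
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
})

test_that("BMI-dependent missingness increases with BMI", {
  spec <- cohort_spec(n_participants = 4000, seed = 13,
                      missingness = list(probs = c(weight_followup_kg = 0.3),
                                         mechanism = "bmi", bmi_coef = 0.6))
  co <- inject_missingness(generate_cohort(spec), spec)
  bmi <- co$participants_complete$weight_baseline_kg /
    (co$participants_complete$height_cm / 100)^2
  miss <- is.na(co$participants$weight_followup_kg)
  expect_gt(mean(bmi[miss]), mean(bmi[!miss]))
})

test_that("under-reporting scales reported energy but not the truth", {
  spec0 <- cohort_spec(n_participants = 200, seed = 3)
  co0 <- apply_underreporting(generate_cohort(spec0), spec0)
  expect_false(any(co0$truth$underreporter))

  spec1 <- cohort_spec(n_participants = 100, seed = 3,
                       underreport = list(fraction = 1, factor = 0.7))
  base <- generate_cohort(cohort_spec(n_participants = 100, seed = 3))
  co1 <- apply_underreporting(generate_cohort(spec1), spec1)
  expect_equal(co1$records$energy_kcal, base$records$energy_kcal * 0.7)
  expect_equal(co1$truth$true_energy, base$truth$true_energy)

  spec2 <- cohort_spec(n_participants = 1000, seed = 3,
                       underreport = list(fraction = 0.2, factor = 0.7))
  co2 <- apply_underreporting(generate_cohort(spec2), spec2)
  n_flagged <- sum(co2$truth$underreporter)
  expect_lt(abs(n_flagged - 200), 3 * sqrt(1000 * 0.2 * 0.8))
})
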