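test_that("record validity thresholds are strict at 100 and 6000 kcal", {
  r <- validate_records(data.frame(energy_kcal = c(99, 100, 2000, 6000,
                                                   6001, NA)))
  expect_equal(r$valid, c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$invalid_code[6], "MISSING_ENERGY")
  expect_equal(r$invalid_code[1], "ENERGY_IMPLAUSIBLE")
})

test_that("low-energy-reporter rule uses sex thresholds and strict one third", {
  p <- tibble::tibble(participant_id = c("m1", "m2", "w1", "w2"),
                      sex = c("M", "M", "F", "F"))
  r <- tibble::tibble(
    participant_id = rep(c("m1", "m2", "w1", "w2"), each = 3),
    energy_kcal = c(700, 900, 900,   # man, exactly 1/3 low: kept
                    700, 700, 900,   # man, 2/3 low: excluded
                    600, 600, 600,   # woman, threshold is 500: kept
                    400, 400, 900))  # woman, 2/3 low: excluded
  fl <- flag_low_energy_reporters(r, p)
  expect_equal(fl$low_energy_reporter[match(c("m1", "m2", "w1", "w2"),
                                            fl$participant_id)],
               c(FALSE, TRUE, FALSE, TRUE))
  expect_error(flag_low_energy_reporters(
    r, tibble::tibble(participant_id = "m1", sex = NA)),
    class = "pnnsgs_error_input")
})

test_that("the denominator basis for the low-energy rule is switchable", {
  p <- tibble::tibble(participant_id = "m1", sex = "M")
  # two low valid records, one implausible (excluded under "valid" basis)
  r <- tibble::tibble(participant_id = "m1",
                      energy_kcal = c(700, 700, 7000, 900, 900, 900))
  valid_based <- flag_low_energy_reporters(r, p, count_basis = "valid")
  all_based <- flag_low_energy_reporters(r, p, count_basis = "all")
  expect_true(valid_based$low_energy_reporter)  # 2/5 > 1/3
  expect_false(all_based$low_energy_reporter)   # 2/6 <= 1/3
})

make_selection_fixture <- function() {
  p <- tibble::tibble(
    participant_id = sprintf("s%d", 1:7),
    sex = c("M", "M", "F", "M", "F", "M", "F"),
    age = c(44, 50, 50, 50, 50, 50, 50),       # s1 under-age
    height_cm = 170,
    weight_baseline_kg = c(80, 71.8, 80, 80, 80, 80, 80), # s2 BMI 24.84
    weight_followup_kg = c(82, 82, 82, 82, NA, 82, 82),   # s5 missing
    education = "primary", smoking = "never",
    supplementation = "placebo",
    alcohol_g_day = 5, alcohol_freq_week = 2, seafood_serv_week = 2,
    menopause = c(NA, NA, FALSE, NA, FALSE, NA, FALSE),
    incident_disease = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  rec <- tidyr::crossing(participant_id = p$participant_id,
                         record_index = 1:4) |>
    dplyr::mutate(energy_kcal = 2000)
  # s3: only two valid records; s4: low-energy reporter (3/4 low)
  rec$energy_kcal[rec$participant_id == "s3" & rec$record_index > 2] <- 50
  rec$energy_kcal[rec$participant_id == "s4" & rec$record_index > 1] <- 700
  list(participants = p, records = rec)
}

test_that("analysis-sample selection logs every exclusion once, in rule order", {
  fx <- make_selection_fixture()
  sel <- select_analysis_sample(fx$participants, fx$records)
  log <- sel$exclusion_log
  expect_equal(log$rule[match(paste0("s", 1:6), log$participant_id)][c(1, 2)],
               c("AGE", "BMI"))
  expect_equal(log$rule[log$participant_id == "s3"], "MIN_RECORDS")
  expect_equal(log$rule[log$participant_id == "s4"], "LOW_ENERGY_REPORTER")
  expect_equal(log$rule[log$participant_id == "s5"], "MISSING_COVARIATES")
  expect_equal(log$rule[log$participant_id == "s6"], "INCIDENT_DISEASE")
  expect_equal(sel$participants$participant_id, "s7")
  # count conservation, no double-counting
  expect_equal(nrow(sel$participants) + nrow(log), nrow(fx$participants))
  expect_equal(anyDuplicated(log$participant_id), 0L)
  expect_equal(sum(sel$counts), nrow(log))
})

test_that("BMI exactly at the threshold is retained; 24.9 is not", {
  p <- tibble::tibble(
    participant_id = c("a", "b"), sex = "M", age = 50, height_cm = 200,
    weight_baseline_kg = c(100, 99.6), # BMI 25.0 and 24.9
    weight_followup_kg = 100, education = "x", smoking = "x",
    supplementation = "x", alcohol_g_day = 0, alcohol_freq_week = 0,
    seafood_serv_week = 0, incident_disease = FALSE)
  rec <- tidyr::crossing(participant_id = p$participant_id,
                         record_index = 1:3) |>
    dplyr::mutate(energy_kcal = 2000)
  sel <- select_analysis_sample(p, rec)
  expect_equal(sel$participants$participant_id, "a")
  expect_equal(sel$exclusion_log$rule, "BMI")
})

test_that("averaging is the arithmetic mean of valid records only", {
  p <- tibble::tibble(participant_id = "a", alcohol_g_day = 12,
                      alcohol_freq_week = 3, seafood_serv_week = 1.5)
  one <- tibble::tibble(participant_id = "a", record_index = 1,
                        energy_kcal = 2000, fruit_veg_serv = 4, salt_g = 7)
  hi <- average_records(one, p)
  expect_equal(hi$energy_kcal, 2000)
  expect_equal(hi$fruit_veg_serv, 4)
  expect_equal(hi$n_valid_records, 1)
  # questionnaire fields come from the participant table, never records
  expect_equal(hi$alcohol_g_day, 12)
  expect_equal(hi$seafood_serv_week, 1.5)

  two <- tibble::tibble(participant_id = "a", record_index = 1:2,
                        energy_kcal = c(2000, 2400))
  expect_equal(average_records(two, p)$energy_kcal, 2200)
})

test_that("averaging matches a brute-force oracle and ignores record order", {
  withr::with_seed(9, {
    r <- tibble::tibble(
      participant_id = "a", record_index = 1:10,
      energy_kcal = runif(10, 1500, 3000),
      fruit_veg_serv = runif(10, 0, 8), salt_g = runif(10, 3, 12))
  })
  p <- tibble::tibble(participant_id = "a", alcohol_g_day = 0,
                      alcohol_freq_week = 0, seafood_serv_week = 0)
  hi <- average_records(r, p)
  expect_equal(hi$energy_kcal, sum(r$energy_kcal) / 10)
  expect_equal(hi$fruit_veg_serv, sum(r$fruit_veg_serv) / 10)
  shuffled <- r[sample(10), ]
  expect_equal(average_records(shuffled, p)$salt_g, hi$salt_g)
})

test_that("a participant with no valid records raises NO_VALID_RECORDS", {
  p <- tibble::tibble(participant_id = "a", alcohol_g_day = 0,
                      alcohol_freq_week = 0, seafood_serv_week = 0)
  r <- tibble::tibble(participant_id = "a", record_index = 1:2,
                      energy_kcal = c(50, 7000))
  expect_error(average_records(r, p), "NO_VALID_RECORDS",
               class = "pnnsgs_error_no_valid_records")
  expect_equal(nrow(average_records(r, p, on_empty = "drop")), 0)
})
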