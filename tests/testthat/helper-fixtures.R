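# fixture builders shared across test files

# habitual-intake row hitting the best-scoring cell of every dietary
# component; energy equal to needs is set by the caller
optimal_intake <- function(id = "opt", energy = 2000) {
  tibble::tibble(
    participant_id = id, n_valid_records = 10, energy_kcal = energy,
    fruit_veg_serv = 8, starch_serv = 4, wholegrain_frac = 0.8,
    dairy_serv = 3, meat_serv = 1.5, seafood_serv_week = 3,
    addedfat_pct_ei = 10, vegfat_ratio = 0.8, sugar_pct_ei = 5,
    water_ml = 1200, soda_ml = 0, salt_g = 5,
    alcohol_g_day = 0, alcohol_freq_week = 0
  )
}

# worst-scoring cell of every component (two -0.5 cells, rest 0)
worst_intake <- function(id = "worst", energy = 2000) {
  tibble::tibble(
    participant_id = id, n_valid_records = 10, energy_kcal = energy,
    fruit_veg_serv = 1, starch_serv = 0.5, wholegrain_frac = 0.1,
    dairy_serv = 0.5, meat_serv = 0, seafood_serv_week = 0,
    addedfat_pct_ei = 30, vegfat_ratio = 0.2, sugar_pct_ei = 20,
    water_ml = 300, soda_ml = 500, salt_g = 13,
    alcohol_g_day = 50, alcohol_freq_week = 5
  )
}

# matching one-row participant table; energy needs for this subject at the
# given activity class are schofield_bmr * PAL
test_participant <- function(id = "opt", sex = "M", age = 50, weight = 85,
                             pa_class = "high") {
  cfg <- pnnsgs::default_score_config()
  tibble::tibble(
    participant_id = id, sex = sex, age = age, height_cm = 178,
    weight_baseline_kg = weight,
    pa_class = factor(pa_class, levels = c("low", "medium", "high")),
    pa_points = unname(cfg$pa_points[pa_class])
  )
}

needs_for <- function(p) {
  pnnsgs::estimate_energy_needs(
    pnnsgs::schofield_bmr(p$sex, p$age, p$weight_baseline_kg), p$pa_class)
}

# three-group outcome fixture for ANCOVA tests
balanced_groups <- function(n_per = 20, means = c(low = 1, medium = 0,
                                                  high = 0),
                            sd = 1, seed = 1) {
  withr::with_seed(seed, {
    g <- factor(rep(names(means), each = n_per),
                levels = c("low", "medium", "high"))
    tibble::tibble(
      pnns_category = g,
      weight_change_pct = rnorm(length(g), means[as.character(g)], sd)
    )
  })
}
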