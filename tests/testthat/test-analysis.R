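test_that("percent and absolute changes are exact", {
  p <- tibble::tibble(participant_id = c("a", "b"),
                      weight_baseline_kg = c(80, 80),
                      weight_followup_kg = c(80, 82))
  oc <- compute_outcomes(p)
  expect_equal(oc$weight_change_pct, c(0, 2.5))
  expect_equal(oc$weight_change_abs, c(0, 2))
  expect_true(all(is.na(oc$wc_change_pct))) # WC optional, subject retained
  withr::with_seed(2, {
    w0 <- runif(50, 60, 110); w1 <- w0 * runif(50, 0.9, 1.15)
  })
  oc2 <- compute_outcomes(tibble::tibble(participant_id = as.character(1:50),
                                         weight_baseline_kg = w0,
                                         weight_followup_kg = w1))
  expect_equal(oc2$weight_change_pct, (w1 - w0) / w0 * 100)
  expect_error(compute_outcomes(tibble::tibble(
    participant_id = "a", weight_baseline_kg = 0, weight_followup_kg = 1)),
    class = "pnnsgs_error_input")
})

test_that("crude LS-means equal raw group means", {
  d <- balanced_groups(n_per = 25, means = c(low = 3, medium = 2, high = 1),
                       sd = 2, seed = 4)
  fit <- fit_ancova(d, model = "A")
  td <- tidy(fit)
  raw <- tapply(d$weight_change_pct, d$pnns_category, mean)
  expect_equal(td$ls_mean, as.numeric(raw[as.character(td$category)]),
               tolerance = 1e-10)
  expect_true(all(td$ci_low <= td$ls_mean & td$ls_mean <= td$ci_high))
  expect_true(is.na(td$p_vs_ref[td$category == "high"]))
  g <- glance(fit)
  expect_equal(g$n, 75)
})

test_that("with a single contrast the Dunnett p equals the unadjusted p", {
  d <- balanced_groups(n_per = 30, means = c(low = 1.5, high = 0), sd = 2,
                       seed = 6)
  d <- d[d$pnns_category != "medium", ]
  fit <- fit_ancova(d, model = "A")
  lmfit <- lm(weight_change_pct ~ pnns_category,
              data = transform(d, pnns_category = droplevels(
                factor(pnns_category, levels = c("high", "low")))))
  p_lm <- summary(lmfit)$coefficients[2, 4]
  p_dunnett <- tidy(fit)$p_vs_ref[tidy(fit)$category == "low"]
  expect_equal(p_dunnett, p_lm, tolerance = 1e-6)
})

test_that("Dunnett-adjusted p is never below the unadjusted p", {
  for (seed in 1:5) {
    d <- balanced_groups(n_per = 15,
                         means = c(low = 0.8, medium = 0.3, high = 0),
                         sd = 1, seed = seed)
    fit <- fit_ancova(d, model = "A")
    cd <- fit$contrast_detail
    p_unadj <- 2 * stats::pt(abs(cd$t.ratio), df = cd$df, lower.tail = FALSE)
    expect_true(all(cd$p.value >= p_unadj - 1e-10))
  }
})

test_that("adjusted p matches a Monte-Carlo max-|t| oracle", {
  d <- balanced_groups(n_per = 20, means = c(low = 0.9, medium = 0.4,
                                             high = 0), sd = 1, seed = 12)
  fit <- fit_ancova(d, model = "A")
  cd <- fit$contrast_detail
  t_low <- abs(cd$t.ratio[grepl("^low", cd$contrast)])
  # oracle: simulate the null distribution of max(|t1|,|t2|) directly from
  # its construction (shared control mean and residual scale)
  df <- stats::df.residual(fit$fit)
  withr::with_seed(99, {
    R <- 2e5
    ctrl <- rnorm(R); z1 <- rnorm(R); z2 <- rnorm(R)
    s <- sqrt(stats::rchisq(R, df) / df)
    tmax <- pmax(abs(z1 - ctrl), abs(z2 - ctrl)) / (sqrt(2) * s)
  })
  p_oracle <- mean(tmax >= t_low)
  p_pkg <- cd$p.value[grepl("^low", cd$contrast)]
  expect_lt(abs(p_pkg - p_oracle), 0.01)
})

test_that("degenerate designs are rejected", {
  d <- balanced_groups(n_per = 10)
  d1 <- d[d$pnns_category == "low", ]
  expect_error(fit_ancova(d1, model = "A"), class = "pnnsgs_error_input")
  d$age <- 50; d$energy_intake <- d$age * 2 # collinear with intercept+age
  expect_error(fit_ancova(d, model = "B"), class = "pnnsgs_error_rank")
  expect_error(fit_ancova(d, model = "A", ref = "absent"),
               class = "pnnsgs_error_input")
})

test_that("sex interaction is detected when effects differ by sex", {
  withr::with_seed(8, {
    n <- 2500
    sex <- rep(c("M", "F"), each = n / 2)
    cat <- factor(sample(c("low", "medium", "high"), n, replace = TRUE),
                  levels = c("low", "medium", "high"))
    eff <- ifelse(sex == "M",
                  c(low = 3.6, medium = 2.5, high = 2.1)[as.character(cat)],
                  c(low = 1.7, medium = 2.6, high = 3.6)[as.character(cat)])
    d <- tibble::tibble(sex = sex, pnns_category = cat,
                        weight_change_pct = eff + rnorm(n, 0, 4))
  })
  res <- test_interaction(d)
  expect_lt(res$p_value, 0.05)
  expect_error(test_interaction(d[d$sex == "M", ]),
               class = "pnnsgs_error_input")
})

test_that("the interaction test holds its type-I error under the null", {
  withr::with_seed(123, {
    rejections <- vapply(1:200, function(i) {
      n <- 120
      d <- tibble::tibble(
        sex = rep(c("M", "F"), each = n / 2),
        pnns_category = factor(sample(c("low", "medium", "high"), n,
                                      replace = TRUE)),
        weight_change_pct = rnorm(n, 2, 4))
      test_interaction(d)$p_value < 0.05
    }, logical(1))
  })
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("descriptive tables use Kruskal-Wallis and chi-squared", {
  d <- tibble::tibble(
    g = factor(rep(c("low", "medium", "high"), each = 30)),
    x = rep(c(1, 2, 3, 4, 5, 6), 15),
    smoke = rep(c("never", "former", "current"), 30),
    const = 1)
  # identical distributions across groups: Kruskal-Wallis p near 1
  tab <- descriptive_table(d, "g", "x")
  expect_gt(tab$p_value[1], 0.95)
  expect_equal(unique(tab$test), "kruskal-wallis")
  # chi-squared matches the hand formula on a known table
  tab2 <- descriptive_table(d, "g", "smoke")
  ct <- table(d$smoke, d$g)
  e <- outer(rowSums(ct), colSums(ct)) / sum(ct)
  x2 <- sum((ct - e)^2 / e)
  p_hand <- stats::pchisq(x2, df = 4, lower.tail = FALSE)
  expect_equal(tab2$p_value[1], p_hand)
  expect_warning(descriptive_table(d, "g", "const"), "constant")
})

test_that("regression imputation is deterministic and flags imputed rows", {
  d <- tibble::tibble(x = 1:20, y = c(2 * (1:15), rep(NA, 5)))
  out <- regression_impute(d, "y", "x")
  expect_equal(out$y[16:20], 2 * (16:20)) # perfectly determined
  expect_equal(out$y_imputed, c(rep(FALSE, 15), rep(TRUE, 5)))
  expect_identical(regression_impute(d, "y", "x"), out)
  # no missing rows: unchanged apart from the flag column
  d2 <- tibble::tibble(x = 1:10, y = 1:10 * 1.0)
  out2 <- regression_impute(d2, "y", "x")
  expect_equal(out2$y, d2$y)
  expect_false(any(out2$y_imputed))
  expect_error(regression_impute(tibble::tibble(x = NA_real_, y = c(1, NA)),
                                 "y", "x"),
               class = "pnnsgs_error_input")
})

test_that("categorical imputation beats the majority-class baseline", {
  withr::with_seed(44, {
    n <- 600
    x <- rnorm(n)
    cls <- ifelse(x + rnorm(n, 0, 0.5) > 0, "medium", "low")
    miss <- runif(n) < 0.3
    d <- tibble::tibble(x = x, cls = ifelse(miss, NA, cls))
  })
  out <- regression_impute(d, "cls", "x")
  acc <- mean(out$cls[miss] == cls[miss])
  baseline <- max(prop.table(table(cls[!miss])))
  expect_gt(acc, baseline)
})

test_that("unit weights reproduce the unweighted ANCOVA bit-for-bit", {
  d <- balanced_groups(n_per = 30, means = c(low = 2, medium = 1.2,
                                             high = 0.5), sd = 2, seed = 10)
  f0 <- fit_ancova(d, model = "A")
  f1 <- fit_ancova(d, model = "A", weights = rep(1, nrow(d)))
  expect_equal(tidy(f1), tidy(f0))
  expect_equal(f1$overall_p, f0$overall_p)
})

test_that("IPW with everyone included equals the plain analysis", {
  d <- balanced_groups(n_per = 40, means = c(low = 2, medium = 1, high = 0),
                       sd = 2, seed = 14)
  d$bmi <- rnorm(nrow(d), 28, 2)
  res <- ipw_reanalysis(d, rep(TRUE, nrow(d)), predictors = "bmi")
  expect_true(all(abs(res$weights - 1) < 1e-6))
  plain <- fit_ancova(d, model = "A")
  expect_equal(tidy(res), tidy(plain), tolerance = 1e-6)
})

test_that("group ordering is preserved between percent and absolute change", {
  co <- generate_cohort(cohort_spec(n_participants = 3000, seed = 22))
  d <- dplyr::inner_join(
    compute_outcomes(co$participants),
    co$truth[c("participant_id", "pnns_category")], by = "participant_id")
  d <- dplyr::inner_join(d, co$participants[c("participant_id", "sex")],
                         by = "participant_id")
  men <- d[d$sex == "M", ]
  pct <- tapply(men$weight_change_pct, men$pnns_category, mean)
  abs_ <- tapply(men$weight_change_abs, men$pnns_category, mean)
  expect_equal(order(pct), order(abs_))
})
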