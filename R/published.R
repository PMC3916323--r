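#' Published least-squares means of six-year weight and WC change
#'
#' The adjusted (least-squares) means of six-year percent change in weight
#' and waist circumference by PNNS-GS / mPNNS-GS category, sex and adjustment
#' model, as printed in the published analysis of a French middle-aged
#' overweight and obese cohort.  Shipped as a
#' reference for contrast reconstruction and for comparing synthetic-cohort
#' runs against the published effect sizes; built in code, one row per
#' (score, outcome, sex, model, category) cell.
#'
#' @return A tibble with columns `score`, `outcome`, `sex`, `model`,
#'   `category`, `n`, `ls_mean`, `ci_low`, `ci_high`.
#' @export
published_lsmeans <- function() {
  row <- function(score, outcome, sex, model, category, n, ls, lo, hi) {
    tibble(score = score, outcome = outcome, sex = sex, model = model,
           category = category, n = n, ls_mean = ls, ci_low = lo,
           ci_high = hi)
  }
  m <- "weight_change_pct"; w <- "wc_change_pct"
  bind_rows(
    # PNNS-GS, weight, men (n low/medium/high = 195/593/241)
    row("pnns", m, "M", "A", c("low", "medium", "high"), c(195, 593, 241),
        c(3.35, 2.23, 1.76), c(2.63, 1.82, 1.11), c(4.06, 2.64, 2.40)),
    row("pnns", m, "M", "B", c("low", "medium", "high"), c(195, 593, 241),
        c(3.45, 2.21, 1.74), c(2.72, 1.80, 1.08), c(4.19, 2.62, 2.39)),
    row("pnns", m, "M", "C", c("low", "medium", "high"), c(195, 593, 241),
        c(3.63, 2.51, 2.10), c(2.87, 2.05, 1.39), c(4.39, 2.97, 2.81)),
    # PNNS-GS, weight, women (40/255/155)
    row("pnns", m, "F", "A", c("low", "medium", "high"), c(40, 255, 155),
        c(1.70, 2.63, 3.58), c(-0.55, 1.73, 2.44), c(3.96, 3.52, 4.73)),
    row("pnns", m, "F", "B", c("low", "medium", "high"), c(40, 255, 155),
        c(2.20, 2.52, 3.63), c(-0.08, 1.64, 2.49), c(4.47, 3.40, 4.77)),
    row("pnns", m, "F", "C", c("low", "medium", "high"), c(40, 255, 155),
        c(2.37, 2.79, 3.79), c(0.01, 1.64, 2.41), c(4.73, 3.93, 5.17)),
    # PNNS-GS, WC, men (157/508/213)
    row("pnns", w, "M", "A", c("low", "medium", "high"), c(157, 508, 213),
        c(1.51, 1.09, 0.72), c(0.59, 0.57, -0.08), c(2.43, 1.60, 1.51)),
    row("pnns", w, "M", "B", c("low", "medium", "high"), c(157, 508, 213),
        c(1.67, 1.07, 0.64), c(0.72, 0.56, -0.18), c(2.62, 1.58, 1.45)),
    row("pnns", w, "M", "C", c("low", "medium", "high"), c(157, 508, 213),
        c(1.97, 1.49, 1.10), c(1.00, 0.92, 0.23), c(2.94, 2.06, 1.97)),
    # PNNS-GS, WC, women (34/221/136)
    row("pnns", w, "F", "A", c("low", "medium", "high"), c(34, 221, 136),
        c(1.30, 1.85, 3.14), c(-1.48, 0.76, 1.75), c(4.08, 2.94, 4.53)),
    row("pnns", w, "F", "B", c("low", "medium", "high"), c(34, 221, 136),
        c(2.12, 1.83, 2.97), c(-0.73, 0.75, 1.57), c(4.97, 2.92, 4.37)),
    row("pnns", w, "F", "C", c("low", "medium", "high"), c(34, 221, 136),
        c(2.31, 1.99, 3.15), c(-0.68, 0.55, 1.44), c(5.29, 3.43, 4.86)),
    # mPNNS-GS, weight, men (200/636/193)
    row("mpnns", m, "M", "A", c("low", "medium", "high"), c(200, 636, 193),
        c(3.04, 2.29, 1.75), c(2.33, 1.89, 1.02), c(3.75, 2.69, 2.47)),
    row("mpnns", m, "M", "B", c("low", "medium", "high"), c(200, 636, 193),
        c(3.27, 2.24, 1.67), c(2.52, 1.85, 0.93), c(4.02, 2.64, 2.40)),
    row("mpnns", m, "M", "C", c("low", "medium", "high"), c(200, 636, 193),
        c(3.50, 2.55, 2.03), c(2.72, 2.10, 1.24), c(4.28, 3.00, 2.82)),
    # mPNNS-GS, weight, women (29/263/158)
    row("mpnns", m, "F", "A", c("low", "medium", "high"), c(29, 263, 158),
        c(0.56, 2.70, 3.60), c(-2.08, 1.82, 2.46), c(3.20, 3.57, 4.73)),
    row("mpnns", m, "F", "B", c("low", "medium", "high"), c(29, 263, 158),
        c(0.59, 2.52, 3.47), c(-2.10, 1.63, 2.33), c(3.29, 3.41, 4.61)),
    row("mpnns", m, "F", "C", c("low", "medium", "high"), c(29, 263, 158),
        c(0.46, 2.79, 3.70), c(-2.33, 1.63, 2.31), c(3.25, 3.96, 5.08)),
    # mPNNS-GS, WC, men (160/542/176)
    row("mpnns", w, "M", "A", c("low", "medium", "high"), c(160, 542, 176),
        c(1.25, 1.17, 0.62), c(0.34, 0.67, -0.25), c(2.16, 1.66, 1.49)),
    row("mpnns", w, "M", "B", c("low", "medium", "high"), c(160, 542, 176),
        c(1.49, 1.13, 0.51), c(0.53, 0.63, -0.38), c(2.46, 1.63, 1.41)),
    row("mpnns", w, "M", "C", c("low", "medium", "high"), c(160, 542, 176),
        c(1.91, 1.54, 0.94), c(0.92, 0.98, -0.02), c(2.90, 2.10, 1.89)),
    # mPNNS-GS, WC, women (25/225/141)
    row("mpnns", w, "F", "A", c("low", "medium", "high"), c(25, 225, 141),
        c(1.04, 1.74, 3.29), c(-2.20, 0.66, 1.92), c(4.27, 2.82, 4.65)),
    row("mpnns", w, "F", "B", c("low", "medium", "high"), c(25, 225, 141),
        c(1.93, 1.75, 3.10), c(-1.46, 0.65, 1.71), c(5.33, 2.86, 4.49)),
    row("mpnns", w, "F", "C", c("low", "medium", "high"), c(25, 225, 141),
        c(2.01, 1.93, 3.30), c(-1.52, 0.47, 1.60), c(5.53, 3.40, 5.00))
  )
}

#' Reconstruct a category contrast from a least-squares-mean table
#'
#' Difference of adjusted means between two categories within one
#' (score, outcome, sex, model) cell of a table shaped like
#' [published_lsmeans()] or like [tidy.pnns_ancova()] output.
#'
#' @param lsmeans A data frame with `category` and `ls_mean` columns, already
#'   filtered to one model cell (or pass the filters below).
#' @param from,to Category labels; the result is
#'   `ls_mean[from] - ls_mean[to]`.
#' @param score,outcome,sex,model Optional filters applied first when the
#'   corresponding columns exist.
#' @return The contrast, a single number (percentage points).
#' @examples
#' lsmean_difference(published_lsmeans(), score = "pnns",
#'   outcome = "weight_change_pct", sex = "M", model = "C")
#' @export
lsmean_difference <- function(lsmeans, from = "low", to = "high",
                              score = NULL, outcome = NULL, sex = NULL,
                              model = NULL) {
  d <- as_tibble(lsmeans)
  for (col in c("score", "outcome", "sex", "model")) {
    val <- get(col)
    if (!is.null(val) && col %in% names(d)) d <- d[d[[col]] == val, ]
  }
  if (!all(c(from, to) %in% as.character(d$category))) {
    abort("lsmean_difference: requested categories not present after filtering",
          class = "pnnsgs_error_input")
  }
  d$ls_mean[match(from, as.character(d$category))] -
    d$ls_mean[match(to, as.character(d$category))]
}
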