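#' Forest plot of adjusted means by score category
#'
#' Least-squares means with their Dunnett-corrected confidence intervals,
#' one point per category.
#'
#' @param object A `pnns_ancova` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pnns_ancova <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$category, y = .data$ls_mean)) +
    geom_point(size = 2) +
    geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                  width = 0.15) +
    labs(x = "score category",
         y = paste0("adjusted mean ", object$outcome),
         title = sprintf("Model %s least-squares means (ref: %s)",
                         object$model, object$ref),
         subtitle = sprintf("overall F-test p = %.3g", object$overall_p)) +
    theme_minimal()
}

#' Histogram of scores with category breakpoints
#'
#' @param scores A [compute_scores()] breakdown table.
#' @param which `"pnns"` or `"mpnns"`.
#' @param config A `pnns_config` (for the breakpoints).
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, which = c("pnns", "mpnns"),
                                    config = default_score_config()) {
  which <- match.arg(which)
  col <- if (which == "pnns") "pnns_gs" else "m_pnns_gs"
  cuts <- config$categories[[if (which == "pnns") "pnns" else "mpnns"]]
  ggplot(scores, aes(x = .data[[col]])) +
    geom_histogram(binwidth = 0.5, boundary = 0, fill = "grey70",
                   colour = "grey30") +
    geom_vline(xintercept = unname(cuts), linetype = "dashed") +
    labs(x = if (which == "pnns") "PNNS-GS (points)" else
      "mPNNS-GS (points)", y = "participants") +
    theme_minimal()
}

#' Weight-change distribution by category and sex
#'
#' @param sample A pipeline sample table with outcome and category columns.
#' @param outcome,category Column names.
#' @return A ggplot object.
#' @export
plot_outcome_by_category <- function(sample,
                                     outcome = "weight_change_pct",
                                     category = "pnns_category") {
  ggplot(sample, aes(x = .data[[category]], y = .data[[outcome]])) +
    geom_boxplot(outlier.alpha = 0.3) +
    facet_wrap(~ sex) +
    labs(x = "score category", y = outcome) +
    theme_minimal()
}
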