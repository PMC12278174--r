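#' Staircase trajectory plot
#'
#' Level played per epoch, coloured by whether the epoch met the pass
#' criterion, with the final threshold score marked.
#'
#' @param object An `ff_session`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ff_session
#' @export
autoplot.ff_session <- function(object, ...) {
  ep <- object$epochs
  ggplot2::ggplot(ep, ggplot2::aes(x = .data$epoch_index,
                                   y = .data$level_index)) +
    ggplot2::geom_step(direction = "mid", colour = "grey55") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$passed), size = 3) +
    ggplot2::geom_hline(yintercept = object$threshold_score,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_y_continuous(
      breaks = seq_along(object$config$level_ladder),
      limits = c(1, length(object$config$level_ladder))
    ) +
    ggplot2::labs(
      x = "Epoch", y = "Difficulty level (1 = easiest)",
      colour = "Epoch passed",
      title = sprintf("Adaptive staircase: threshold score %d, accuracy %.1f%%",
                      object$threshold_score, object$mean_accuracy_pct)
    ) +
    ggplot2::theme_minimal()
}

#' Cohort accuracy histogram
#'
#' Performance histogram of assessment scores across the cohort; missing
#' scores are dropped.
#'
#' @param cohort A cohort tibble with `freeze_frame_accuracy_pct`.
#' @param binwidth Histogram bin width in percentage points.
#' @return A ggplot object.
#' @export
plot_accuracy_histogram <- function(cohort, binwidth = 1) {
  stopifnot("freeze_frame_accuracy_pct" %in% names(cohort))
  dat <- cohort[!is.na(cohort$freeze_frame_accuracy_pct), , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$freeze_frame_accuracy_pct)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "Mean accuracy (%)", y = "Participants",
                  title = "Assessment score distribution") +
    ggplot2::theme_minimal()
}

#' Concurrent-validity scatter plot
#'
#' Accuracy against the executive composite with the fitted regression line.
#'
#' @param cohort A cohort tibble with `freeze_frame_accuracy_pct` and
#'   `examiner_z`.
#' @return A ggplot object.
#' @export
plot_concurrent_validity <- function(cohort) {
  stopifnot(all(c("freeze_frame_accuracy_pct", "examiner_z") %in% names(cohort)))
  dat <- cohort[!is.na(cohort$freeze_frame_accuracy_pct), , drop = FALSE]
  fit <- simple_ols(dat$freeze_frame_accuracy_pct, dat$examiner_z)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$freeze_frame_accuracy_pct,
                                    y = .data$examiner_z)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "Mean accuracy (%)", y = "Executive composite (z)",
      title = sprintf("Concurrent validity: R² = %.3f, F(%d, %d) = %.2f",
                      fit$r_squared, fit$df_num, fit$df_den, fit$f_statistic)
    ) +
    ggplot2::theme_minimal()
}

#' Association panel for a validation report
#'
#' Dot-and-interval style display of the association estimates in a report
#' (correlations on their own scale; the rank-sum U is omitted since it is
#' not on a correlation scale).
#'
#' @param object An `ff_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ff_report
#' @export
autoplot.ff_report <- function(object, ...) {
  assoc <- tidy(object)
  assoc <- assoc[assoc$statistic_name != "rank_sum_U", , drop = FALSE]
  ggplot2::ggplot(assoc, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(size = 3, colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("p = %.3f", .data$p_value)),
                       vjust = -1, size = 3) +
    ggplot2::xlim(-1, 1) +
    ggplot2::labs(x = "Correlation estimate", y = NULL,
                  title = "Assessment associations (complete cases)") +
    ggplot2::theme_minimal()
}
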