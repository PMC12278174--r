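REPORT_SCHEMA_VERSION <- "1.0"

#' Build a validation report from a cohort table
#'
#' Runs the whole validation pipeline on the complete-case subset (records
#' with a non-missing accuracy score; nothing is imputed): descriptives of
#' accuracy with skew and kurtosis, floor/ceiling quantification on the 0-100
#' scale, Spearman correlations of accuracy with age and education, a
#' Wilcoxon rank-sum comparison between gender groups, the Pearson
#' correlation with the executive composite, and a simple linear regression
#' of the composite on accuracy with its F test. Duration descriptives are
#' included when the cohort carries a `duration_min` column (i.e. when the
#' sessions were actually simulated).
#'
#' @param cohort A cohort tibble with columns `age`, `gender`, `education`,
#'   `examiner_z` and `freeze_frame_accuracy_pct` (possibly with `NA`s).
#' @param score_bounds Lowest and highest possible accuracy, for the
#'   floor/ceiling analysis.
#' @return An object of class `ff_report`.
#' @examples
#' cohort <- apply_missingness(generate_cohort(cohort_config(seed = 3)),
#'                             rate = 0.13, rng = 4)
#' report <- build_report(cohort)
#' tidy(report)
#' @export
build_report <- function(cohort, score_bounds = c(0, 100)) {
  required <- c("age", "gender", "education", "examiner_z",
                "freeze_frame_accuracy_pct")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    abort(paste0("Cohort is missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  cc <- cohort[!is.na(cohort$freeze_frame_accuracy_pct), , drop = FALSE]
  if (nrow(cc) < 10L) {
    abort("Fewer than 10 complete cases; the validation report is not meaningful.")
  }
  acc <- cc$freeze_frame_accuracy_pct

  gender_assoc <- NULL
  g_female <- acc[cc$gender == "female"]
  g_male <- acc[cc$gender == "male"]
  if (length(g_female) < 2L || length(g_male) < 2L) {
    warn("Fewer than 2 participants in a gender group; gender comparison omitted.")
  } else {
    gender_assoc <- rank_sum_test(g_female, g_male)
  }

  structure(
    list(
      schema_version = REPORT_SCHEMA_VERSION,
      n_total = nrow(cohort),
      n_complete = nrow(cc),
      accuracy_descriptives = describe(acc),
      floor_ceiling = floor_ceiling(acc, score_bounds[1], score_bounds[2]),
      age_assoc = assoc_spearman(acc, cc$age),
      edu_assoc = assoc_spearman(acc, cc$education),
      gender_assoc = gender_assoc,
      examiner_assoc = assoc_pearson(acc, cc$examiner_z),
      regression = simple_ols(acc, cc$examiner_z),
      duration_descriptives =
        if ("duration_min" %in% names(cohort)) {
          describe(cohort$duration_min[!is.na(cohort$duration_min)])
        } else {
          NULL
        }
    ),
    class = "ff_report"
  )
}

#' @export
print.ff_report <- function(x, ...) {
  d <- x$accuracy_descriptives
  fc <- x$floor_ceiling
  cat("<validation report>\n")
  cat(sprintf("  complete cases: %d of %d\n", x$n_complete, x$n_total))
  cat(sprintf("  accuracy: mean %.2f (SD %.2f), range [%.2f, %.2f], skew %.2f, kurtosis %.2f\n",
              d$mean, d$sd, d$minimum, d$maximum, d$skewness,
              d$excess_kurtosis))
  cat(sprintf("  floor %.1f%%, ceiling %.1f%% (observed extremes: %d at min, %d at max)\n",
              100 * fc$floor_prop, 100 * fc$ceiling_prop,
              fc$n_at_min_observed, fc$n_at_max_observed))
  cat(sprintf("  age:       Spearman rho = %+.3f, p = %.3f\n",
              x$age_assoc$estimate, x$age_assoc$p_value))
  cat(sprintf("  education: Spearman rho = %+.3f, p = %.3f\n",
              x$edu_assoc$estimate, x$edu_assoc$p_value))
  if (!is.null(x$gender_assoc)) {
    cat(sprintf("  gender:    rank-sum U = %.1f, p = %.3f\n",
                x$gender_assoc$estimate, x$gender_assoc$p_value))
  }
  cat(sprintf("  executive composite: Pearson r = %+.3f, p = %.3f\n",
              x$examiner_assoc$estimate, x$examiner_assoc$p_value))
  r <- x$regression
  cat(sprintf("  regression: R^2 = %.3f, F(%d, %d) = %.3f, p = %.3f\n",
              r$r_squared, r$df_num, r$df_den, r$f_statistic, r$p_value))
  invisible(x)
}

#' @describeIn build_report All association tests stacked in one tibble.
#' @param x An `ff_report`.
#' @param ... Unused.
#' @method tidy ff_report
#' @export
tidy.ff_report <- function(x, ...) {
  rows <- list(
    dplyr::mutate(x$age_assoc, term = "age", .before = 1),
    dplyr::mutate(x$edu_assoc, term = "education", .before = 1),
    if (!is.null(x$gender_assoc)) {
      dplyr::mutate(x$gender_assoc[names(x$age_assoc)], term = "gender",
                    .before = 1)
    },
    dplyr::mutate(x$examiner_assoc, term = "executive_composite", .before = 1)
  )
  dplyr::bind_rows(rows)
}

#' @describeIn build_report One-row report summary.
#' @method glance ff_report
#' @export
glance.ff_report <- function(x, ...) {
  tibble(
    n_total = x$n_total,
    n_complete = x$n_complete,
    accuracy_mean = x$accuracy_descriptives$mean,
    accuracy_sd = x$accuracy_descriptives$sd,
    skewness = x$accuracy_descriptives$skewness,
    excess_kurtosis = x$accuracy_descriptives$excess_kurtosis,
    floor_prop = x$floor_ceiling$floor_prop,
    ceiling_prop = x$floor_ceiling$ceiling_prop,
    age_rho = x$age_assoc$estimate,
    age_p = x$age_assoc$p_value,
    edu_rho = x$edu_assoc$estimate,
    edu_p = x$edu_assoc$p_value,
    gender_p = if (is.null(x$gender_assoc)) NA_real_ else x$gender_assoc$p_value,
    examiner_r = x$examiner_assoc$estimate,
    examiner_p = x$examiner_assoc$p_value,
    r_squared = x$regression$r_squared,
    f_statistic = x$regression$f_statistic,
    df_den = x$regression$df_den
  )
}

#' Serialize a validation report to JSON
#'
#' @param report An `ff_report`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "ff_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Render a validation report as Markdown
#'
#' A compact two-table summary: score characteristics, then the association
#' and regression results.
#'
#' @param report An `ff_report`.
#' @param path Optional output path; when `NULL` the Markdown is returned as
#'   a character vector of lines.
#' @export
report_markdown <- function(report, path = NULL) {
  stopifnot(inherits(report, "ff_report"))
  d <- report$accuracy_descriptives
  fc <- report$floor_ceiling
  assoc <- tidy(report)
  lines <- c(
    "# Assessment validation report",
    "",
    sprintf("Complete cases: %d of %d (missing scores are excluded, not imputed).",
            report$n_complete, report$n_total),
    "",
    "## Score characteristics",
    "",
    "| Statistic | Value |",
    "| --- | --- |",
    sprintf("| Mean accuracy (%%) | %.2f |", d$mean),
    sprintf("| SD (%%) | %.2f |", d$sd),
    sprintf("| Range (%%) | %.2f to %.2f |", d$minimum, d$maximum),
    sprintf("| Skewness (G1) | %.2f |", d$skewness),
    sprintf("| Excess kurtosis (G2) | %.2f |", d$excess_kurtosis),
    sprintf("| Floor / ceiling | %.1f%% / %.1f%% |",
            100 * fc$floor_prop, 100 * fc$ceiling_prop),
    if (!is.null(report$duration_descriptives)) {
      sprintf("| Duration (min), mean (SD) | %.2f (%.2f) |",
              report$duration_descriptives$mean,
              report$duration_descriptives$sd)
    },
    "",
    "## Associations",
    "",
    "| Term | Test | Estimate | p | n |",
    "| --- | --- | --- | --- | --- |",
    sprintf("| %s | %s | %.3f | %.3f | %d |",
            assoc$term, assoc$statistic_name, assoc$estimate, assoc$p_value,
            assoc$n_used),
    "",
    sprintf("Concurrent-validity regression: R^2 = %.3f, F(%d, %d) = %.3f, p = %.3f.",
            report$regression$r_squared, report$regression$df_num,
            report$regression$df_den, report$regression$f_statistic,
            report$regression$p_value)
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}
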