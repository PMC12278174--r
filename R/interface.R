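RUN_SCHEMA_VERSION <- "1.0"

#' Run configuration
#'
#' Bundles an assessment configuration, a cohort configuration, respondent
#' defaults and a global seed into one reproducible unit. The global seed
#' deterministically derives the per-module seeds, so one integer pins an
#' entire simulate-then-validate run.
#'
#' @param assessment An [assessment_config()]; its seed is overridden by a
#'   derivation from `seed`.
#' @param cohort A [cohort_config()]; likewise re-seeded from `seed`.
#' @param respondent Default respondent parameters, an `ff_respondent`.
#' @param seed Global integer seed.
#' @return An object of class `ff_run_config`.
#' @export
run_config <- function(assessment = assessment_config(),
                       cohort = cohort_config(),
                       respondent = respondent_model(),
                       seed = 1L) {
  stopifnot(inherits(assessment, "ff_assessment_config"),
            inherits(cohort, "ff_cohort_config"),
            inherits(respondent, "ff_respondent"))
  assert_scalar_number(seed, "seed")
  assessment$seed <- derive_seed(seed, "assessment")
  cohort$seed <- derive_seed(seed, "cohort")
  structure(
    list(schema_version = RUN_SCHEMA_VERSION, assessment = assessment,
         cohort = cohort, respondent = respondent, seed = as.integer(seed)),
    class = "ff_run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Top-level keys `assessment`, `cohort`, `respondent` and `seed`, each
#' mirroring the corresponding constructor's arguments; absent keys fall
#' back to defaults.
#'
#' @param path Path to a YAML file.
#' @return An `ff_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) abort("Run config did not parse to a mapping.")
  known <- c("assessment", "cohort", "respondent", "seed", "schema_version")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(paste0("Unknown run config fields: ", paste(extra, collapse = ", ")))
  }
  build <- function(ctor, args) {
    if (is.null(args)) return(ctor())
    allowed <- names(formals(ctor))
    bad <- setdiff(names(args), allowed)
    if (length(bad)) {
      abort(paste0("Unknown fields: ", paste(bad, collapse = ", ")))
    }
    do.call(ctor, args)
  }
  run_config(
    assessment = build(assessment_config, raw$assessment),
    cohort = build(cohort_config, raw$cohort),
    respondent = build(respondent_model, raw$respondent),
    seed = if (is.null(raw$seed)) 1L else raw$seed
  )
}

#' Simulate one session and write its log
#'
#' @param run An `ff_run_config` (or path to a YAML run config).
#' @param output Path for the session-log JSON.
#' @param respondent Optional respondent override (e.g. a
#'   [deterministic_respondent()]).
#' @return The `ff_session`, invisibly; the log is written to `output`.
#' @export
simulate_session_file <- function(run, output, respondent = NULL) {
  if (is.character(run)) run <- read_run_config(run)
  stopifnot(inherits(run, "ff_run_config"))
  if (is.null(respondent)) respondent <- run$respondent
  session <- run_session(run$assessment, respondent)
  write_session_log(session, output)
  invisible(session)
}

#' Simulate a cohort and write it as CSV
#'
#' Generates the cohort, optionally replaces analytic accuracies with
#' engine-played sessions, applies missingness at the configured rate, and
#' writes the table.
#'
#' @param run An `ff_run_config` (or path to a YAML run config).
#' @param output Path for the cohort CSV.
#' @param play_sessions If `TRUE`, run one full adaptive session per
#'   participant instead of using the analytic accuracy.
#' @return The cohort tibble, invisibly.
#' @export
simulate_cohort_file <- function(run, output, play_sessions = FALSE) {
  if (is.character(run)) run <- read_run_config(run)
  stopifnot(inherits(run, "ff_run_config"))
  cohort <- generate_cohort(run$cohort)
  if (play_sessions) {
    cohort <- simulate_cohort_sessions(cohort, run$assessment)
  }
  cohort <- apply_missingness(cohort, run$cohort$missing_rate,
                              rng = derive_seed(run$seed, "missingness"))
  write_cohort_csv(cohort, output)
  invisible(cohort)
}

#' Validate a cohort CSV and write the report
#'
#' Reads a cohort table, builds the validation report on its complete cases,
#' and writes it as JSON plus a Markdown rendering.
#'
#' @param cohort_csv Path to a cohort CSV (as written by
#'   [write_cohort_csv()]).
#' @param output_json Path for the report JSON.
#' @param output_md Optional path for the Markdown rendering.
#' @return The `ff_report`, invisibly.
#' @export
validate_cohort_file <- function(cohort_csv, output_json, output_md = NULL) {
  cohort <- read_cohort_csv(cohort_csv)
  report <- build_report(cohort)
  write_report_json(report, output_json)
  if (!is.null(output_md)) report_markdown(report, output_md)
  invisible(report)
}
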