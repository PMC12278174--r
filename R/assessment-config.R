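#' Assessment configuration
#'
#' Parameters of the adaptive reverse go/no-go task. The task presents a rapid
#' stream of target and foil images; the respondent must withhold a response
#' to targets and respond quickly to foils. Difficulty is adapted across
#' epochs by changing the target frequency: lower target frequency makes
#' withholding harder, so the ladder runs from the easiest level (highest
#' frequency) to the hardest (lowest frequency).
#'
#' Defaults mirror the deployed assessment: seven levels at target
#' frequencies 40/35/30/25/20/15/10 percent, a 30 percent starting level,
#' five epochs of thirty trials, an inclusive 80 percent pass criterion on
#' both stimulus classes, and interstimulus intervals drawn uniformly between
#' 500 and 1500 ms.
#'
#' @param level_ladder Numeric vector of target frequencies in (0, 1),
#'   strictly decreasing (easiest first).
#' @param start_level 1-based index into `level_ladder` where every session
#'   begins.
#' @param epochs_per_session Number of adaptation epochs per session.
#' @param trials_per_epoch Number of trials in each epoch.
#' @param pass_criterion Minimum proportion correct, applied inclusively to
#'   both the target-withhold and the foil-response accuracy, for the epoch
#'   to count as passed.
#' @param isi_min_ms,isi_max_ms Bounds of the uniform interstimulus-interval
#'   distribution, in milliseconds.
#' @param stimulus_duration_ms Stimulus presentation time in milliseconds
#'   (the response window extends to the next stimulus onset).
#' @param seed Integer seed from which all session randomness is derived.
#' @return An object of class `ff_assessment_config` (a validated list).
#' @examples
#' cfg <- assessment_config()
#' build_level_ladder(cfg)
#' @export
assessment_config <- function(level_ladder = c(0.40, 0.35, 0.30, 0.25, 0.20, 0.15, 0.10),
                              start_level = 3L,
                              epochs_per_session = 5L,
                              trials_per_epoch = 30L,
                              pass_criterion = 0.80,
                              isi_min_ms = 500,
                              isi_max_ms = 1500,
                              stimulus_duration_ms = 500,
                              seed = 1L) {
  if (!is.numeric(level_ladder) || length(level_ladder) < 1L ||
      any(level_ladder <= 0) || any(level_ladder >= 1)) {
    abort("`level_ladder` must be target frequencies strictly inside (0, 1).")
  }
  if (length(level_ladder) > 1L && any(diff(level_ladder) >= 0)) {
    abort("`level_ladder` must be strictly decreasing (easiest level first).")
  }
  start_level <- as.integer(assert_scalar_number(start_level, "start_level",
                                                 1, length(level_ladder)))
  epochs_per_session <- as.integer(assert_scalar_number(
    epochs_per_session, "epochs_per_session", 1))
  trials_per_epoch <- as.integer(assert_scalar_number(
    trials_per_epoch, "trials_per_epoch", 2))
  assert_scalar_number(pass_criterion, "pass_criterion", 0, 1,
                       strict_lower = TRUE)
  assert_scalar_number(isi_min_ms, "isi_min_ms", 0)
  assert_scalar_number(isi_max_ms, "isi_max_ms", isi_min_ms)
  assert_scalar_number(stimulus_duration_ms, "stimulus_duration_ms", 0)
  assert_scalar_number(seed, "seed")

  structure(
    list(
      level_ladder = as.numeric(level_ladder),
      start_level = start_level,
      epochs_per_session = epochs_per_session,
      trials_per_epoch = trials_per_epoch,
      pass_criterion = pass_criterion,
      isi_min_ms = isi_min_ms,
      isi_max_ms = isi_max_ms,
      stimulus_duration_ms = stimulus_duration_ms,
      seed = as.integer(seed)
    ),
    class = "ff_assessment_config"
  )
}

#' @export
print.ff_assessment_config <- function(x, ...) {
  cat("<assessment config>\n")
  cat("  levels:", paste0(sprintf("%g%%", 100 * x$level_ladder), collapse = " "),
      "\n")
  cat(sprintf("  start level %d; %d epochs x %d trials; pass >= %g%% on both classes\n",
              x$start_level, x$epochs_per_session, x$trials_per_epoch,
              100 * x$pass_criterion))
  cat(sprintf("  ISI uniform [%g, %g] ms; stimulus %g ms; seed %d\n",
              x$isi_min_ms, x$isi_max_ms, x$stimulus_duration_ms, x$seed))
  invisible(x)
}

#' Difficulty ladder as a table
#'
#' @param config An [assessment_config()].
#' @return A tibble with columns `level_index` (1 = easiest) and
#'   `target_frequency`.
#' @export
build_level_ladder <- function(config = assessment_config()) {
  stopifnot(inherits(config, "ff_assessment_config"))
  tibble(
    level_index = seq_along(config$level_ladder),
    target_frequency = config$level_ladder
  )
}

#' Read an assessment configuration from YAML
#'
#' The YAML keys mirror the arguments of [assessment_config()]; absent keys
#' fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return An `ff_assessment_config`.
#' @export
read_assessment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) abort("Config file did not parse to a mapping.")
  allowed <- names(formals(assessment_config))
  extra <- setdiff(names(raw), allowed)
  if (length(extra)) {
    abort(paste0("Unknown assessment config fields: ",
                 paste(extra, collapse = ", ")))
  }
  do.call(assessment_config, raw)
}

#' Write an assessment configuration to YAML
#' @param config An `ff_assessment_config`.
#' @param path Output path.
#' @export
write_assessment_config <- function(config, path) {
  stopifnot(inherits(config, "ff_assessment_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
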