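#' Plan one epoch of trials
#'
#' Builds the stimulus schedule for a single epoch at a given ladder level.
#' The number of targets is the nominal count
#' `round-half-to-even(target_frequency * trials_per_epoch)`, realized
#' exactly and then uniformly shuffled among the foils, so the advertised
#' frequency holds per epoch rather than only in expectation. Interstimulus
#' intervals are drawn from a continuous uniform distribution on
#' `[isi_min_ms, isi_max_ms]`.
#'
#' @param config An [assessment_config()].
#' @param level_index Ladder level to plan at.
#' @param rng `NULL`, an integer seed, or an internal stream; when `NULL`
#'   the global RNG is used.
#' @return A tibble with columns `trial_index`, `stimulus_kind`
#'   (`"target"`/`"foil"`) and `isi_ms`.
#' @examples
#' plan_epoch(assessment_config(), level_index = 3, rng = 1)
#' @export
plan_epoch <- function(config, level_index, rng = NULL) {
  stopifnot(inherits(config, "ff_assessment_config"))
  if (!is.numeric(level_index) || length(level_index) != 1L ||
      level_index < 1 || level_index > length(config$level_ladder)) {
    abort("`level_index` is outside the configured ladder.")
  }
  rng <- as_rng(rng)
  n <- config$trials_per_epoch
  freq <- config$level_ladder[[level_index]]
  n_targets <- round_half_even(freq * n)
  if (n_targets < 1L || n_targets > n - 1L) {
    abort("Epoch would contain zero targets or zero foils; increase trials_per_epoch.")
  }
  kinds <- rep("foil", n)
  pos <- rng_eval(rng, function() sample.int(n, n_targets))
  kinds[pos] <- "target"
  isi <- rng_eval(rng, function() runif(n, config$isi_min_ms, config$isi_max_ms))
  tibble(trial_index = seq_len(n), stimulus_kind = kinds, isi_ms = isi)
}

#' Score one epoch against the pass criterion
#'
#' Computes the proportion of targets correctly withheld and of foils
#' correctly responded to; the epoch passes when both proportions reach the
#' criterion, with an inclusive (>=) comparison on each.
#'
#' @param trials A tibble of trials from a single epoch with columns
#'   `stimulus_kind` and `responded` (a `correct` column is derived if
#'   absent: withhold on target, respond on foil).
#' @param pass_criterion Fraction in (0, 1\]; both class accuracies must be
#'   at least this to pass.
#' @param level_index,target_frequency Optional level bookkeeping carried
#'   into the result.
#' @return A one-row tibble: `level_index`, `target_frequency`, `n_targets`,
#'   `n_foils`, `target_withhold_accuracy`, `foil_response_accuracy`,
#'   `passed`.
#' @export
evaluate_epoch <- function(trials, pass_criterion = 0.80,
                           level_index = NA_integer_,
                           target_frequency = NA_real_) {
  stopifnot(is.data.frame(trials),
            all(c("stimulus_kind", "responded") %in% names(trials)))
  assert_scalar_number(pass_criterion, "pass_criterion", 0, 1,
                       strict_lower = TRUE)
  is_target <- trials$stimulus_kind == "target"
  n_targets <- sum(is_target)
  n_foils <- sum(!is_target)
  if (n_targets == 0L || n_foils == 0L) {
    abort("Epoch accuracy is undefined without at least one target and one foil.")
  }
  target_acc <- mean(!trials$responded[is_target])
  foil_acc <- mean(trials$responded[!is_target])
  tibble(
    level_index = as.integer(level_index),
    target_frequency = target_frequency,
    n_targets = n_targets,
    n_foils = n_foils,
    target_withhold_accuracy = target_acc,
    foil_response_accuracy = foil_acc,
    passed = target_acc >= pass_criterion && foil_acc >= pass_criterion
  )
}

#' Staircase adaptation rule
#'
#' A passed epoch moves to the next harder level (lower target frequency);
#' a failed epoch moves to the next easier level. The trajectory is clamped
#' at both ends of the ladder.
#'
#' @param level_index Current level.
#' @param passed Logical: did the epoch meet the criterion on both classes?
#' @param n_levels Ladder length.
#' @return The level for the following epoch.
#' @export
next_level <- function(level_index, passed, n_levels) {
  stopifnot(level_index >= 1, level_index <= n_levels,
            is.logical(passed), length(passed) == 1L, !is.na(passed))
  if (passed) min(level_index + 1L, n_levels) else max(level_index - 1L, 1L)
}

#' Run one full adaptive session
#'
#' Plays `epochs_per_session` epochs starting at `start_level`, adapting the
#' level after each epoch with [next_level()]. The raw threshold score is the
#' level the staircase would play next after the final epoch's adaptation
#' (clamped to the ladder), so a respondent who passes every epoch from the
#' default start reaches the hardest level, 7, and one who fails every epoch
#' ends at the easiest, 1. Session mean accuracy is the percentage of correct
#' trials over the whole session; the duration estimate sums stimulus time,
#' interstimulus intervals, and response latencies on responded trials.
#'
#' All randomness derives from `config$seed` through three named sub-streams
#' (trial sequence, intervals, respondent), so a session is fully reproducible
#' from its configuration.
#'
#' @param config An [assessment_config()].
#' @param respondent An `ff_respondent`.
#' @return An object of class `ff_session`: a list with `trials` (tibble of
#'   per-trial records), `epochs` (tibble of per-epoch results),
#'   `threshold_score`, `mean_accuracy_pct`, `estimated_duration_min`,
#'   `seed`, and the `config` used.
#' @examples
#' s <- run_session(assessment_config(seed = 7), respondent_model())
#' s$threshold_score
#' tidy(s)
#' @export
run_session <- function(config = assessment_config(),
                        respondent = respondent_model()) {
  stopifnot(inherits(config, "ff_assessment_config"),
            inherits(respondent, "ff_respondent"))
  seq_rng <- new_rng(derive_seed(config$seed, "sequence"))
  isi_rng <- new_rng(derive_seed(config$seed, "isi"))
  resp_rng <- new_rng(derive_seed(config$seed, "respondent"))

  n_levels <- length(config$level_ladder)
  level <- config$start_level
  trial_list <- vector("list", config$epochs_per_session)
  epoch_list <- vector("list", config$epochs_per_session)

  for (e in seq_len(config$epochs_per_session)) {
    plan <- plan_epoch(config, level, rng = seq_rng)
    plan$isi_ms <- rng_eval(isi_rng, function() {
      runif(nrow(plan), config$isi_min_ms, config$isi_max_ms)
    })
    resp <- simulate_epoch_responses(respondent, plan, level, resp_rng)
    trials <- tibble(
      epoch_index = e,
      trial_index = plan$trial_index,
      stimulus_kind = plan$stimulus_kind,
      isi_ms = plan$isi_ms,
      responded = resp$responded,
      latency_ms = resp$latency_ms,
      correct = (plan$stimulus_kind == "target") != resp$responded
    )
    ep <- evaluate_epoch(trials, config$pass_criterion,
                         level_index = level,
                         target_frequency = config$level_ladder[[level]])
    ep$epoch_index <- e
    trial_list[[e]] <- trials
    epoch_list[[e]] <- ep
    level <- next_level(level, ep$passed, n_levels)
  }

  trials <- dplyr::bind_rows(trial_list)
  epochs <- dplyr::relocate(dplyr::bind_rows(epoch_list), "epoch_index")
  duration_ms <- sum(config$stimulus_duration_ms + trials$isi_ms +
                       ifelse(trials$responded, trials$latency_ms, 0))
  structure(
    list(
      trials = trials,
      epochs = epochs,
      threshold_score = as.integer(level),
      mean_accuracy_pct = 100 * mean(trials$correct),
      estimated_duration_min = duration_ms / 60000,
      seed = config$seed,
      config = config
    ),
    class = "ff_session"
  )
}

#' Session mean accuracy
#'
#' Percentage of correct trials over the whole session (equivalently, the
#' trial-weighted mean of per-epoch accuracies, since epochs share a size).
#'
#' @param session An `ff_session`.
#' @return A percentage in \[0, 100\].
#' @export
mean_accuracy <- function(session) {
  stopifnot(inherits(session, "ff_session"))
  if (nrow(session$trials) == 0L) abort("Session has no trials.")
  100 * mean(session$trials$correct)
}

#' @export
print.ff_session <- function(x, ...) {
  cat("<adaptive session>\n")
  cat(sprintf("  threshold score: %d of %d\n", x$threshold_score,
              length(x$config$level_ladder)))
  cat(sprintf("  mean accuracy:   %.2f%% over %d trials\n",
              x$mean_accuracy_pct, nrow(x$trials)))
  cat(sprintf("  est. duration:   %.2f min\n", x$estimated_duration_min))
  cat("  levels played:  ",
      paste(x$epochs$level_index, collapse = " -> "), "\n")
  invisible(x)
}

#' @describeIn run_session Per-epoch results as a tibble.
#' @param x An `ff_session`.
#' @param ... Unused.
#' @method tidy ff_session
#' @export
tidy.ff_session <- function(x, ...) x$epochs

#' @describeIn run_session One-row session summary.
#' @method glance ff_session
#' @export
glance.ff_session <- function(x, ...) {
  tibble(
    threshold_score = x$threshold_score,
    mean_accuracy_pct = x$mean_accuracy_pct,
    estimated_duration_min = x$estimated_duration_min,
    n_trials = nrow(x$trials),
    n_epochs = nrow(x$epochs),
    seed = x$seed
  )
}
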