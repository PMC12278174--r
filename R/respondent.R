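#' Simulated respondent
#'
#' A simulated participant maps latent inhibitory-control ability onto
#' trial-level behaviour so the adaptive engine can be exercised in closed
#' loop. On target trials the probability of correctly withholding is a
#' logistic function of ability minus a per-level difficulty,
#' `plogis(ability - d_l)`, with `d_l = difficulty_delta *
#' (level_index - difficulty_anchor)`: lower target frequencies (higher
#' level indices) are harder, so `d_l` increases with level. On foil trials
#' the respondent responds with probability `1 - foil_lapse_rate`. Response
#' latencies, used only for duration estimates, are log-normal.
#'
#' The default ability places the 80 percent withhold point one level above
#' the default starting level (i.e. at mid-ladder), which keeps the staircase
#' informative: `ability = qlogis(0.8) + difficulty_delta`.
#'
#' @param ability Latent inhibition ability (unitless; higher is better).
#' @param difficulty_delta Difficulty increment per ladder level (> 0).
#' @param difficulty_anchor Level index at which difficulty is zero.
#' @param foil_lapse_rate Probability of failing to respond to a foil, in
#'   \[0, 1).
#' @param latency_meanlog,latency_sdlog Log-normal response-latency
#'   parameters (ms scale; default median ~450 ms).
#' @param seed Optional integer seed for the respondent's own stream.
#' @return An object of class `ff_respondent`.
#' @examples
#' r <- respondent_model()
#' p_withhold(r, level_index = 1:7)
#' @export
respondent_model <- function(ability = qlogis(0.8) + 0.9,
                             difficulty_delta = 0.9,
                             difficulty_anchor = 3,
                             foil_lapse_rate = 0.02,
                             latency_meanlog = log(450),
                             latency_sdlog = 0.25,
                             seed = NULL) {
  assert_scalar_number(ability, "ability")
  assert_scalar_number(difficulty_delta, "difficulty_delta", 0,
                       strict_lower = TRUE)
  assert_scalar_number(difficulty_anchor, "difficulty_anchor")
  assert_scalar_number(foil_lapse_rate, "foil_lapse_rate", 0, 1)
  if (foil_lapse_rate >= 1) abort("`foil_lapse_rate` must be below 1.")
  assert_scalar_number(latency_sdlog, "latency_sdlog", 0)
  structure(
    list(
      type = "stochastic",
      ability = ability,
      difficulty_delta = difficulty_delta,
      difficulty_anchor = difficulty_anchor,
      foil_lapse_rate = foil_lapse_rate,
      latency_meanlog = latency_meanlog,
      latency_sdlog = latency_sdlog,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "ff_respondent"
  )
}

#' Deterministic respondent (test fixture)
#'
#' Realizes fixed per-epoch accuracies exactly rather than stochastically:
#' in an epoch with `n` targets it withholds on exactly
#' `ceiling(target_withhold_acc * n)` of them (and analogously for foils),
#' so staircase trajectories are fully predictable. The ceiling guarantees
#' the realized proportion is at least the nominal one, so a respondent built
#' at the pass criterion always passes under the inclusive comparison.
#'
#' @param target_withhold_acc Fraction of targets correctly withheld, in
#'   \[0, 1\].
#' @param foil_hit_acc Fraction of foils correctly responded to, in \[0, 1\].
#' @param latency_ms Fixed response latency used when a response is emitted.
#' @return An `ff_respondent` of deterministic type.
#' @examples
#' perfect <- deterministic_respondent(1, 1)
#' always_responds <- deterministic_respondent(0, 1)
#' @export
deterministic_respondent <- function(target_withhold_acc, foil_hit_acc,
                                     latency_ms = 450) {
  assert_scalar_number(target_withhold_acc, "target_withhold_acc", 0, 1)
  assert_scalar_number(foil_hit_acc, "foil_hit_acc", 0, 1)
  assert_scalar_number(latency_ms, "latency_ms", 0)
  structure(
    list(
      type = "deterministic",
      target_withhold_acc = target_withhold_acc,
      foil_hit_acc = foil_hit_acc,
      latency_ms = latency_ms,
      seed = NULL
    ),
    class = "ff_respondent"
  )
}

#' @export
print.ff_respondent <- function(x, ...) {
  if (x$type == "deterministic") {
    cat(sprintf("<deterministic respondent: withhold %g, foil hit %g>\n",
                x$target_withhold_acc, x$foil_hit_acc))
  } else {
    cat(sprintf("<respondent: ability %.3f, delta %.2f, foil lapse %.3f>\n",
                x$ability, x$difficulty_delta, x$foil_lapse_rate))
  }
  invisible(x)
}

# Per-level difficulty d_l, strictly increasing in level_index.
level_difficulty <- function(respondent, level_index) {
  respondent$difficulty_delta * (level_index - respondent$difficulty_anchor)
}

#' Probability of correctly withholding on a target
#'
#' `plogis(ability - d_l)`: strictly increasing in ability and strictly
#' decreasing in level index for a fixed ability.
#'
#' @param respondent An [respondent_model()].
#' @param level_index Ladder level (vectorized).
#' @param ability Optional ability override (defaults to the respondent's).
#' @return Probabilities in (0, 1).
#' @export
p_withhold <- function(respondent, level_index, ability = NULL) {
  stopifnot(inherits(respondent, "ff_respondent"))
  if (respondent$type == "deterministic") {
    return(rep(respondent$target_withhold_acc, length(level_index)))
  }
  if (is.null(ability)) ability <- respondent$ability
  plogis(ability - level_difficulty(respondent, level_index))
}

#' Simulate trial-level responses
#'
#' Vectorized over stimuli: targets elicit a response with probability
#' `1 - p_withhold`; foils with probability `1 - foil_lapse_rate`. A
#' log-normal latency is drawn whenever a response is emitted and is `NA`
#' otherwise. For a deterministic respondent the per-trial rule only
#' supports the degenerate accuracies 0 and 1 (exact fractional counts are
#' realized at the epoch level by [run_session()]).
#'
#' @param respondent An `ff_respondent`.
#' @param stimulus_kind Character vector of `"target"` / `"foil"`.
#' @param level_index Ladder level of the epoch the trials belong to.
#' @param rng `NULL` (use the global RNG), an integer seed, or an internal
#'   stream.
#' @return A tibble with columns `responded` (logical) and `latency_ms`.
#' @export
simulate_response <- function(respondent, stimulus_kind, level_index,
                              rng = NULL) {
  stopifnot(inherits(respondent, "ff_respondent"))
  if (!all(stimulus_kind %in% c("target", "foil"))) {
    abort("`stimulus_kind` must be 'target' or 'foil'.")
  }
  rng <- as_rng(if (is.null(rng)) respondent$seed else rng)
  n <- length(stimulus_kind)
  is_target <- stimulus_kind == "target"

  if (respondent$type == "deterministic") {
    if (!all(c(respondent$target_withhold_acc, respondent$foil_hit_acc)
             %in% c(0, 1))) {
      abort(paste("Per-trial simulation of a deterministic respondent needs",
                  "accuracies of exactly 0 or 1; fractional accuracies are",
                  "realized per epoch by run_session()."))
    }
    responded <- ifelse(is_target,
                        respondent$target_withhold_acc == 0,
                        respondent$foil_hit_acc == 1)
    latency <- ifelse(responded, respondent$latency_ms, NA_real_)
    return(tibble(responded = responded, latency_ms = latency))
  }

  p_resp <- ifelse(is_target,
                   1 - p_withhold(respondent, level_index),
                   1 - respondent$foil_lapse_rate)
  draws <- rng_eval(rng, function() {
    u <- runif(n)
    lat <- rlnorm(n, respondent$latency_meanlog, respondent$latency_sdlog)
    list(u = u, lat = lat)
  })
  responded <- draws$u < p_resp
  tibble(responded = responded,
         latency_ms = ifelse(responded, draws$lat, NA_real_))
}

# Epoch-level response realization. Dispatches on respondent type so that
# deterministic respondents hit their nominal accuracies exactly
# (ceiling(acc * n) correct per stimulus class, positions arbitrary but
# reproducible: the first k of each class).
simulate_epoch_responses <- function(respondent, plan, level_index, rng) {
  if (respondent$type == "deterministic") {
    is_target <- plan$stimulus_kind == "target"
    n_t <- sum(is_target)
    n_f <- sum(!is_target)
    k_withhold <- min(n_t, ceiling(respondent$target_withhold_acc * n_t))
    k_hit <- min(n_f, ceiling(respondent$foil_hit_acc * n_f))
    responded <- logical(nrow(plan))
    target_pos <- which(is_target)
    foil_pos <- which(!is_target)
    # targets: correct = withheld; first k_withhold targets stay silent
    if (n_t > k_withhold) responded[target_pos[seq_len(n_t - k_withhold) + k_withhold]] <- TRUE
    if (k_hit > 0) responded[foil_pos[seq_len(k_hit)]] <- TRUE
    latency <- ifelse(responded, respondent$latency_ms, NA_real_)
    return(tibble(responded = responded, latency_ms = latency))
  }
  simulate_response(respondent, plan$stimulus_kind, level_index, rng)
}
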