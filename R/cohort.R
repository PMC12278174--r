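#' Cohort configuration
#'
#' Parameters of the synthetic baseline cohort: a healthy older-adult sample
#' with demographics, an executive-function composite, a latent
#' inhibitory-control ability, and assessment accuracy. Defaults emulate a
#' 92-person intent-to-treat sample: age 65-83 (mean 71.9, SD 4.86), 66%
#' female, education mean 16.45 (SD 3.40) years, executive composite mean
#' 0.43 (SD 0.57) z-units, assessment accuracy mean 92.01% (SD 4.70%), a
#' rank correlation of accuracy with age of -0.22, a Pearson correlation
#' with the executive composite of 0.26, and 13% of accuracy scores missing
#' completely at random.
#'
#' A single latent ability factor mediates every association: ability loads
#' negatively on standardized age, positively on female gender, and the
#' executive composite loads on ability. The age loading is set to
#' `2 * sin(pi * rho_age / 6)` so the *population Spearman* correlation of
#' accuracy with age equals `rho_age` under the (approximately) Gaussian
#' generative model; `r_examiner` is a Pearson target and is used directly.
#' Education is generated independent of ability.
#'
#' @param n Cohort size.
#' @param age_mean,age_sd,age_range Truncated-normal age distribution (years).
#' @param prop_female Proportion of female participants.
#' @param edu_mean,edu_sd,edu_range Truncated-normal education (years).
#' @param examiner_mean,examiner_sd Executive composite, z-units.
#' @param accuracy_mean,accuracy_sd Assessment accuracy targets (percent).
#' @param rho_age Target rank correlation of accuracy with age, in (-1, 1).
#' @param r_examiner Target Pearson correlation of accuracy with the
#'   executive composite, in (-1, 1).
#' @param gender_effect_sd Standardized female-minus-male ability difference.
#' @param missing_rate Probability that an accuracy score is missing.
#' @param seed Integer seed.
#' @return An object of class `ff_cohort_config`.
#' @export
cohort_config <- function(n = 92L,
                          age_mean = 71.9, age_sd = 4.86,
                          age_range = c(65, 83),
                          prop_female = 0.66,
                          edu_mean = 16.45, edu_sd = 3.40,
                          edu_range = c(9, 27),
                          examiner_mean = 0.43, examiner_sd = 0.57,
                          accuracy_mean = 92.01, accuracy_sd = 4.70,
                          rho_age = -0.22,
                          r_examiner = 0.26,
                          gender_effect_sd = 0.35,
                          missing_rate = 0.13,
                          seed = 1L) {
  n <- as.integer(assert_scalar_number(n, "n", 2))
  for (nm in c("age_sd", "edu_sd", "examiner_sd", "accuracy_sd")) {
    assert_scalar_number(get(nm), nm, 0, strict_lower = TRUE)
  }
  assert_scalar_number(prop_female, "prop_female", 0, 1)
  assert_scalar_number(missing_rate, "missing_rate", 0, 1)
  for (nm in c("rho_age", "r_examiner")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || abs(v) >= 1) {
      abort(sprintf("`%s` must be a correlation strictly inside (-1, 1).", nm))
    }
  }
  stopifnot(length(age_range) == 2L, age_range[1] < age_range[2],
            length(edu_range) == 2L, edu_range[1] < edu_range[2])
  structure(
    list(n = n, age_mean = age_mean, age_sd = age_sd, age_range = age_range,
         prop_female = prop_female, edu_mean = edu_mean, edu_sd = edu_sd,
         edu_range = edu_range, examiner_mean = examiner_mean,
         examiner_sd = examiner_sd, accuracy_mean = accuracy_mean,
         accuracy_sd = accuracy_sd, rho_age = rho_age,
         r_examiner = r_examiner, gender_effect_sd = gender_effect_sd,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "ff_cohort_config"
  )
}

#' @export
print.ff_cohort_config <- function(x, ...) {
  cat(sprintf("<cohort config: n=%d, age %.1f (%.2f), %.0f%% female, accuracy %.2f (%.2f), seed %d>\n",
              x$n, x$age_mean, x$age_sd, 100 * x$prop_female,
              x$accuracy_mean, x$accuracy_sd, x$seed))
  invisible(x)
}

# Mean and SD of a normal(mu, sigma) truncated to [lo, hi]; used to
# standardize truncated draws against their population moments.
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  phi_a <- dnorm(a)
  phi_b <- dnorm(b)
  m <- mu + sigma * (phi_a - phi_b) / z
  v <- sigma^2 * (1 + (a * phi_a - b * phi_b) / z - ((phi_a - phi_b) / z)^2)
  list(mean = m, sd = sqrt(v))
}

#' Generate a synthetic cohort
#'
#' Draws demographics from truncated-normal / Bernoulli marginals, builds the
#' latent ability factor with loadings solved from the configured correlation
#' targets, derives the executive composite from ability, and fills accuracy
#' as an affine function of ability scaled to the configured mean and SD
#' (clamped to \[0, 100\]). Deterministic given the seed. No missingness is
#' applied here; see [apply_missingness()].
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per participant: `participant_id`, `age`,
#'   `gender`, `education`, `examiner_z`, `latent_ability`,
#'   `freeze_frame_accuracy_pct`.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 42))
#' nrow(cohort)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "ff_cohort_config"))
  n <- config$n

  loading_age <- 2 * sin(pi * config$rho_age / 6)
  var_gender <- config$gender_effect_sd^2 *
    config$prop_female * (1 - config$prop_female)
  var_noise <- 1 - loading_age^2 - var_gender
  if (var_noise <= 0) {
    abort("Infeasible correlation targets: age and gender loadings exceed unit ability variance.")
  }

  rng <- new_rng(derive_seed(config$seed, "cohort"))
  draws <- rng_eval(rng, function() {
    list(
      age = rtruncnorm(n, config$age_mean, config$age_sd,
                       config$age_range[1], config$age_range[2]),
      female = runif(n) < config$prop_female,
      education = rtruncnorm(n, config$edu_mean, config$edu_sd,
                             config$edu_range[1], config$edu_range[2]),
      ability_noise = rnorm(n),
      examiner_noise = rnorm(n)
    )
  })

  tn <- truncnorm_moments(config$age_mean, config$age_sd,
                          config$age_range[1], config$age_range[2])
  z_age <- (draws$age - tn$mean) / tn$sd

  ability <- loading_age * z_age +
    config$gender_effect_sd * (draws$female - config$prop_female) +
    sqrt(var_noise) * draws$ability_noise

  b <- config$r_examiner
  examiner_std <- b * ability + sqrt(1 - b^2) * draws$examiner_noise
  examiner_z <- config$examiner_mean + config$examiner_sd * examiner_std

  accuracy <- config$accuracy_mean + config$accuracy_sd * ability
  accuracy <- pmin(pmax(accuracy, 0), 100)

  tibble(
    participant_id = sprintf("P%04d", seq_len(n)),
    age = draws$age,
    gender = ifelse(draws$female, "female", "male"),
    education = draws$education,
    examiner_z = examiner_z,
    latent_ability = ability,
    freeze_frame_accuracy_pct = accuracy
  )
}

#' Fill cohort accuracies by playing full adaptive sessions
#'
#' The closed-loop route: each participant's latent ability is mapped
#' affinely onto respondent ability and one full session is played per
#' participant, replacing `freeze_frame_accuracy_pct` with the session's
#' per-trial accuracy and adding the raw `threshold_score` and
#' `duration_min`. The default offset and scale were calibrated by
#' Monte-Carlo so the cohort-level accuracy mean approaches the default
#' accuracy target as the cohort grows.
#'
#' @param cohort A cohort tibble with a `latent_ability` column.
#' @param aconfig The [assessment_config()] to play; per-participant session
#'   seeds are derived from `aconfig$seed`.
#' @param ability_offset,ability_scale Affine map from latent ability to
#'   respondent ability.
#' @param foil_lapse_rate Passed to [respondent_model()].
#' @return The cohort tibble with engine-derived `freeze_frame_accuracy_pct`,
#'   `threshold_score` and `duration_min`.
#' @export
simulate_cohort_sessions <- function(cohort,
                                     aconfig = assessment_config(),
                                     ability_offset = 1.72,
                                     ability_scale = 1.60,
                                     foil_lapse_rate = 0.02) {
  stopifnot(is.data.frame(cohort), "latent_ability" %in% names(cohort))
  if (anyNA(cohort$latent_ability)) {
    abort("`latent_ability` must be present for every participant.")
  }
  res <- purrr::map(seq_len(nrow(cohort)), function(i) {
    cfg <- aconfig
    cfg$seed <- derive_seed(aconfig$seed, paste0("participant-", i))
    r <- respondent_model(
      ability = ability_offset + ability_scale * cohort$latent_ability[[i]],
      foil_lapse_rate = foil_lapse_rate
    )
    s <- run_session(cfg, r)
    tibble(freeze_frame_accuracy_pct = s$mean_accuracy_pct,
           threshold_score = s$threshold_score,
           duration_min = s$estimated_duration_min)
  })
  res <- dplyr::bind_rows(res)
  cohort$freeze_frame_accuracy_pct <- res$freeze_frame_accuracy_pct
  cohort$threshold_score <- res$threshold_score
  cohort$duration_min <- res$duration_min
  cohort
}

#' Remove accuracy scores completely at random
#'
#' Each accuracy is independently set missing with probability `rate`,
#' regardless of any generated variable (MCAR); all other columns are
#' untouched.
#'
#' @param cohort A cohort tibble.
#' @param rate Missingness probability in \[0, 1\].
#' @param rng `NULL`, an integer seed, or an internal stream.
#' @return The cohort with some `freeze_frame_accuracy_pct` entries `NA`.
#' @export
apply_missingness <- function(cohort, rate = 0.13, rng = NULL) {
  stopifnot(is.data.frame(cohort),
            "freeze_frame_accuracy_pct" %in% names(cohort))
  assert_scalar_number(rate, "rate", 0, 1)
  rng <- as_rng(rng)
  drop <- rng_eval(rng, function() runif(nrow(cohort)) < rate)
  cohort$freeze_frame_accuracy_pct[drop] <- NA_real_
  cohort
}

#' Write / read a cohort table as CSV
#'
#' UTF-8, comma-separated, header row; missing accuracy is an empty field.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `path` (write) or the cohort tibble (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  cohort <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      gender = readr::col_character(),
      .default = readr::col_double()
    ),
    na = ""
  )
  required <- c("participant_id", "age", "gender", "education",
                "examiner_z", "freeze_frame_accuracy_pct")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    abort(paste0("Cohort CSV is missing required columns: ",
                 paste(missing, collapse = ", ")))
  }
  cohort
}
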