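test_that("epoch plans realize the nominal target count exactly", {
  cfg <- assessment_config()
  # 30% of 30 is exactly 9; 35% of 30 is 10.5 and rounds half-to-even to 10;
  # 25% of 30 is 7.5 and rounds to 8.
  cases <- list(c(level = 3, targets = 9),
                c(level = 2, targets = 10),
                c(level = 4, targets = 8),
                c(level = 1, targets = 12),
                c(level = 7, targets = 3))
  for (cs in cases) {
    plan <- plan_epoch(cfg, cs[["level"]], rng = 42)
    expect_equal(sum(plan$stimulus_kind == "target"), cs[["targets"]])
    expect_equal(nrow(plan), 30L)
    # realized count within 1 of frequency * trials
    expect_lt(abs(cs[["targets"]] -
                    cfg$level_ladder[cs[["level"]]] * 30), 1)
  }
  expect_error(plan_epoch(cfg, 8), "ladder")
  expect_error(plan_epoch(cfg, 0), "ladder")
})

test_that("interstimulus intervals stay within the configured bounds", {
  cfg <- assessment_config()
  isi <- unlist(lapply(1:20, function(i) plan_epoch(cfg, 3, rng = i)$isi_ms))
  expect_true(all(isi >= 500))
  expect_true(all(isi <= 1500))
  # and they vary (continuous uniform, not a constant)
  expect_gt(stats::sd(isi), 100)
})

test_that("epoch evaluation applies the inclusive pass rule on both classes", {
  # 8/9 targets withheld (0.889) and all foils hit -> pass
  e <- evaluate_epoch(make_epoch_trials(9, 8, 21, 21))
  expect_equal(e$target_withhold_accuracy, 8 / 9)
  expect_equal(e$foil_response_accuracy, 1)
  expect_true(e$passed)
  # 7/9 (0.778) fails the 80% criterion
  expect_false(evaluate_epoch(make_epoch_trials(9, 7, 21, 21))$passed)
  # exactly 80% on both classes passes (inclusive comparison)
  e80 <- evaluate_epoch(make_epoch_trials(10, 8, 20, 16))
  expect_equal(e80$target_withhold_accuracy, 0.8)
  expect_equal(e80$foil_response_accuracy, 0.8)
  expect_true(e80$passed)
  # failing either single class fails the epoch
  expect_false(evaluate_epoch(make_epoch_trials(10, 10, 20, 15))$passed)
  expect_error(evaluate_epoch(make_epoch_trials(0, 0, 20, 20)), "target")
})

test_that("the staircase moves one level and clamps at the ladder ends", {
  expect_equal(next_level(3, TRUE, 7), 4L)
  expect_equal(next_level(3, FALSE, 7), 2L)
  expect_equal(next_level(7, TRUE, 7), 7L)
  expect_equal(next_level(1, FALSE, 7), 1L)
  expect_equal(next_level(1, TRUE, 7), 2L)
  expect_error(next_level(8, TRUE, 7))
})

test_that("deterministic trajectories reach the ladder extremes", {
  cfg <- assessment_config(seed = 21)
  perfect <- run_session(cfg, deterministic_respondent(1, 1))
  expect_equal(perfect$epochs$level_index, c(3L, 4L, 5L, 6L, 7L))
  expect_equal(perfect$threshold_score, 7L)
  expect_equal(perfect$mean_accuracy_pct, 100)
  expect_equal(nrow(perfect$trials), 150L)

  responder <- run_session(cfg, deterministic_respondent(0, 1))
  expect_equal(responder$epochs$level_index, c(3L, 2L, 1L, 1L, 1L))
  expect_equal(responder$threshold_score, 1L)
})

test_that("session trajectories agree with the brute-force staircase oracle", {
  cfg <- assessment_config(seed = 33)
  fixtures <- list(
    deterministic_respondent(1, 1),
    deterministic_respondent(0, 1),
    deterministic_respondent(0.85, 0.85),
    deterministic_respondent(0.5, 1),
    respondent_model(ability = 1.2),
    respondent_model(ability = 3)
  )
  for (r in fixtures) {
    s <- run_session(cfg, r)
    oracle <- trajectory_oracle(cfg$start_level, s$epochs$passed, 7L)
    expect_equal(s$epochs$level_index, oracle$played)
    expect_equal(s$threshold_score, oracle$final)
    # trajectory stays on the ladder and moves at most one step per epoch
    expect_true(all(s$epochs$level_index >= 1 & s$epochs$level_index <= 7))
    expect_true(all(abs(diff(s$epochs$level_index)) <= 1))
  }
})

test_that("an always-passing respondent tops out as fast as the ladder allows", {
  # starting at level 5 of 7, the ceiling is reachable in 3 epochs
  cfg <- assessment_config(start_level = 5, seed = 4)
  s <- run_session(cfg, deterministic_respondent(1, 1))
  expect_equal(s$epochs$level_index, c(5L, 6L, 7L, 7L, 7L))
  n_to_top <- min(cfg$epochs_per_session, 7 - cfg$start_level + 1)
  expect_equal(s$epochs$level_index[n_to_top], 7L)
})

test_that("sessions are reproducible from the configuration seed", {
  cfg <- assessment_config(seed = 123)
  s1 <- run_session(cfg, respondent_model(ability = 2))
  s2 <- run_session(cfg, respondent_model(ability = 2))
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$threshold_score, s2$threshold_score)
  s3 <- run_session(assessment_config(seed = 124), respondent_model(ability = 2))
  expect_false(identical(s1$trials$isi_ms, s3$trials$isi_ms))
})

test_that("session accuracy is the trial-weighted mean of epoch accuracies", {
  cfg <- assessment_config(seed = 55)
  s <- run_session(cfg, respondent_model(ability = 1.5))
  expect_equal(mean_accuracy(s), s$mean_accuracy_pct)
  expect_equal(mean_accuracy(s), 100 * mean(s$trials$correct))
  per_epoch <- vapply(split(s$trials$correct, s$trials$epoch_index),
                      mean, numeric(1))
  expect_equal(s$mean_accuracy_pct, 100 * mean(per_epoch))
  expect_gt(s$estimated_duration_min, 0)
  # duration is the summed stimulus, interval and latency time
  expected_ms <- sum(500 + s$trials$isi_ms +
                       ifelse(s$trials$responded, s$trials$latency_ms, 0))
  expect_equal(s$estimated_duration_min, expected_ms / 60000)
})

test_that("session logs round-trip through JSON and are byte-stable", {
  cfg <- assessment_config(seed = 77)
  s <- run_session(cfg, respondent_model())
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_session_log(s, p1)
  write_session_log(run_session(cfg, respondent_model()), p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_session_log(p1)
  expect_equal(back$threshold_score, s$threshold_score)
  expect_equal(back$mean_accuracy_pct, s$mean_accuracy_pct)
  expect_equal(as.data.frame(back$trials), as.data.frame(s$trials))
})

test_that("tidy and glance summarize a session", {
  s <- run_session(assessment_config(seed = 8), respondent_model())
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5L)
  expect_true(all(c("epoch_index", "level_index", "passed") %in% names(td)))
  gl <- glance(s)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$threshold_score, s$threshold_score)
  expect_equal(gl$n_trials, 150L)
})
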