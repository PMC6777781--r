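test_that("outcome classification is the full 2x2 table", {
  grid <- expand.grid(state = c("reflecting", "nonreflecting"),
                      resp = c("yes", "no"), stringsAsFactors = FALSE)
  got <- classify_outcome(grid$state, grid$resp)
  expect_setequal(got, c("hit", "false_alarm", "miss", "correct_rejection"))
  expect_equal(classify_outcome("reflecting", "yes"), "hit")
  expect_equal(classify_outcome("reflecting", "no"), "miss")
  expect_equal(classify_outcome("nonreflecting", "yes"), "false_alarm")
  expect_equal(classify_outcome("nonreflecting", "no"), "correct_rejection")
  expect_error(classify_outcome("sideways", "yes"), "invalid")
  expect_error(classify_outcome("reflecting", "maybe"), "invalid")
})

test_that("step rules move, clip and snap to the rail grid", {
  cfg <- staircase_config()
  expect_equal(next_distance(1.50, "false_alarm", cfg), 1.00)
  expect_equal(next_distance(1.50, "hit", cfg), 1.75)
  expect_equal(next_distance(1.50, "miss", cfg), 1.25)
  expect_equal(next_distance(1.50, "correct_rejection", cfg), 1.50)
  # clipping at both rails
  expect_equal(next_distance(0.70, "miss", cfg), 0.70)
  expect_equal(next_distance(0.75, "false_alarm", cfg), 0.70)
  expect_equal(next_distance(3.80, "hit", cfg), 3.90)
  # off-grid distances are rejected
  expect_error(next_distance(1.502, "hit", cfg), "grid")
  expect_error(next_distance(5.0, "hit", cfg), "grid")
})

test_that("config invariants are enforced", {
  expect_error(staircase_config(step_hit = 0.2501), "multiple")
  expect_error(staircase_config(d_min = 2, d_max = 1))
  expect_error(staircase_config(start_distance = 5))
  expect_error(staircase_config(n_reversals_stop = 5, n_reversals_avg = 10))
  expect_error(staircase_config(p_reflect = 0))
})

test_that("reversal detection flips on direction change, ignores zero steps", {
  expect_equal(detect_reversals(c(1, 1, -1)), c(FALSE, FALSE, TRUE))
  expect_equal(detect_reversals(c(1, 0, 0, 1)), rep(FALSE, 4))
  expect_equal(detect_reversals(c(1, 0, -1)), c(FALSE, FALSE, TRUE))
  expect_equal(detect_reversals(c(-1, 1, -1, 1)), c(FALSE, TRUE, TRUE, TRUE))
  # property: zero steps are transparent to reversal structure
  set.seed(41)
  for (i in 1:20) {
    steps <- sample(c(-0.5, -0.25, 0, 0.25), 40, replace = TRUE)
    with_zeros <- detect_reversals(steps)
    without <- detect_reversals(steps[steps != 0])
    expect_equal(with_zeros[steps != 0], without)
    expect_false(any(with_zeros[steps == 0]))
  }
})

test_that("threshold estimator averages the trailing reversals", {
  expect_equal(threshold_from_reversals(rep(2.40, 12)), 2.40)
  expect_equal(threshold_from_reversals(rep(c(0.95, 0.70), 6)), 0.825)
  expect_equal(threshold_from_reversals(1:12), 7.5)
  expect_error(threshold_from_reversals(1:5), "only 5 reversals")
  expect_warning(th <- threshold_from_reversals(1:5, partial = TRUE),
                 "averaging")
  expect_equal(th, 3)
  expect_warning(th0 <- threshold_from_reversals(numeric(0), partial = TRUE),
                 "no reversals")
  expect_true(is.na(th0))
})

test_that("sessions stay on the grid, within bounds, and are reproducible", {
  cfg <- staircase_config()
  s1 <- run_session(random_observer(), cfg, seed = 7)
  s2 <- run_session(random_observer(), cfg, seed = 7)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$threshold, s2$threshold)
  d <- s1$trials$distance
  expect_true(all(d >= cfg$d_min - 1e-12 & d <= cfg$d_max + 1e-12))
  on_grid <- (d - cfg$d_min) / cfg$grid_step
  expect_equal(on_grid, round(on_grid))
  expect_true(s1$stopped_normally)
  expect_length(s1$reversal_distances, cfg$n_reversals_stop)
  expect_equal(s1$threshold,
               mean(utils::tail(s1$reversal_distances, cfg$n_reversals_avg)))
  # reversal flags agree with the offline detector on the intended steps
  expect_equal(s1$trials$is_reversal, detect_reversals(s1$trials$step_m))
})

test_that("expected drift of a coin-flip responder is -0.125 m per trial", {
  # away from the rails each outcome is equally likely, so the mean intended
  # step is (0.25 - 0.25 + 0 - 0.50) / 4
  set.seed(5)
  n <- 200000
  state <- ifelse(runif(n) < 0.5, "reflecting", "nonreflecting")
  resp <- ifelse(runif(n) < 0.5, "yes", "no")
  steps <- staircase_config()$steps_m[classify_outcome(state, resp)]
  se <- sd(steps) / sqrt(n)
  expect_lt(abs(mean(steps) - (-0.125)), 3 * se)
})

test_that("degenerate observers hit the trial cap with sensible fallbacks", {
  cfg <- staircase_config(max_trials = 300L)
  # an observer that is always correct marches to the far rail and stays
  ideal <- sdt_observer(50, ref_distance = 0.7, decay_per_m = 0)
  expect_warning(s <- run_session(ideal, cfg, seed = 1), "cap")
  expect_false(s$stopped_normally)
  expect_lte(abs(s$threshold - cfg$d_max), 0.25)
  # an observer that never says yes never reverses and pins the near rail
  mute <- random_observer(p_yes = 0)
  expect_warning(s2 <- run_session(mute, cfg, seed = 1), "cap")
  expect_false(s2$stopped_normally)
  expect_length(s2$reversal_distances, 0)
  expect_equal(s2$threshold, cfg$d_min)
  expect_equal(unique(s2$trials$distance), cfg$d_min)
})
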