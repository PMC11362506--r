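# The transformed up-down state machine: stepping, reversals, phases,
# termination, and reversal-based threshold estimators.

test_that("hand-traced two-down/one-up track steps and logs reversals correctly", {
  cfg <- staircase_config(2, phases = list(c(6, 2)), start_delta = 100,
                          reversal_threshold_k = 4)
  tr <- new_track(cfg)
  tr <- update_track(tr, cfg, TRUE); tr <- update_track(tr, cfg, TRUE)
  expect_equal(tr$delta, 50)                       # first down step
  expect_length(tr$reversal_delta, 0)              # initial direction: none
  tr <- update_track(tr, cfg, TRUE); tr <- update_track(tr, cfg, TRUE)
  expect_equal(tr$delta, 25)
  tr <- update_track(tr, cfg, FALSE)               # up step: direction change
  expect_equal(tr$delta, 50)
  expect_equal(tr$reversal_trial, 5L)
  expect_equal(tr$reversal_delta, 25)              # pre-step delta is logged
  tr <- update_track(tr, cfg, TRUE); tr <- update_track(tr, cfg, TRUE)
  expect_equal(tr$delta, 25)
  expect_equal(tr$reversal_trial, c(5L, 7L))
  expect_equal(tr$reversal_delta, c(25, 50))
})

test_that("an alternating +-+-+- string produces only up steps and no reversal", {
  cfg <- staircase_config(2, phases = list(c(6, 2)), start_delta = 100,
                          reversal_threshold_k = 4)
  tr <- drive_track(c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE), cfg)
  expect_length(tr$reversal_delta, 0)
  expect_equal(tr$delta, 800)          # 100 -> 200 -> 400 -> 800
})

test_that("updating a finished track is a usage error", {
  cfg <- staircase_config(1, phases = list(c(2, 2)), start_delta = 10,
                          reversal_threshold_k = 2)
  tr <- drive_track(c(TRUE, FALSE, TRUE), cfg)   # down, up(rev), down(rev 2)
  expect_true(tr$finished)
  expect_error(update_track(tr, cfg, TRUE), "finished")
})

test_that("no step is applied after the final reversal is recorded", {
  cfg <- staircase_config(1, phases = list(c(2, 2)), start_delta = 10,
                          reversal_threshold_k = 2)
  tr <- drive_track(c(TRUE, FALSE, TRUE), cfg)
  expect_equal(tr$reversal_delta, c(5, 10))
  expect_equal(tr$delta, 10)           # delta frozen at the terminal reversal
})

test_that("the factor in force follows the phase of the next reversal", {
  cfg <- staircase_config(2, start_delta = 100)  # phases (4, 2), (8, sqrt(2))
  tr <- new_track(cfg)
  expect_equal(current_factor(tr, cfg), 2)
  tr$reversal_delta <- c(50, 100, 50, 100); tr$reversal_trial <- 1:4
  expect_equal(current_factor(tr, cfg), sqrt(2))
  cfg1 <- staircase_config(2, phases = list(c(6, 2)), start_delta = 100,
                           reversal_threshold_k = 4)
  tr1 <- new_track(cfg1)
  tr1$reversal_delta <- c(1, 2, 3, 4, 5); tr1$reversal_trial <- 1:5
  expect_equal(current_factor(tr1, cfg1), 2)
})

test_that("phase switch applies from the trial after the boundary reversal", {
  # drive a 2-down/1-up track with phases (1, 2), (2, sqrt(2)) through its
  # first reversal; the up step recording reversal 1 still multiplies by 2,
  # the next up step multiplies by sqrt(2)
  cfg <- staircase_config(2, phases = list(c(1, 2), c(2, sqrt(2))),
                          start_delta = 100, reversal_threshold_k = 2)
  tr <- drive_track(c(TRUE, TRUE, FALSE, FALSE), cfg)
  # trial 2: down to 50; trial 3: up (reversal 1 at 50) with factor 2 -> 100
  # trial 4: up, same direction, factor sqrt(2) -> 141.42
  expect_equal(tr$reversal_delta, 50)
  expect_equal(tr$delta, 100 * sqrt(2))
})

test_that("engine matches the brute-force enumerator on random response strings", {
  set.seed(4711)
  phase_sets <- list(list(c(4, 2), c(8, sqrt(2))),
                     list(c(2, 2), c(4, sqrt(2))),
                     list(c(6, 2)),
                     list(c(3, 3), c(3, 1.5), c(3, 1.2)))
  for (i in 1:1000) {
    n_down <- sample(1:3, 1)
    phases <- phase_sets[[sample(length(phase_sets), 1)]]
    len <- sample(10:60, 1)
    responses <- stats::runif(len) < 0.65
    cfg <- suppressWarnings(staircase_config(
      n_down, phases, start_delta = 100,
      reversal_threshold_k = 1L, max_trials = 200L))
    tr <- drive_track(responses, cfg)
    or <- oracle_staircase(responses, n_down,
                           vapply(phases, `[`, numeric(1), 1),
                           vapply(phases, `[`, numeric(1), 2),
                           100, max_trials = 200L)
    expect_identical(tr$reversal_trial, or$reversal_trial)
    expect_equal(tr$reversal_delta, or$reversal_delta)
    expect_equal(tr$delta, or$final_delta)
  }
})

test_that("consecutive deltas differ exactly by the factor in force", {
  set.seed(99)
  cfg <- staircase_config(2, start_delta = 100, delta_min = 1e-6,
                          delta_max = 1e6)
  tr <- new_track(cfg)
  while (!tr$finished) {
    fac <- current_factor(tr, cfg)
    before <- tr$delta
    tr <- update_track(tr, cfg, stats::runif(1) < 0.6)
    ratio <- tr$delta / before
    expect_true(any(abs(ratio - c(1, fac, 1 / fac)) < 1e-12))
  }
})

test_that("delta is clamped at the bounds and never exceeds them", {
  cfg <- staircase_config(2, phases = list(c(4, 2)), start_delta = 100,
                          reversal_threshold_k = 2, delta_min = 50,
                          delta_max = 400, max_trials = 40L)
  tr <- new_track(cfg)
  for (i in 1:40) {                      # all wrong: delta rises and pins
    if (tr$finished) break
    tr <- update_track(tr, cfg, FALSE)
    expect_lte(tr$delta, 400)
    expect_gte(tr$delta, 50)
  }
  expect_equal(tr$delta, 400)
  expect_gt(tr$n_clamped, 0)
})

test_that("threshold_last_k averages the final reversals", {
  est <- threshold_last_k(c(40, 20, 40, 20, 40, 20, 40, 20), k = 8)
  expect_equal(est$value, 30)
  expect_equal(est$method, "last_k_mean")
  est <- threshold_last_k(c(10, 40, 10, 40), k = 4, mean_type = "geometric")
  expect_equal(est$value, 20)
  est <- threshold_last_k(c(100, 50, 25, 40, 20, 40, 20, 40, 20, 40, 20, 40),
                          k = 6)
  expect_equal(est$value, 30)
  expect_warning(threshold_last_k(c(1, 2, 3), k = 3), "even number")
  expect_error(threshold_last_k(c(1, 2), k = 4), "insufficient")
})

test_that("threshold_midpoint_runs averages midpoints of bounding reversals", {
  expect_equal(threshold_midpoint_runs(c(20, 40, 20, 40), 4)$value, 30)
  expect_equal(threshold_midpoint_runs(c(10, 30), 2)$value, 20)
  expect_equal(threshold_midpoint_runs(c(16, 32, 8, 24), 4)$value, 20)
  expect_error(threshold_midpoint_runs(c(1, 2, 3), 3), "even")
})

test_that("geometric mean never exceeds the arithmetic mean (AM-GM)", {
  set.seed(12)
  for (i in 1:50) {
    revs <- stats::rlnorm(8, log(20), 0.5)
    a <- threshold_last_k(revs, 8)$value
    g <- threshold_last_k(revs, 8, mean_type = "geometric")$value
    expect_lte(g, a + 1e-12)
  }
})

test_that("equilibrium probabilities solve p^n = 1/2", {
  for (n in 1:6)
    expect_equal(equilibrium_probability(n)^n, 0.5, tolerance = 1e-12)
  expect_equal(round(equilibrium_probability(2), 4), 0.7071)
  expect_equal(round(equilibrium_probability(3), 4), 0.7937)
  expect_equal(round(equilibrium_probability(4), 4), 0.8409)
  expect_equal(equilibrium_probability(1), 0.5)
  expect_error(equilibrium_probability(0), "n_down")
})

test_that("hitting the trial cap yields an incomplete threshold, not an error", {
  cfg <- staircase_config(2, phases = list(c(4, 2), c(8, sqrt(2))),
                          start_delta = 100, max_trials = 8L)
  set.seed(3)
  tr <- drive_track(stats::runif(8) < 0.6, cfg)
  expect_true(tr$finished)
  expect_lt(length(tr$reversal_delta), 12)
  expect_warning(est <- track_threshold(tr, cfg), "trial cap")
  expect_false(est$complete)
})

test_that("configuration invariants are enforced", {
  expect_error(staircase_config(2, list(c(4, 1)), 100), "factor")
  expect_error(staircase_config(2, list(c(4, 2)), 100,
                                reversal_threshold_k = 5), "between 1 and")
  expect_error(staircase_config(2, list(c(4, 2)), 100, delta_min = 200,
                                reversal_threshold_k = 4), "within")
  expect_warning(staircase_config(2, list(c(4, 2)), 100,
                                  reversal_threshold_k = 3), "even")
  expect_equal(staircase_config("3d1u", start_delta = 10)$n_down, 3L)
})
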