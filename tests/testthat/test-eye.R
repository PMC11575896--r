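eye_session <- function(nt = 200, rate_run = 2.653, rate_stat = 2.525,
                        mag_run = 9.261, mag_stat = 8.337,
                        pupil_gain = 1.08, seed = 1, duration = 0.833) {
  set.seed(seed)
  run <- rep(c(TRUE, FALSE), length.out = nt)
  onsets <- seq(1, by = duration + 0.5, length.out = nt)
  win_len <- duration + 0.3
  st <- numeric(0); sm <- numeric(0)
  for (t in seq_len(nt)) {
    k <- rpois(1, ifelse(run[t], rate_run, rate_stat) * win_len)
    if (k > 0) {
      st <- c(st, sort(runif(k, onsets[t] - 0.2, onsets[t] + duration + 0.1)))
      sm <- c(sm, rgamma(k, 9, scale = ifelse(run[t], mag_run, mag_stat) / 9))
    }
  }
  session_data(session_id = "eye", species = "synthetic",
               counts = matrix(rpois(nt * 3, 4), nt, 3),
               duration = rep(duration, nt),
               orientation = rep_len(1:12, nt), spatial_freq = rep_len(1:3, nt),
               drift_speed = rep_len(1:2, nt),
               running_speed = ifelse(run, 10, 0),
               trial_onsets = onsets, trial_offsets = onsets + duration,
               saccade_times = st, saccade_magnitudes = sm,
               pupil = 1000 * ifelse(run, pupil_gain, 1) * (1 + 0.02 * rnorm(nt)))
}

test_that("saccades are counted in the perimstimulus window", {
  onsets <- c(1, 10)
  s <- session_data(session_id = "w", species = "synthetic",
                    counts = matrix(0L, 2, 1), duration = rep(0.833, 2),
                    orientation = 1:2, spatial_freq = c(1L, 1L),
                    drift_speed = c(1L, 1L), running_speed = c(0, 0),
                    trial_onsets = onsets, trial_offsets = onsets + 0.833,
                    saccade_times = c(1 - 0.1, 1.833 + 0.2),
                    saccade_magnitudes = c(5, 5))
  f <- eye_features(s)
  expect_equal(f$n_saccades, c(1L, 0L))   # -0.1 s before onset counted; +0.2 s after offset not
  expect_true(is.nan(f$mean_magnitude[2]))
  expect_equal(f$window_length[1], 0.833 + 0.3)
})

test_that("missing eye data is reported, not an error", {
  s <- make_test_session(matrix(0L, 30, 1))
  f <- eye_features(s)
  expect_true(f$eye_absent)
  expect_error(eye_state_comparison(f, split_by_running(s)), "absent")
})

test_that("state comparison recovers generative saccade statistics", {
  s <- eye_session(nt = 2000, seed = 5)
  lab <- split_by_running(s)
  f <- eye_features(s, lab)
  cmp <- eye_state_comparison(f, lab, n_boot = 500, seed = 2)
  run_rate <- cmp$mean_running[cmp$measure == "saccade_rate"]
  stat_rate <- cmp$mean_stationary[cmp$measure == "saccade_rate"]
  n <- 1000; win <- 1.133
  se <- sqrt(2.653 / (n * win))   # Poisson SE of a rate estimate
  expect_lt(abs(run_rate - 2.653), 3 * se)
  expect_lt(abs(stat_rate - 2.525), 3 * se)
  expect_gt(cmp$mean_running[cmp$measure == "saccade_magnitude"],
            cmp$mean_stationary[cmp$measure == "saccade_magnitude"])
  # pupil ~8% larger during running
  pup <- cmp$rel_diff_pct[cmp$measure == "pupil"]
  expect_gt(pup, 6); expect_lt(pup, 10)
})

test_that("pupil is normalized to the stationary mean", {
  s <- eye_session(nt = 400, pupil_gain = 1.2, seed = 7)
  lab <- split_by_running(s)
  f <- eye_features(s, lab)
  expect_equal(mean(f$pupil[lab$label == "stationary"]), 100)
})

test_that("matched eye statistics rarely exclude zero difference", {
  hits <- 0
  for (k in 1:200) {
    s <- eye_session(nt = 200, rate_run = 2.5, rate_stat = 2.5,
                     mag_run = 8, mag_stat = 8, pupil_gain = 1, seed = 1000 + k)
    lab <- split_by_running(s)
    cmp <- eye_state_comparison(eye_features(s, lab), lab, n_boot = 500,
                                seed = k)
    row <- cmp[cmp$measure == "pupil", ]
    if (row$rel_diff_ci_low <= 0 && row$rel_diff_ci_high >= 0) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.93)
})

test_that("deterministic saccade-driven rates reproduce the injected effect", {
  s <- eye_session(nt = 400, seed = 9)
  lab <- split_by_running(s)
  f <- eye_features(s, lab)
  rates <- matrix(1.0 * f$n_saccades, ncol = 1)[, c(1, 1)]
  pred <- saccade_rate_prediction(rates, f, lab)
  run <- lab$label == "running"; stat <- lab$label == "stationary"
  delta_count <- mean(f$n_saccades[run]) - mean(f$n_saccades[stat])
  expect_equal(pred$predicted_change_hz, 1.0 * delta_count, tolerance = 1e-10)
  # swapping the labels negates the prediction exactly
  swapped <- lab
  swapped$label <- factor(
    c(running = "stationary", stationary = "running",
      ambiguous = "ambiguous")[as.character(lab$label)], levels(lab$label))
  pred2 <- saccade_rate_prediction(rates, f, swapped)
  expect_equal(pred2$predicted_change_hz, -pred$predicted_change_hz,
               tolerance = 1e-10)
})

test_that("saccade-independent activity predicts no change", {
  set.seed(61)
  preds <- replicate(50, {
    s <- eye_session(nt = 300, seed = sample.int(1e6, 1))
    lab <- split_by_running(s)
    f <- eye_features(s, lab)
    rates <- matrix(rpois(300 * 5, 5), 300, 5)
    saccade_rate_prediction(rates, f, lab)$predicted_change_hz
  })
  expect_lt(abs(mean(preds)), 2 * sd(preds) / sqrt(50))
})

test_that("collinear magnitude regressors are dropped with a flag", {
  s <- eye_session(nt = 200, seed = 13)
  lab <- split_by_running(s)
  f <- eye_features(s, lab)
  f$n_saccades <- pmax(f$n_saccades, 1L)      # every trial has a saccade...
  f$mean_magnitude <- rep(5, 200)             # ...of identical magnitude
  pred <- saccade_rate_prediction(matrix(rpois(400, 4), 200, 2), f, lab)
  expect_true(pred$magnitude_dropped)
})
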