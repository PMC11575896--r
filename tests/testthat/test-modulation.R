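test_that("running labels use hysteresis thresholds with a dead zone", {
  s <- make_test_session(matrix(0L, 4, 1), running_speed = c(0, 0.5, 10, 2))
  lab <- split_by_running(s)
  expect_equal(as.character(lab$label),
               c("stationary", "stationary", "running", "ambiguous"))
  expect_error(split_by_running(s, threshold_run = -1), "negative")
  expect_error(split_by_running(s, threshold_run = 1, threshold_stat = 3),
               "exceed")
})

test_that("labels recover the generative running fraction", {
  g <- generate_session(sim_config(n_trials = 800, run_fraction = 0.5, seed = 17))
  lab <- split_by_running(g$session)
  truth_frac <- mean(g$truth$running_label_true)
  est_frac <- mean(lab$label == "running")
  expect_lt(abs(est_frac - truth_frac), 0.1)
})

test_that("noiseless doubling gives ratio 2 and a significant increase", {
  nt <- 100
  run_speed <- rep(c(10, 0), each = nt / 2)
  cnt <- matrix(rep(c(8L, 4L), each = nt / 2), ncol = 1)
  s <- make_test_session(cnt, running_speed = run_speed)
  lab <- split_by_running(s)
  m <- unit_modulation(s, trial_rates(s), lab, n_boot = 500, seed = 2)
  expect_equal(m$ratio, 2)
  expect_true(m$significant_increase)
  expect_false(m$significant_decrease)
})

test_that("swapping the state labels inverts ratios exactly", {
  g <- generate_session(sim_config(n_units = 10, n_trials = 400, gain_sd = 1.5,
                                   seed = 23))
  s <- g$session
  lab <- split_by_running(s)
  swapped <- lab
  swapped$label <- factor(
    c(running = "stationary", stationary = "running",
      ambiguous = "ambiguous")[as.character(lab$label)],
    levels(lab$label))
  m1 <- unit_modulation(s, trial_rates(s), lab, n_boot = 200, seed = 3)
  m2 <- unit_modulation(s, trial_rates(s), swapped, n_boot = 200, seed = 3)
  ok <- !m1$skipped & !m1$floored
  expect_equal(m2$ratio[ok], 1 / m1$ratio[ok], tolerance = 1e-12)
  a1 <- aggregate_modulation(m1, n_boot = 200, seed = 4)
  a2 <- aggregate_modulation(m2, n_boot = 200, seed = 4)
  if (all(!m1$floored[!m1$skipped]))
    expect_equal(a2$geometric_mean, 1 / a1$geometric_mean, tolerance = 1e-12)
})

test_that("aggregate geometric mean follows closed forms", {
  mk <- function(ratios) {
    data.frame(unit_id = seq_along(ratios), ratio = ratios, skipped = FALSE,
               significant_increase = FALSE, significant_decrease = FALSE)
  }
  expect_equal(aggregate_modulation(mk(c(2, 0.5)), n_boot = 200, seed = 1)$geometric_mean, 1)
  a1 <- aggregate_modulation(mk(rep(1, 20)), n_boot = 200, seed = 1)
  expect_equal(c(a1$ci_low, a1$ci_high), c(1, 1))
  expect_error(aggregate_modulation(mk(1)[0, ]), "no units")
  # lognormal population: geometric mean and bootstrap CI vs analytic SE
  set.seed(44)
  ratios <- exp(rnorm(500, log(1.5), 0.2))
  a <- aggregate_modulation(mk(ratios), n_boot = 2000, seed = 5)
  expect_gt(a$geometric_mean, 1.45); expect_lt(a$geometric_mean, 1.55)
  analytic_width <- 2 * 1.96 * 0.2 / sqrt(500) * a$geometric_mean
  expect_lt(abs(log(a$ci_high / a$ci_low) * a$geometric_mean - analytic_width) /
              analytic_width, 0.2)
})

test_that("matched rate distributions are rarely called significant", {
  set.seed(47)
  hits <- 0
  for (k in 1:200) {
    x <- rpois(200, 4)
    s <- make_test_session(matrix(x, ncol = 1),
                           running_speed = rep(c(10, 0), each = 100))
    m <- unit_modulation(s, trial_rates(s), split_by_running(s),
                         n_boot = 500, seed = k)
    if (m$significant_increase || m$significant_decrease) hits <- hits + 1
  }
  expect_lte(hits / 200, 0.07)
})

test_that("gain-coupled populations show mostly significant increases", {
  g <- generate_session(sim_config(n_units = 30, n_trials = 500, gain_sd = 2,
                                   gain_running_coupling = 1, seed = 29))
  s <- g$session
  m <- unit_modulation(s, trial_rates(s), split_by_running(s), n_boot = 1000,
                       seed = 6)
  ok <- !m$skipped
  expect_gt(mean(m$significant_increase[ok]), 0.5)
})
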