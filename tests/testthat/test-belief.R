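test_that("visit_series validates dates and counts", {
  s <- toy_series(c(10, 12, 9))
  expect_s3_class(s, "visit_series")
  expect_equal(nrow(s), 3)
  expect_error(visit_series(as.Date(c("2020-01-01", "2020-01-03")), c(1, 2)),
               "consecutive")
  expect_error(toy_series(c(1, -2)), "non-negative")
  expect_error(toy_series(c(1.5, 2)), "integers")
})

test_that("the balance equation is a convex combination with a fixed point", {
  expect_equal(update_belief(0.5, 0.2, 1), 0.6)
  expect_equal(update_belief(0.5, 0.2, 0), 0.4)
  for (p in c(0, 0.25, 0.7, 1)) {
    expect_equal(update_belief(p, 0.3, p), p) # signal = p leaves p unchanged
  }
  expect_error(update_belief(1.2, 0.2, 1), "p_prev")
  expect_error(update_belief(0.5, 0, 1), "learning_rate")
  expect_error(update_belief(0.5, 0.2, 2), "signal")
})

test_that("observation signals implement the three window rules", {
  expect_equal(observation_signal(c(1200, 1300), 1250, "fraction"), 0.5)
  expect_equal(observation_signal(c(1200, 1300), 1250, "all"), 0)
  expect_equal(observation_signal(c(1200, 1300), 1250, "mean"), 1)
  for (rule in c("fraction", "all", "mean")) {
    expect_equal(observation_signal(1000, 1250, rule), 1)
  }
  # weak inequality: a count equal to the threshold is favourable
  expect_equal(observation_signal(1250, 1250, "fraction"), 1)
  expect_error(observation_signal(numeric(0), 10), "non-empty")
})

test_that("belief bounds bracket the update and match the closed form", {
  expect_equal(belief_bounds(0.5, 0.2, 1), c(lower = 0.5, upper = 0.5))
  expect_equal(belief_bounds(0.5, 0.2, 3), c(lower = 0.32, upper = 0.68))
  expect_equal(unname(belief_bounds(1, 0.7, 9)["upper"]), 1)
  expect_error(belief_bounds(0.5, 0.2, 0), "positive")
})

test_that("constant series attain the analytic envelope exactly", {
  params <- belief_params(threshold = 100, learning_rate = 0.2,
                          initial_p = 0.5, window_days = 1)
  below <- run_belief_trajectory(toy_series(rep(90, 10)), params)
  expect_equal(below$p, 1 - 0.8^(1:10) * 0.5)
  above <- run_belief_trajectory(toy_series(rep(110, 10)), params)
  expect_equal(above$p, 0.8^(1:10) * 0.5)
})

test_that("alternating favourable/unfavourable days settle near one half", {
  counts <- rep(c(90, 110), 200)
  params <- belief_params(threshold = 100, learning_rate = 0.2,
                          initial_p = 0.5, window_days = 1)
  traj <- run_belief_trajectory(toy_series(counts), params)
  expect_lt(abs(mean(traj$p) - 0.5), 0.02)
})

test_that("every trajectory stays inside its analytic envelope", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(20:60, 1)
    counts <- rpois(n, 100)
    params <- belief_params(threshold = sample(80:120, 1),
                            learning_rate = runif(1, 0.05, 1),
                            initial_p = runif(1),
                            window_days = sample(1:7, 1),
                            signal_rule = sample(c("fraction", "all", "mean"), 1))
    traj <- run_belief_trajectory(toy_series(counts), params)
    # the prior sits at day 0, so day t corresponds to envelope index t + 1
    b <- belief_bounds(params$initial_p, params$learning_rate, seq_len(n) + 1L)
    expect_true(all(traj$p >= b[, "lower"] - 1e-12))
    expect_true(all(traj$p <= b[, "upper"] + 1e-12))
    expect_true(all(traj$p >= 0 & traj$p <= 1))
  }
})

test_that("two priors under identical signals differ by the decayed prior gap", {
  counts <- rpois(50, 100)
  base <- belief_params(threshold = 100, learning_rate = 0.25, initial_p = 0.2,
                        window_days = 3)
  alt <- base; alt$initial_p <- 0.9
  t1 <- run_belief_trajectory(toy_series(counts), base)
  t2 <- run_belief_trajectory(toy_series(counts), alt)
  gap <- (0.9 - 0.2) * (1 - 0.25)^(1:50)
  expect_equal(t2$p - t1$p, gap, tolerance = 1e-12)
})

test_that("learning-rate limits: omega = 1 is memoryless, omega -> 0 freezes", {
  counts <- rpois(30, 100)
  memoryless <- belief_params(threshold = 100, learning_rate = 1,
                              initial_p = 0.3, window_days = 1)
  traj <- run_belief_trajectory(toy_series(counts), memoryless)
  expect_equal(traj$p, traj$signal)
  frozen <- belief_params(threshold = 100, learning_rate = 1e-9,
                          initial_p = 0.3, window_days = 1)
  traj0 <- run_belief_trajectory(toy_series(counts), frozen)
  expect_true(all(abs(traj0$p - 0.3) < 1e-6))
})

test_that("trajectory summaries count strict exceedances of one half", {
  params <- belief_params(threshold = 100, initial_p = 0.5, window_days = 1)
  traj <- run_belief_trajectory(toy_series(rep(90, 10)), params)
  s <- summarize_trajectory(traj)
  expect_equal(s$days_above_half, 10) # p1 = 0.6 already above 0.5
  expect_equal(s$fraction_above_half, 1)
  # exactly 0.5 never counts
  traj$p <- rep(0.5, 10)
  expect_equal(summarize_trajectory(traj)$days_above_half, 0)
})

test_that("monthly summary averages daily beliefs within calendar months", {
  dates <- seq(as.Date("2020-01-01"), as.Date("2020-02-29"), by = "day")
  s <- visit_series(dates, rep(10, length(dates)))
  params <- belief_params(threshold = 100, window_days = 1)
  traj <- run_belief_trajectory(s, params)
  traj$p <- c(rep(0.3, 31), rep(0.7, 29))
  m <- monthly_summary(traj)
  expect_equal(m$mean_p, c(0.3, 0.7))
  traj$p <- rep(1, 60)
  expect_equal(monthly_summary(traj)$mean_p, c(1, 1))
})

test_that("emergency analysis commits the prior and thresholds at the annual mean", {
  s <- toy_series(rep(150, 366))
  m <- emergency_analysis(s)
  expect_equal(attr(m, "threshold"), 150)
  # constant series at the mean: always favourable, monthly means climb to 1
  expect_true(all(diff(m$mean_p) >= -1e-12))
  expect_gt(m$mean_p[12], 0.999)

  # forced always-unfavourable: threshold fit to the mean, counts above it
  s2 <- toy_series(rep(c(100, 200), 183))
  params <- belief_params(threshold = 99, initial_p = 1, window_days = 1)
  traj <- run_belief_trajectory(s2, params)
  mm <- monthly_summary(traj)
  expect_true(all(diff(mm$mean_p) <= 1e-12))
  expect_lt(mm$mean_p[12], 0.01)

  em <- generate_emergency_series(seed = 7)
  m3 <- emergency_analysis(em)
  expect_true(all(m3$mean_p >= 0 & m3$mean_p <= 1))
})
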