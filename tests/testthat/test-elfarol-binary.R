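test_that("game_spec validates its fields and derives the indifference level", {
  g <- game_spec(4, 2, gain = 3, loss = 1)
  expect_equal(g$indifference, 0.75)
  expect_equal(indifference_threshold(g), 0.75)
  expect_equal(indifference_threshold(1, 1), 0.5)
  expect_equal(indifference_threshold(0.5, 1.5), 0.25)
  expect_error(game_spec(4, 0, 1, 1), "capacity")
  expect_error(game_spec(4, 4, 1, 1), "capacity") # c <= N-1 in the binary game
  expect_error(game_spec(4, 2, -1, 1), "gain")
  expect_error(game_spec(4, 2, 1, 0), "loss")
  expect_error(game_spec(4, 2, 1, 1, weights = c(1, -1, 1, 1)), "positive")
})

test_that("payoff_value follows the capacity rule and the action-zero rule", {
  g <- game_spec(6, 3, gain = 2, loss = 1)
  expect_equal(payoff_value(1, 0, 100, g), 0)
  expect_equal(payoff_value(1, 1, g$capacity, g), 2)
  expect_equal(payoff_value(1, 1, g$capacity + 1, g), -1)
  gw <- game_spec(3, 2, gain = 2, loss = 1, weights = c(1, 0.5, 2))
  expect_equal(payoff_value(3, 1, 2, gw), 4)
  expect_equal(payoff_value(2, 1, 3, gw), -0.5)
  expect_error(payoff_value(1, 2, 2, g), "out of range")
})

test_that("Poisson-binomial DP tail matches examples and full enumeration", {
  expect_equal(tail_probability(c(0.5, 0.5, 0.5), 2), 0.5)
  expect_equal(tail_probability(c(1, 1), 2), 1)
  expect_equal(tail_probability(c(0, 0, 0), 1), 0)
  expect_equal(tail_probability(numeric(0), 0), 1)
  expect_error(tail_probability(c(0.5, 1.2), 1), "\\[0, 1\\]")

  set.seed(11)
  for (rep in 1:40) {
    m <- sample(1:10, 1)
    b <- runif(m)
    thr <- sample(0:(m + 1), 1)
    expect_equal(tail_probability(b, thr), enum_tail(b, thr),
                 tolerance = 1e-12)
  }
})

test_that("expected payoff of attending matches H - (H+L) * tail", {
  g <- game_spec(4, 2, gain = 1, loss = 1)
  expect_equal(expected_payoff_binary(c(0.5, 0.5, 0.5), g), 0)
  expect_equal(expected_payoff_binary(c(0, 0, 0), g), g$gain)
  expect_equal(expected_payoff_binary(c(1, 1, 1), g), -g$loss)
  expect_error(expected_payoff_binary(c(0.5, 0.5), g), "length")
})

test_that("expected payoff of attending strictly decreases in each opponent belief", {
  g <- game_spec(5, 3, gain = 1.3, loss = 0.7)
  base <- c(0.2, 0.5, 0.8, 0.4)
  for (i in seq_along(base)) {
    lo <- hi <- base
    lo[i] <- 0.1; hi[i] <- 0.9
    expect_gt(expected_payoff_binary(lo, g), expected_payoff_binary(hi, g))
  }
})

test_that("best response attends on ties and defects under saturation", {
  g <- game_spec(4, 2, gain = 1, loss = 1) # u = 0.5
  # beliefs (0.5, 0.5, 0.5) give tail exactly 0.5 = u: tie goes to attending
  expect_identical(best_response_binary(c(0.5, 0.5, 0.5), g), 1L)
  expect_identical(best_response_binary(c(1, 1, 1), g), 0L)
  expect_identical(best_response_binary(c(0, 0, 0), g), 1L)
})

test_that("fictitious play follows the balance equation and stays in [0,1]", {
  g <- game_spec(3, 1, gain = 1, loss = 1)
  traj <- fictitious_play_binary(g, horizon = 1, init = c(0, 0, 0))
  # everyone best-responds to an empty bar in one step
  expect_equal(unname(traj[2, ]), c(1, 1, 1))

  g2 <- game_spec(2, 1, gain = 1, loss = 2)
  traj2 <- fictitious_play_binary(g2, horizon = 300, init = c(0.7, 0.2))
  expect_true(all(traj2 >= 0 & traj2 <= 1))
  expect_error(fictitious_play_binary(g2, horizon = 0, init = c(0, 0)), "horizon")
})

test_that("long-run fictitious play sorts players into c attendees", {
  g <- game_spec(4, 2, gain = 1, loss = 1)
  traj <- fictitious_play_binary(g, horizon = 10000,
                                 init = c(0.2, 0.4, 0.6, 0.8))
  final <- traj[nrow(traj), ]
  rounded <- round(final)
  expect_true(all(abs(final - rounded) < 0.05))
  expect_equal(sum(rounded), g$capacity)
})

test_that("pure Nash profiles are exactly those with c attendees", {
  cases <- list(c(4, 2), c(2, 1), c(3, 2))
  for (cs in cases) {
    g <- game_spec(cs[1], cs[2], gain = 1, loss = 1)
    eq <- enumerate_pure_nash_binary(g)
    expect_equal(nrow(eq), choose(cs[1], cs[2]))
    expect_true(all(rowSums(eq) == cs[2]))
  }
  # independent brute-force oracle with asymmetric payoffs
  oracle <- brute_nash_binary(5, 3, H = 2, L = 0.5)
  mine <- enumerate_pure_nash_binary(game_spec(5, 3, gain = 2, loss = 0.5))
  expect_equal(mine[order(apply(mine, 1, paste, collapse = "")), ],
               oracle[order(apply(oracle, 1, paste, collapse = "")), ],
               ignore_attr = TRUE)
  expect_error(enumerate_pure_nash_binary(game_spec(21, 5, 1, 1)), "<= 20")
})

test_that("convergence flag requires a long flat tail", {
  flat <- matrix(0.5, 200, 2)
  expect_true(has_converged(flat))
  expect_false(has_converged(flat[1:50, ]))
  moving <- cbind(seq(0, 1, length.out = 200), 0.5)
  expect_false(has_converged(moving))
})

test_that("pharmacy game matrix is additive with a zero outside option", {
  m <- pharmacy_game_matrix(2, 1)
  expect_equal(m["no", "no"], 0)
  expect_equal(m["no", "yes"], 1)
  expect_equal(m["yes", "no"], 2)
  expect_equal(m["yes", "yes"], 3)
  expect_equal(unname(pharmacy_game_matrix(0, 0)), matrix(0, 2, 2),
               ignore_attr = TRUE)
  m2 <- pharmacy_game_matrix(1.135, 0.2)
  expect_equal(m2["yes", "yes"], 1.335)
  expect_equal(m2["yes", "yes"], m2["yes", "no"] + m2["no", "yes"])
})
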