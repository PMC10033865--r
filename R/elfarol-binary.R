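#' Poisson-binomial tail probability of attendance
#'
#' Probability that at least \code{threshold} of a set of independent
#' attenders show up, where attender \code{k} attends with probability
#' \code{beliefs[k]}. This is the upper tail of a Poisson-binomial
#' distribution, computed by exact dynamic-programming convolution (cost
#' O(m^2) for m beliefs), equivalent to enumerating all 2^m attendance
#' subsets.
#'
#' @param beliefs Numeric vector of attendance probabilities in [0, 1].
#' @param threshold Integer c >= 0.
#' @return P(number of attendees >= threshold).
#' @examples
#' tail_probability(c(0.5, 0.5, 0.5), 2) # 0.5
#' @export
tail_probability <- function(beliefs, threshold) {
  if (length(beliefs) == 0L) beliefs <- numeric(0)
  if (any(is.na(beliefs)) || any(beliefs < 0) || any(beliefs > 1))
    stop("all beliefs must lie in [0, 1]", call. = FALSE)
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 0L)
    stop("`threshold` must be a non-negative integer", call. = FALSE)
  if (threshold == 0L) return(1)
  m <- length(beliefs)
  if (threshold > m) return(0)
  # pmf[j + 1] = P(exactly j of the first i attenders show up)
  pmf <- c(1, numeric(m))
  for (i in seq_len(m)) {
    p <- beliefs[i]
    pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
    pmf <- pmf[seq_len(m + 1L)]
  }
  sum(pmf[(threshold + 1L):(m + 1L)])
}

#' Expected payoff of attending, binary game
#'
#' Given a player's beliefs about the other N-1 players' attendance
#' probabilities, the expected payoff of action 1 is
#' \code{H - (H + L) * P(opponent attendance >= c)}; the payoff of action 0
#' is identically 0.
#'
#' @param beliefs_excluding_i Attendance probabilities of the other
#'   \code{n_players - 1} players.
#' @param spec A [game_spec()] with \code{n_actions = 2}.
#' @return Expected payoff of attending.
#' @examples
#' g <- game_spec(4, 2, gain = 1, loss = 1)
#' expected_payoff_binary(c(0.5, 0.5, 0.5), g) # 0
#' @export
expected_payoff_binary <- function(beliefs_excluding_i, spec) {
  stopifnot(inherits(spec, "game_spec"))
  if (length(beliefs_excluding_i) != spec$n_players - 1L)
    stop("`beliefs_excluding_i` must have length n_players - 1", call. = FALSE)
  tail <- tail_probability(beliefs_excluding_i, spec$capacity)
  spec$gain - (spec$gain + spec$loss) * tail
}

#' Best response in the binary game
#'
#' A player attends (action 1) exactly when the probability that the others
#' already fill the capacity does not exceed the indifference threshold
#' \code{u = H/(H+L)}; the tie at equality goes to attending, matching the
#' weak inequality in the best-response condition.
#'
#' @inheritParams expected_payoff_binary
#' @return 0L or 1L.
#' @export
best_response_binary <- function(beliefs_excluding_i, spec) {
  stopifnot(inherits(spec, "game_spec"))
  if (length(beliefs_excluding_i) != spec$n_players - 1L)
    stop("`beliefs_excluding_i` must have length n_players - 1", call. = FALSE)
  tail <- tail_probability(beliefs_excluding_i, spec$capacity)
  if (tail <= spec$indifference) 1L else 0L
}

#' Fictitious play of the binary bar game
#'
#' Iterates the discrete balance equation
#' \code{(t+1) x_i(t+1) = t x_i(t) + I(best response of i is 1)},
#' with all players updating simultaneously. \code{x_i(t)} is the empirical
#' frequency with which player i has attended; at \code{t = 0} frequencies
#' are undefined, so the initial belief vector is supplied explicitly and
#' counting starts at the first step.
#'
#' @param spec A [game_spec()] with \code{n_actions = 2}.
#' @param horizon Number of steps to iterate (>= 1).
#' @param init Initial attendance beliefs, one per player, in [0, 1].
#' @return A \code{(horizon + 1) x n_players} matrix of belief trajectories;
#'   row \code{t + 1} holds the beliefs after step t (row 1 is \code{init}).
#' @examples
#' g <- game_spec(3, 1, gain = 1, loss = 1)
#' fictitious_play_binary(g, horizon = 5, init = c(0, 0, 0))
#' @export
fictitious_play_binary <- function(spec, horizon, init) {
  stopifnot(inherits(spec, "game_spec"))
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1L)
    stop("`horizon` must be at least 1", call. = FALSE)
  n <- spec$n_players
  if (length(init) != n || any(init < 0) || any(init > 1))
    stop("`init` must give one probability in [0, 1] per player", call. = FALSE)
  x <- as.numeric(init)
  traj <- matrix(NA_real_, horizon + 1L, n)
  traj[1L, ] <- x
  for (t in 0:(horizon - 1L)) {
    br <- vapply(seq_len(n), function(i)
      best_response_binary(x[-i], spec), integer(1))
    x <- (t * x + br) / (t + 1)
    traj[t + 2L, ] <- x
  }
  colnames(traj) <- paste0("player", seq_len(n))
  traj
}

#' Flag convergence of a fictitious-play trajectory
#'
#' A trajectory is flagged converged when no belief changes by more than
#' \code{tol} over the last \code{window} steps.
#'
#' @param traj Matrix returned by [fictitious_play_binary()] or the
#'   \code{frequencies} of [fictitious_play_generalized()].
#' @param tol Maximum absolute change counted as "no movement".
#' @param window Number of trailing steps inspected.
#' @return TRUE/FALSE.
#' @export
has_converged <- function(traj, tol = 1e-6, window = 100L) {
  n_steps <- nrow(traj)
  if (n_steps <= window) return(FALSE)
  tail_block <- traj[(n_steps - window):n_steps, , drop = FALSE]
  rng <- apply(tail_block, 2, function(col) max(col) - min(col))
  all(rng < tol)
}

#' Enumerate pure Nash equilibria of the binary game
#'
#' Scans all 2^N action profiles and keeps those from which no single player
#' can strictly improve by switching action. For this game the equilibrium
#' set is exactly the profiles with \code{capacity} attendees.
#'
#' @param spec A [game_spec()] with \code{n_actions = 2} and
#'   \code{n_players <= 20}.
#' @return A matrix with one equilibrium profile per row (0/1 entries).
#' @examples
#' nrow(enumerate_pure_nash_binary(game_spec(4, 2, 1, 1))) # choose(4, 2) = 6
#' @export
enumerate_pure_nash_binary <- function(spec) {
  stopifnot(inherits(spec, "game_spec"))
  n <- spec$n_players
  if (n > 20L)
    stop("exhaustive scan limited to n_players <= 20 (2^N profiles)",
         call. = FALSE)
  profiles <- as.matrix(expand.grid(rep(list(0:1), n)))
  colnames(profiles) <- paste0("player", seq_len(n))
  keep <- apply(profiles, 1, function(a) {
    total <- sum(a)
    for (i in seq_len(n)) {
      here <- payoff_value(i, a[i], total, spec)
      flipped <- 1L - a[i]
      there <- payoff_value(i, flipped, total - a[i] + flipped, spec)
      if (there > here) return(FALSE)
    }
    TRUE
  })
  profiles[keep, , drop = FALSE]
}
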