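#' Aggregated opponent-demand distribution
#'
#' Each player summarises opponents by the distribution of their total
#' demand \code{Y_i = sum of opponents' actions}. Given each opponent's
#' action pmf on \code{0..k-1}, the aggregate pmf is their convolution, with
#' support \code{0..(N-1)(k-1)}.
#'
#' @param opponent_pmfs List of numeric pmf vectors; element j of a vector
#'   is the probability of action \code{j - 1}. Each must be non-negative
#'   and sum to 1 (within numerical slack).
#' @return Numeric pmf over total demand; element m is P(Y = m - 1).
#' @examples
#' aggregated_belief_pmf(list(c(0.5, 0.5), c(0.5, 0.5)))
#' @export
aggregated_belief_pmf <- function(opponent_pmfs) {
  if (!is.list(opponent_pmfs) || length(opponent_pmfs) == 0L)
    stop("`opponent_pmfs` must be a non-empty list of pmf vectors",
         call. = FALSE)
  for (p in opponent_pmfs) {
    if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-8)
      stop("each opponent pmf must be non-negative and sum to 1",
           call. = FALSE)
  }
  agg <- 1
  for (p in opponent_pmfs) {
    new <- numeric(length(agg) + length(p) - 1L)
    for (j in seq_along(p)) {
      if (p[j] > 0) {
        idx <- seq_along(agg) + j - 1L
        new[idx] <- new[idx] + agg * p[j]
      }
    }
    agg <- new
  }
  agg
}

#' Expected payoff of an action against an aggregate belief
#'
#' With aggregate opponent demand Y, the expected payoff of action j >= 1 is
#' \code{w_ij (H + L) (H/(H+L) - P(Y >= c - j + 1))}: attending pays off
#' whenever the full total \code{Y + j} stays within capacity (weak
#' inequality). Action 0 always pays 0.
#'
#' @param action Action j in \code{0:(n_actions - 1)}.
#' @param agg Aggregate pmf from [aggregated_belief_pmf()].
#' @param player Player index (for the weight w_ij).
#' @param spec A [game_spec()].
#' @return Expected payoff.
#' @export
expected_payoff_generalized <- function(action, agg, player, spec) {
  stopifnot(inherits(spec, "game_spec"))
  action <- as.integer(action)
  if (is.na(action) || action < 0L || action > spec$n_actions - 1L)
    stop("`action` out of range 0..k-1", call. = FALSE)
  if (any(agg < -1e-12) || abs(sum(agg) - 1) > 1e-8)
    stop("`agg` must be a valid pmf", call. = FALSE)
  if (action == 0L) return(0)
  m0 <- spec$capacity - action + 1L   # smallest opponent total that overloads
  tail <- if (m0 <= 0L) 1 else if (m0 >= length(agg)) 0 else
    sum(agg[(m0 + 1L):length(agg)])
  w <- spec$weights[player, action + 1L]
  w * (spec$gain + spec$loss) * (spec$indifference - tail)
}

#' Fictitious play of the generalized k-action game
#'
#' Iterates the balance equations
#' \code{(t+1) x_ij(t+1) = t x_ij(t) + I(j = argmax_k u_ik(t))} with
#' simultaneous updates: each step, every player best-responds to the
#' aggregate of the others' current empirical action frequencies and
#' increments the count of exactly one action. Argmax ties break toward the
#' lowest action index. Initial frequencies are supplied explicitly (at
#' t = 0 the count ratio is undefined).
#'
#' @param spec A [game_spec()].
#' @param horizon Number of steps (>= 1).
#' @param init An \code{n_players x n_actions} matrix of initial action
#'   pmfs (rows sum to 1). A vector of attendance probabilities is accepted
#'   for \code{n_actions = 2} and expanded to \code{cbind(1 - p, p)}.
#' @return A list of class \code{fictitious_play} with \code{actions}
#'   (\code{horizon x n_players} matrix of chosen actions),
#'   \code{frequencies} (\code{(horizon + 1) x n_players x n_actions} array;
#'   slice 1 is \code{init}), and \code{spec}.
#' @examples
#' g <- game_spec(3, 2, gain = 1, loss = 1, n_actions = 3)
#' fp <- fictitious_play_generalized(g, 50, matrix(1 / 3, 3, 3))
#' @export
fictitious_play_generalized <- function(spec, horizon, init) {
  stopifnot(inherits(spec, "game_spec"))
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1L)
    stop("`horizon` must be at least 1", call. = FALSE)
  n <- spec$n_players
  k <- spec$n_actions
  if (!is.matrix(init) && k == 2L && length(init) == n)
    init <- cbind(1 - init, init)
  if (!is.matrix(init) || !all(dim(init) == c(n, k)))
    stop("`init` must be an n_players x n_actions matrix of pmfs",
         call. = FALSE)
  if (any(init < 0) || any(abs(rowSums(init) - 1) > 1e-8))
    stop("each row of `init` must be a pmf summing to 1", call. = FALSE)

  x <- init
  freqs <- array(NA_real_, c(horizon + 1L, n, k))
  freqs[1L, , ] <- x
  actions <- matrix(NA_integer_, horizon, n)
  for (t in 0:(horizon - 1L)) {
    chosen <- integer(n)
    for (i in seq_len(n)) {
      agg <- aggregated_belief_pmf(
        lapply(setdiff(seq_len(n), i), function(m) x[m, ]))
      u <- vapply(0:(k - 1L), function(j)
        expected_payoff_generalized(j, agg, i, spec), numeric(1))
      chosen[i] <- which.max(u) - 1L   # ties -> lowest action index
    }
    for (i in seq_len(n)) {
      e <- numeric(k)
      e[chosen[i] + 1L] <- 1
      x[i, ] <- (t * x[i, ] + e) / (t + 1)
    }
    actions[t + 1L, ] <- chosen
    freqs[t + 2L, , ] <- x
  }
  structure(list(actions = actions, frequencies = freqs, spec = spec),
            class = "fictitious_play")
}

#' Modal action of each player at the end of fictitious play
#'
#' @param fp A \code{fictitious_play} object.
#' @return Integer vector of per-player actions with the highest final
#'   empirical frequency.
#' @export
modal_actions <- function(fp) {
  stopifnot(inherits(fp, "fictitious_play"))
  final <- fp$frequencies[dim(fp$frequencies)[1L], , , drop = TRUE]
  if (is.null(dim(final))) final <- matrix(final, nrow = 1)
  apply(final, 1, which.max) - 1L
}

#' Test a profile for pure Nash equilibrium (generalized game)
#'
#' Checks by direct deviation scan that no player can strictly improve by
#' switching to any of the other k - 1 actions. With unit weights the
#' equilibrium profiles are exactly those whose actions sum to the capacity.
#'
#' @param profile Integer vector of length \code{n_players}, actions in
#'   \code{0:(n_actions - 1)}.
#' @param spec A [game_spec()].
#' @return TRUE/FALSE.
#' @examples
#' g <- game_spec(3, 2, 1, 1, n_actions = 3)
#' is_pure_nash_generalized(c(0, 1, 1), g) # TRUE: actions sum to c = 2
#' @export
is_pure_nash_generalized <- function(profile, spec) {
  stopifnot(inherits(spec, "game_spec"))
  profile <- as.integer(profile)
  if (length(profile) != spec$n_players || any(is.na(profile)) ||
      any(profile < 0L) || any(profile > spec$n_actions - 1L))
    stop("`profile` must give one action in 0..k-1 per player", call. = FALSE)
  total <- sum(profile)
  for (i in seq_len(spec$n_players)) {
    here <- payoff_value(i, profile[i], total, spec)
    for (alt in 0:(spec$n_actions - 1L)) {
      if (alt == profile[i]) next
      there <- payoff_value(i, alt, total - profile[i] + alt, spec)
      if (there > here) return(FALSE)
    }
  }
  TRUE
}
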