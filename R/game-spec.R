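#' Specify a generalized El Farol bar game
#'
#' A congestion game with \code{n_players} players, each choosing an action
#' in \code{0, 1, ..., n_actions - 1}. Action 0 ("stay away") always pays 0.
#' A player taking action \code{j >= 1} receives \code{w_ij * gain} when the
#' sum of all actions is at most the capacity \code{capacity}, and
#' \code{-w_ij * loss} otherwise. The classical binary bar game is the case
#' \code{n_actions = 2}.
#'
#' @param n_players Number of players N (integer >= 2).
#' @param capacity Congestion threshold c: the largest total action at which
#'   attending still pays off. Must satisfy
#'   \code{1 <= capacity <= (n_players - 1) * (n_actions - 1)}.
#' @param gain Payoff H (> 0) received per unit weight when total demand is
#'   within capacity.
#' @param loss Penalty L (> 0) per unit weight when capacity is exceeded.
#' @param n_actions Number of actions k (integer >= 2, default 2).
#' @param weights Per-player, per-action positive weights w_ij: a single
#'   number, a vector of length \code{n_players} (recycled across actions),
#'   or an \code{n_players x n_actions} matrix. Defaults to 1. The weight on
#'   action 0 is never used.
#'
#' @return An object of class \code{game_spec}: a list with the validated
#'   fields plus \code{indifference}, the ratio \code{gain / (gain + loss)}
#'   at which a player is indifferent between attending and staying away.
#' @examples
#' g <- game_spec(n_players = 4, capacity = 2, gain = 1, loss = 1)
#' g$indifference
#' @export
game_spec <- function(n_players, capacity, gain, loss, n_actions = 2L,
                      weights = 1) {
  n_players <- as.integer(n_players)
  capacity <- as.integer(capacity)
  n_actions <- as.integer(n_actions)
  if (is.na(n_players) || n_players < 2L)
    stop("`n_players` must be an integer >= 2", call. = FALSE)
  if (is.na(n_actions) || n_actions < 2L)
    stop("`n_actions` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(gain) || length(gain) != 1L || gain <= 0)
    stop("`gain` (H) must be a single positive number", call. = FALSE)
  if (!is.numeric(loss) || length(loss) != 1L || loss <= 0)
    stop("`loss` (L) must be a single positive number", call. = FALSE)
  c_max <- (n_players - 1L) * (n_actions - 1L)
  if (is.na(capacity) || capacity < 1L || capacity > c_max)
    stop(sprintf("`capacity` must lie in [1, %d] for this game", c_max),
         call. = FALSE)

  if (is.matrix(weights)) {
    if (!all(dim(weights) == c(n_players, n_actions)))
      stop("`weights` matrix must be n_players x n_actions", call. = FALSE)
    w <- weights
  } else if (length(weights) == 1L) {
    w <- matrix(weights, n_players, n_actions)
  } else if (length(weights) == n_players) {
    w <- matrix(rep(weights, n_actions), n_players, n_actions)
  } else {
    stop("`weights` must be scalar, length n_players, or a matrix",
         call. = FALSE)
  }
  if (any(w <= 0)) stop("all weights must be positive", call. = FALSE)

  structure(
    list(n_players = n_players, capacity = capacity, gain = gain,
         loss = loss, n_actions = n_actions, weights = w,
         indifference = gain / (gain + loss)),
    class = "game_spec"
  )
}

#' @export
print.game_spec <- function(x, ...) {
  cat(sprintf(
    "El Farol bar game: N = %d players, k = %d actions, capacity c = %d\n",
    x$n_players, x$n_actions, x$capacity))
  cat(sprintf("  gain H = %g, loss L = %g, indifference u = H/(H+L) = %.4f\n",
              x$gain, x$loss, x$indifference))
  if (any(x$weights != 1)) cat("  heterogeneous weights w_ij\n")
  invisible(x)
}

#' Realised payoff of one player's action
#'
#' Payoff to player \code{player} for playing \code{action} when the sum of
#' all players' actions is \code{total_actions}: 0 for action 0,
#' \code{w_ij * H} when the total is within capacity, \code{-w_ij * L}
#' otherwise.
#'
#' @param player Player index (1-based).
#' @param action Action played, in \code{0:(n_actions - 1)}.
#' @param total_actions Sum of all actions played, including this player's.
#' @param spec A [game_spec()].
#' @return A single payoff value.
#' @examples
#' g <- game_spec(4, 2, gain = 2, loss = 1)
#' payoff_value(1, 1, total_actions = 2, g) # within capacity: +2
#' payoff_value(1, 1, total_actions = 3, g) # over capacity: -1
#' @export
payoff_value <- function(player, action, total_actions, spec) {
  stopifnot(inherits(spec, "game_spec"))
  action <- as.integer(action)
  if (is.na(action) || action < 0L || action > spec$n_actions - 1L)
    stop("`action` out of range 0..k-1", call. = FALSE)
  if (total_actions < action)
    stop("`total_actions` cannot be less than `action`", call. = FALSE)
  if (action == 0L) return(0)
  w <- spec$weights[player, action + 1L]
  if (total_actions <= spec$capacity) w * spec$gain else -w * spec$loss
}

#' Indifference threshold of the bar game
#'
#' The probability level \code{u = H / (H + L)} at which the expected payoff
#' of attending equals that of staying away; always strictly inside (0, 1).
#'
#' @param spec A [game_spec()], or a positive gain H when `loss` is given.
#' @param loss Optional loss L, for calling with raw payoffs.
#' @return The threshold u.
#' @examples
#' indifference_threshold(game_spec(3, 1, gain = 3, loss = 1)) # 0.75
#' @export
indifference_threshold <- function(spec, loss = NULL) {
  if (inherits(spec, "game_spec")) return(spec$indifference)
  gain <- spec
  if (!is.numeric(gain) || gain <= 0 || !is.numeric(loss) || loss <= 0)
    stop("gain and loss must both be positive", call. = FALSE)
  gain / (gain + loss)
}

#' Hospital-pharmacy 2x2 payoff matrix
#'
#' Builds the payoff matrix of the first-stage hospital-versus-pharmacy
#' choice: visiting neither pays 0, the pharmacy alone pays \code{e}, the
#' hospital alone pays \code{E}, and both pay \code{E + e}. The hospital
#' payoff \code{E} is intended to come from [expected_payoff()] evaluated at
#' the current belief, which couples the two stages of the model.
#'
#' @param hospital_payoff Payoff E of attending the hospital.
#' @param pharmacy_payoff Payoff e of attending the pharmacy.
#' @return A \code{pharmacy_game} object: a 2x2 numeric matrix with
#'   dimnames \code{hospital = c("no", "yes")}, \code{pharmacy = c("no",
#'   "yes")}, plus the two payoffs as attributes.
#' @examples
#' pharmacy_game_matrix(2, 1)
#' @export
pharmacy_game_matrix <- function(hospital_payoff, pharmacy_payoff) {
  stopifnot(is.numeric(hospital_payoff), length(hospital_payoff) == 1L,
            is.numeric(pharmacy_payoff), length(pharmacy_payoff) == 1L)
  m <- matrix(
    c(0, pharmacy_payoff, hospital_payoff, hospital_payoff + pharmacy_payoff),
    nrow = 2, byrow = TRUE,
    dimnames = list(hospital = c("no", "yes"), pharmacy = c("no", "yes"))
  )
  structure(m, hospital_payoff = hospital_payoff,
            pharmacy_payoff = pharmacy_payoff, class = c("pharmacy_game", "matrix"))
}
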