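#' Percentage rate of change of the mean belief
#'
#' \code{(mean_p - initial_p) / initial_p}, expressed in percent and
#' rounded half away from zero to the nearest integer, as reported in
#' prior-sensitivity tables.
#'
#' @param initial_p Prior belief (> 0).
#' @param mean_p Mean updated belief.
#' @return Integer percentage.
#' @examples
#' rate_of_change(0.3, 0.353) # 18
#' rate_of_change(0.5, 0.455) # -9
#' @export
rate_of_change <- function(initial_p, mean_p) {
  if (any(initial_p <= 0))
    stop("rate of change undefined for initial_p = 0", call. = FALSE)
  pct <- (mean_p - initial_p) / initial_p * 100
  as.integer(sign(pct) * floor(abs(pct) + 0.5))
}

#' Sensitivity of the mean belief to the prior
#'
#' Reruns the belief update for each candidate prior and reports the mean
#' updated belief and its percentage rate of change from the prior.
#'
#' @param series A [visit_series()].
#' @param params A [belief_params()]; its \code{initial_p} is overridden.
#' @param initial_values Priors to try, each in (0, 1].
#' @return Data frame with columns \code{initial_p}, \code{mean_p},
#'   \code{rate_pct}.
#' @export
sweep_initial_p <- function(series, params,
                            initial_values = seq(0.3, 0.7, by = 0.1)) {
  stopifnot(inherits(series, "visit_series"), inherits(params, "belief_params"))
  if (any(initial_values <= 0) || any(initial_values > 1))
    stop("initial values must lie in (0, 1]", call. = FALSE)
  rows <- lapply(initial_values, function(p0) {
    pr <- params
    pr$initial_p <- p0
    s <- summarize_trajectory(run_belief_trajectory(series, pr))
    data.frame(initial_p = p0, mean_p = s$mean_p,
               rate_pct = rate_of_change(p0, s$mean_p))
  })
  do.call(rbind, rows)
}

#' Sensitivity of the mean belief to the learning rate
#'
#' Reruns the belief update over a grid of learning rates, for each of a
#' set of observation windows (1, 3 and 5 days by default). Larger learning
#' rates weight the newest experience more heavily; at omega = 1 the belief
#' equals the raw daily signal.
#'
#' @param series A [visit_series()].
#' @param params A [belief_params()]; its learning rate and window are
#'   overridden.
#' @param omegas Learning rates in (0, 1].
#' @param windows Observation windows to cross with the rates.
#' @return Data frame with columns \code{learning_rate}, \code{window_days},
#'   \code{mean_p}, \code{days_above_half}.
#' @export
sweep_omega <- function(series, params, omegas, windows = c(1L, 3L, 5L)) {
  stopifnot(inherits(series, "visit_series"), inherits(params, "belief_params"))
  if (any(omegas <= 0) || any(omegas > 1))
    stop("learning rates must lie in (0, 1]", call. = FALSE)
  grid <- expand.grid(learning_rate = omegas, window_days = as.integer(windows))
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    pr <- params
    pr$learning_rate <- grid$learning_rate[r]
    pr$window_days <- grid$window_days[r]
    s <- summarize_trajectory(run_belief_trajectory(series, pr))
    data.frame(learning_rate = grid$learning_rate[r],
               window_days = grid$window_days[r],
               mean_p = s$mean_p, days_above_half = s$days_above_half)
  })
  do.call(rbind, rows)
}

#' Sensitivity of the mean belief to the crowding threshold
#'
#' Reruns the belief update over a grid of thresholds, crossed with
#' observation windows (1, 2 and 3 days by default). For a fixed series and
#' rule the daily signals are non-decreasing in the threshold, so the mean
#' belief is non-decreasing in c; at c equal to the series median with the
#' fraction rule the long-run mean belief settles near 0.5.
#'
#' @param series A [visit_series()].
#' @param params A [belief_params()]; its threshold and window are
#'   overridden.
#' @param thresholds Positive candidate thresholds.
#' @param windows Observation windows to cross with the thresholds.
#' @return Data frame with columns \code{threshold}, \code{window_days},
#'   \code{mean_p}, \code{days_above_half}.
#' @export
sweep_threshold <- function(series, params, thresholds,
                            windows = c(1L, 2L, 3L)) {
  stopifnot(inherits(series, "visit_series"), inherits(params, "belief_params"))
  if (any(thresholds < 1)) stop("thresholds must be positive", call. = FALSE)
  grid <- expand.grid(threshold = thresholds,
                      window_days = as.integer(windows))
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    pr <- params
    pr$threshold <- grid$threshold[r]
    pr$window_days <- grid$window_days[r]
    s <- summarize_trajectory(run_belief_trajectory(series, pr))
    data.frame(threshold = grid$threshold[r],
               window_days = grid$window_days[r],
               mean_p = s$mean_p, days_above_half = s$days_above_half)
  })
  do.call(rbind, rows)
}
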