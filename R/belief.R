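#' Construct a daily visit series
#'
#' A dated, gap-free series of non-negative integer daily visit counts
#' (outpatient or emergency attendances).
#'
#' @param dates Vector of \code{Date}s (or ISO-8601 strings), strictly
#'   increasing by one day.
#' @param counts Non-negative integer counts, one per date.
#' @return A data frame of class \code{visit_series} with columns
#'   \code{date} and \code{count}.
#' @export
visit_series <- function(dates, counts) {
  dates <- as.Date(dates)
  if (length(dates) < 1L) stop("series must have at least one day", call. = FALSE)
  if (length(dates) != length(counts))
    stop("`dates` and `counts` must have the same length", call. = FALSE)
  if (any(is.na(dates))) stop("unparseable dates in series", call. = FALSE)
  if (length(dates) > 1L && any(diff(dates) != 1)) {
    gaps <- dates[which(diff(dates) != 1)]
    stop("dates must be consecutive days; gap(s) after ",
         paste(format(gaps), collapse = ", "), call. = FALSE)
  }
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(data.frame(date = dates, count = as.integer(counts)),
            class = c("visit_series", "data.frame"))
}

#' Parameters of the daily belief update
#'
#' Bundles the tunables of the exponential belief update: the visit
#' threshold c regarded as "the hospital was not crowded", the learning
#' rate (the weight on the newest observation, also called learning
#' efficiency or discount rate), the prior belief, the observation window
#' in days, and the rule turning a window of counts into a reward signal.
#'
#' @param threshold Positive count level c at or below which a day counts
#'   as favourable. Usually an integer; a half-integer (e.g. an empirical
#'   median of an even-length series) is accepted.
#' @param learning_rate Learning rate in (0, 1]; default 0.2.
#' @param initial_p Prior belief in [0, 1]; default 0.5.
#' @param window_days Observation window d >= 1 (default 1): how many
#'   recent days of counts the patient consults.
#' @param signal_rule One of \code{"fraction"} (share of window days at or
#'   below threshold; the default), \code{"all"} (1 only if every window
#'   day is at or below threshold), \code{"mean"} (1 if the window mean is
#'   at or below threshold).
#' @return A list of class \code{belief_params}.
#' @export
belief_params <- function(threshold, learning_rate = 0.2, initial_p = 0.5,
                          window_days = 1L,
                          signal_rule = c("fraction", "all", "mean")) {
  signal_rule <- match.arg(signal_rule)
  window_days <- as.integer(window_days)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold < 1)
    stop("`threshold` must be a positive number", call. = FALSE)
  if (!is.numeric(learning_rate) || learning_rate <= 0 || learning_rate > 1)
    stop("`learning_rate` must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(initial_p) || initial_p < 0 || initial_p > 1)
    stop("`initial_p` must lie in [0, 1]", call. = FALSE)
  if (is.na(window_days) || window_days < 1L)
    stop("`window_days` must be at least 1", call. = FALSE)
  structure(list(threshold = threshold, learning_rate = learning_rate,
                 initial_p = initial_p, window_days = window_days,
                 signal_rule = signal_rule),
            class = "belief_params")
}

#' One step of the balance equation
#'
#' \code{p_t = (1 - omega) p_{t-1} + omega * signal}: an exponentially
#' weighted average of past favourable-experience indicators. The result is
#' a convex combination of two values in [0, 1] and so stays in [0, 1].
#'
#' @param p_prev Previous belief in [0, 1].
#' @param learning_rate Weight omega in (0, 1] on the new signal.
#' @param signal Reward signal in [0, 1].
#' @return Updated belief.
#' @examples
#' update_belief(0.5, 0.2, 1) # 0.6
#' @export
update_belief <- function(p_prev, learning_rate, signal) {
  if (any(p_prev < 0) || any(p_prev > 1))
    stop("`p_prev` must lie in [0, 1]", call. = FALSE)
  if (any(learning_rate <= 0) || any(learning_rate > 1))
    stop("`learning_rate` must lie in (0, 1]", call. = FALSE)
  if (any(signal < 0) || any(signal > 1))
    stop("`signal` must lie in [0, 1]", call. = FALSE)
  (1 - learning_rate) * p_prev + learning_rate * signal
}

#' Reward signal from a window of daily counts
#'
#' Converts the most recent \code{d} daily counts into the reward of the
#' belief update. A day is favourable when its count is at or below the
#' threshold (weak inequality).
#'
#' @param window_counts Non-empty vector of daily counts.
#' @param threshold Threshold c.
#' @param rule \code{"fraction"}, \code{"all"}, or \code{"mean"}; see
#'   [belief_params()].
#' @return Signal in [0, 1].
#' @examples
#' observation_signal(c(1200, 1300), 1250, "fraction") # 0.5
#' @export
observation_signal <- function(window_counts, threshold,
                               rule = c("fraction", "all", "mean")) {
  rule <- match.arg(rule)
  if (length(window_counts) == 0L)
    stop("observation window must be non-empty", call. = FALSE)
  if (threshold < 0) stop("`threshold` must be non-negative", call. = FALSE)
  switch(rule,
    fraction = mean(window_counts <= threshold),
    all = as.numeric(all(window_counts <= threshold)),
    mean = as.numeric(mean(window_counts) <= threshold)
  )
}

#' Analytic envelope of the belief sequence
#'
#' Unrolling the balance equation from \code{p_1 = initial_p} shows that
#' after t days the belief is bracketed by the all-unfavourable and
#' all-favourable paths:
#' \code{(1 - omega)^(t-1) p_1 <= p_t <= 1 - (1 - omega)^(t-1) (1 - p_1)}.
#'
#' @param initial_p Belief at day 1.
#' @param learning_rate Learning rate omega.
#' @param t Day index >= 1 (t = 1 returns the degenerate interval at
#'   \code{initial_p}).
#' @return Named vector \code{c(lower, upper)}.
#' @examples
#' belief_bounds(0.5, 0.2, 3) # c(0.32, 0.68)
#' @export
belief_bounds <- function(initial_p, learning_rate, t) {
  t <- as.integer(t)
  if (any(is.na(t)) || any(t < 1L))
    stop("`t` must be a positive integer", call. = FALSE)
  decay <- (1 - learning_rate)^(t - 1)
  lower <- decay * initial_p
  upper <- 1 - decay * (1 - initial_p)
  if (length(t) == 1L) c(lower = lower, upper = upper)
  else cbind(lower = lower, upper = upper)
}

#' Run the belief update over a visit series
#'
#' Simulates one representative patient's daily belief that the hospital is
#' accessible. The prior \code{initial_p} sits at day 0 and is not
#' reported; for each day t >= 1 the reward signal is computed from the
#' window of the most recent \code{min(t, window_days)} counts ending at t
#' (early days use however many days exist — no warm-up days are dropped),
#' then the balance equation is applied. One belief per calendar day is
#' returned.
#'
#' @param series A [visit_series()].
#' @param params A [belief_params()].
#' @return A data frame of class \code{belief_trajectory} with columns
#'   \code{date}, \code{count}, \code{signal}, \code{p}, and the parameters
#'   attached as attribute \code{params}.
#' @export
run_belief_trajectory <- function(series, params) {
  stopifnot(inherits(series, "visit_series"), inherits(params, "belief_params"))
  n <- nrow(series)
  counts <- series$count
  d <- params$window_days
  omega <- params$learning_rate
  signals <- numeric(n)
  p <- numeric(n)
  p_prev <- params$initial_p
  for (t in seq_len(n)) {
    win <- counts[max(1L, t - d + 1L):t]
    signals[t] <- observation_signal(win, params$threshold, params$signal_rule)
    p_prev <- update_belief(p_prev, omega, signals[t])
    p[t] <- p_prev
  }
  out <- data.frame(date = series$date, count = counts,
                    signal = signals, p = p)
  structure(out, params = params,
            class = c("belief_trajectory", "data.frame"))
}

#' Summarise a belief trajectory
#'
#' @param traj A \code{belief_trajectory}.
#' @return A list with \code{mean_p}, \code{days_above_half} (days with
#'   p strictly above 0.5), \code{fraction_above_half}, and \code{n_days}.
#' @export
summarize_trajectory <- function(traj) {
  stopifnot(inherits(traj, "belief_trajectory"))
  if (nrow(traj) == 0L) stop("empty trajectory", call. = FALSE)
  n <- nrow(traj)
  above <- sum(traj$p > 0.5)
  list(mean_p = mean(traj$p), days_above_half = above,
       fraction_above_half = above / n, n_days = n)
}

#' Monthly means of the belief
#'
#' Groups the trajectory by calendar month and averages the daily beliefs
#' within each month.
#'
#' @param traj A \code{belief_trajectory}.
#' @return A data frame with columns \code{month} (first day of month) and
#'   \code{mean_p}.
#' @export
monthly_summary <- function(traj) {
  stopifnot(inherits(traj, "belief_trajectory"))
  if (nrow(traj) == 0L) stop("empty trajectory", call. = FALSE)
  month <- as.Date(format(traj$date, "%Y-%m-01"))
  agg <- aggregate(list(mean_p = traj$p), by = list(month = month), FUN = mean)
  agg[order(agg$month), , drop = FALSE]
}

#' Emergency-mode monthly analysis
#'
#' Emergency patients are modelled as committed attenders: the prior is
#' p = 1 with a one-day observation window, and the crowding threshold is
#' the annual mean of the emergency series rounded to the nearest integer
#' (the average daily number of emergency visits). Returns the monthly mean
#' beliefs.
#'
#' @param series An emergency [visit_series()].
#' @param learning_rate Learning rate omega; default 0.2.
#' @return A data frame as from [monthly_summary()], with the fitted
#'   threshold attached as attribute \code{threshold}.
#' @export
emergency_analysis <- function(series, learning_rate = 0.2) {
  stopifnot(inherits(series, "visit_series"))
  thr <- max(1L, as.integer(round(mean(series$count))))
  params <- belief_params(threshold = thr, learning_rate = learning_rate,
                          initial_p = 1, window_days = 1L,
                          signal_rule = "fraction")
  traj <- run_belief_trajectory(series, params)
  out <- monthly_summary(traj)
  attr(out, "threshold") <- thr
  out
}
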