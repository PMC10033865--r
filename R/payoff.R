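#' Ratio-standardised indicator value
#'
#' Evaluation standard value of a service indicator: the hospital's value
#' divided by the national reference value. Reported tables round it to two
#' decimals; the raw ratio is returned (round separately for display).
#'
#' @param instance Hospital-level indicator value (> 0).
#' @param national National reference value (> 0).
#' @return The raw ratio instance / national.
#' @examples
#' round(standard_value(1200, 1002), 2) # 1.2
#' @export
standard_value <- function(instance, national) {
  if (any(!is.finite(national)) || any(national <= 0))
    stop("`national` must be positive", call. = FALSE)
  if (any(!is.finite(instance)) || any(instance <= 0))
    stop("`instance` must be positive", call. = FALSE)
  instance / national
}

#' Read a healthcare indicator table
#'
#' Reads a CSV with columns \code{category} (H or L), \code{name},
#' \code{national}, \code{instance}, \code{comprehensive_index} and an
#' optional \code{weight}. Thousands separators in numeric columns are
#' stripped. When \code{weight} is present and \code{comprehensive_index}
#' is absent, the index is computed as \code{weight * standard_value}.
#'
#' @param path Path to the CSV file.
#' @return A data frame of class \code{indicator_table} with an added
#'   \code{standard_value} column (raw ratio).
#' @export
read_indicator_csv <- function(path) {
  if (!file.exists(path)) stop("indicator file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  strip_num <- function(x) as.numeric(gsub("[,%]", "", as.character(x)))
  required <- c("category", "name", "national", "instance")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L)
    stop("indicator CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  raw$national <- strip_num(raw$national)
  raw$instance <- strip_num(raw$instance)
  if (!all(raw$category %in% c("H", "L")))
    stop("`category` must be 'H' or 'L' on every row", call. = FALSE)
  raw$standard_value <- standard_value(raw$instance, raw$national)
  if (!("comprehensive_index" %in% names(raw))) {
    if (!("weight" %in% names(raw)))
      stop("need either `comprehensive_index` or `weight` column", call. = FALSE)
    raw$weight <- strip_num(raw$weight)
    raw$comprehensive_index <- raw$weight * raw$standard_value
  } else {
    raw$comprehensive_index <- strip_num(raw$comprehensive_index)
  }
  structure(raw, class = c("indicator_table", "data.frame"))
}

#' Packaged hospital indicator table
#'
#' The eight-indicator composite measure (four gain-side, four loss-side)
#' shipped with the package: bed numbers, bed utilization, consultation and
#' inpatient loads, admission counts, disposable income, and stay length,
#' each ratio-standardised against its national value.
#'
#' @return An \code{indicator_table} data frame.
#' @export
healthcare_indicators <- function() {
  read_indicator_csv(system.file("extdata", "healthcare_indicators.csv",
                                 package = "elfarolcare", mustWork = TRUE))
}

#' Aggregate indicator table into the payoff pair (H, L)
#'
#' Sums the comprehensive indices within each payoff category: the H
#' (gain) categories measure service capacity quality, the L (loss)
#' categories measure demand burden. The loss sum can legitimately be
#' negative — the expected-payoff formula is applied to the signed values
#' as they stand.
#'
#' @param records An \code{indicator_table} (e.g. from
#'   [healthcare_indicators()] or [read_indicator_csv()]).
#' @return A list of class \code{payoff_index} with elements \code{gain}
#'   and \code{loss}.
#' @examples
#' aggregate_payoffs(healthcare_indicators())
#' @export
aggregate_payoffs <- function(records) {
  if (!all(c("category", "comprehensive_index") %in% names(records)))
    stop("`records` must have category and comprehensive_index columns",
         call. = FALSE)
  if (!all(c("H", "L") %in% records$category))
    stop("both payoff categories H and L must be present", call. = FALSE)
  gain <- sum(records$comprehensive_index[records$category == "H"])
  loss <- sum(records$comprehensive_index[records$category == "L"])
  payoff_index(gain, loss)
}

#' Construct a payoff index directly
#'
#' @param gain Aggregated gain-side payoff H.
#' @param loss Aggregated loss-side payoff L (may be negative).
#' @return A list of class \code{payoff_index}.
#' @export
payoff_index <- function(gain, loss) {
  stopifnot(is.numeric(gain), is.finite(gain),
            is.numeric(loss), is.finite(loss))
  structure(list(gain = gain, loss = loss), class = "payoff_index")
}

#' @export
print.payoff_index <- function(x, ...) {
  cat(sprintf("healthcare payoff index: H = %.4g, L = %.4g\n", x$gain, x$loss))
  invisible(x)
}

#' Reference payoff pair of the packaged indicator table
#'
#' The published composite table reports the gain-side payoff as 1.55
#' although its four indices sum to 1.56 (a rounding artefact of the
#' source table); the reported pair (1.55, -0.72) is returned, with the
#' raw column sums attached as attributes \code{computed_gain} and
#' \code{computed_loss}.
#'
#' @return A \code{payoff_index} with gain 1.55 and loss -0.72.
#' @export
healthcare_payoff_index <- function() {
  sums <- aggregate_payoffs(healthcare_indicators())
  out <- payoff_index(1.55, -0.72)
  attr(out, "computed_gain") <- sums$gain
  attr(out, "computed_loss") <- sums$loss
  out
}

#' Expected payoff of a hospital visit at belief p
#'
#' \code{E = H p - L (1 - p)}: the anticipated net benefit of attending
#' when the patient believes with probability p that the hospital is
#' accessible. Applied literally to signed H and L; E is affine in p with
#' slope \code{H + L} and range endpoints \code{-L} (at p = 0) and \code{H}
#' (at p = 1).
#'
#' @param p Belief(s) in [0, 1]; vectorised.
#' @param index A [payoff_index()].
#' @return Expected payoff(s).
#' @examples
#' expected_payoff(0.5, payoff_index(1.55, -0.72)) # 1.135
#' @export
expected_payoff <- function(p, index) {
  stopifnot(inherits(index, "payoff_index"))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("`p` must lie in [0, 1]", call. = FALSE)
  index$gain * p - index$loss * (1 - p)
}

#' Daily expected-payoff series from a belief trajectory
#'
#' Maps each daily belief through [expected_payoff()] and summarises by
#' calendar month.
#'
#' @param traj A \code{belief_trajectory}.
#' @param index A [payoff_index()].
#' @return A list of class \code{payoff_series} with \code{daily} (data
#'   frame: date, p, expected_payoff), \code{monthly} (month, mean
#'   expected payoff), and \code{range} (annual min and max).
#' @export
payoff_trajectory <- function(traj, index) {
  stopifnot(inherits(traj, "belief_trajectory"), inherits(index, "payoff_index"))
  if (nrow(traj) == 0L) stop("empty trajectory", call. = FALSE)
  e <- expected_payoff(traj$p, index)
  daily <- data.frame(date = traj$date, p = traj$p, expected_payoff = e)
  month <- as.Date(format(traj$date, "%Y-%m-01"))
  monthly <- aggregate(list(mean_expected_payoff = e),
                       by = list(month = month), FUN = mean)
  monthly <- monthly[order(monthly$month), , drop = FALSE]
  structure(list(daily = daily, monthly = monthly,
                 range = c(min = min(e), max = max(e)), index = index),
            class = "payoff_series")
}
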