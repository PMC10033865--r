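#' Load a daily visit series from CSV
#'
#' Expects a header \code{date,count} with ISO-8601 dates and one row per
#' day. Thousands separators inside counts are stripped. Non-consecutive
#' dates are a validation error that names the gap.
#'
#' @param path Path to the CSV file.
#' @return A [visit_series()].
#' @export
load_visit_csv <- function(path) {
  if (!file.exists(path)) stop("visit file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("date", "count") %in% names(raw)))
    stop("visit CSV must have header `date,count`: ", path, call. = FALSE)
  counts <- as.numeric(gsub(",", "", raw$count))
  bad <- which(is.na(counts))
  if (length(bad) > 0L)
    stop("unparseable count at line ", bad[1] + 1L, " of ", path,
         call. = FALSE)
  visit_series(raw$date, counts)
}

#' Write a visit series (or any table) to CSV
#'
#' @param table A data frame (e.g. a [visit_series()] or sweep table).
#' @param path Output path.
#' @return The path, invisibly. \code{load_visit_csv(write_table(s, p))}
#'   round-trips a visit series exactly.
#' @export
write_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Published monthly emergency belief reference
#'
#' The packaged table of monthly mean emergency beliefs (committed
#' attenders, one-day observation) used as a fixed reference in reporting;
#' values range between 0.8 and 1 across the year.
#'
#' @return Data frame with columns \code{month} (abbreviated name) and
#'   \code{mean_p}.
#' @export
emergency_monthly_reference <- function() {
  utils::read.csv(system.file("extdata", "emergency_monthly_p.csv",
                              package = "elfarolcare", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Scenario configuration for an end-to-end run
#'
#' Exactly one of \code{visit_csv} (a path) or \code{synth_preset}
#' ("outpatient" or "emergency", generated with \code{seed}) supplies the
#' visit series.
#'
#' @param out_dir Output directory (created if absent).
#' @param visit_csv Optional path to a `date,count` CSV.
#' @param synth_preset Optional synthetic preset name.
#' @param seed Seed for the synthetic preset.
#' @param params A [belief_params()]; defaults to threshold 1250, learning
#'   rate 0.2, prior 0.5, one-day window, fraction rule.
#' @param indicator_csv Path to an indicator CSV; defaults to the packaged
#'   indicator table.
#' @param sweep_thresholds,sweep_omegas Optional grids; when supplied the
#'   corresponding sweep tables are written.
#' @return A list of class \code{scenario_config}.
#' @export
scenario_config <- function(out_dir, visit_csv = NULL, synth_preset = NULL,
                            seed = 1L,
                            params = belief_params(threshold = 1250L),
                            indicator_csv = NULL,
                            sweep_thresholds = NULL, sweep_omegas = NULL) {
  if (is.null(visit_csv) == is.null(synth_preset))
    stop("supply exactly one of `visit_csv` or `synth_preset`", call. = FALSE)
  if (!is.null(synth_preset))
    synth_preset <- match.arg(synth_preset, c("outpatient", "emergency"))
  stopifnot(inherits(params, "belief_params"))
  structure(list(out_dir = out_dir, visit_csv = visit_csv,
                 synth_preset = synth_preset, seed = as.integer(seed),
                 params = params, indicator_csv = indicator_csv,
                 sweep_thresholds = sweep_thresholds,
                 sweep_omegas = sweep_omegas),
            class = "scenario_config")
}

#' Run a full scenario and write its report bundle
#'
#' Loads or generates the visit series, runs the belief update, maps it
#' through the payoff index, optionally runs threshold / learning-rate
#' sweeps, and writes: \code{trajectory.csv} (date, count, signal, p),
#' \code{payoff.csv} (date, p, expected payoff), \code{summary.json},
#' sweep CSVs, and \code{manifest.json} echoing every parameter. Identical
#' configurations produce identical bundles.
#'
#' @param config A [scenario_config()].
#' @return Invisibly, a list with the in-memory results
#'   (\code{series}, \code{trajectory}, \code{summary}, \code{payoffs},
#'   \code{paths}).
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  series <- if (!is.null(config$visit_csv)) {
    load_visit_csv(config$visit_csv)
  } else if (config$synth_preset == "outpatient") {
    generate_visit_series(default_outpatient_config(config$seed))
  } else {
    generate_visit_series(default_emergency_config(config$seed))
  }

  indicators <- if (is.null(config$indicator_csv)) healthcare_indicators()
                else read_indicator_csv(config$indicator_csv)
  index <- aggregate_payoffs(indicators)

  traj <- run_belief_trajectory(series, config$params)
  summ <- summarize_trajectory(traj)
  monthly <- monthly_summary(traj)
  pay <- payoff_trajectory(traj, index)

  paths <- list(
    trajectory = file.path(config$out_dir, "trajectory.csv"),
    payoff = file.path(config$out_dir, "payoff.csv"),
    summary = file.path(config$out_dir, "summary.json"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  write_table(as.data.frame(traj), paths$trajectory)
  write_table(pay$daily, paths$payoff)

  summary_obj <- list(
    mean_p = summ$mean_p, days_above_half = summ$days_above_half,
    fraction_above_half = summ$fraction_above_half, n_days = summ$n_days,
    gain = index$gain, loss = index$loss,
    monthly_mean_p = stats::setNames(monthly$mean_p,
                                     format(monthly$month, "%Y-%m")),
    monthly_mean_expected_payoff = stats::setNames(
      pay$monthly$mean_expected_payoff, format(pay$monthly$month, "%Y-%m"))
  )
  jsonlite::write_json(summary_obj, paths$summary, auto_unbox = TRUE,
                       digits = NA)

  if (!is.null(config$sweep_thresholds)) {
    paths$sweep_threshold <- file.path(config$out_dir, "sweep_threshold.csv")
    write_table(sweep_threshold(series, config$params,
                                config$sweep_thresholds),
                paths$sweep_threshold)
  }
  if (!is.null(config$sweep_omegas)) {
    paths$sweep_omega <- file.path(config$out_dir, "sweep_omega.csv")
    write_table(sweep_omega(series, config$params, config$sweep_omegas),
                paths$sweep_omega)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("elfarolcare")),
    seed = config$seed, synth_preset = config$synth_preset,
    visit_csv = config$visit_csv,
    params = unclass(config$params),
    n_days = nrow(series), outputs = unlist(paths)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")

  invisible(list(series = series, trajectory = traj, summary = summ,
                 monthly = monthly, payoffs = pay, index = index,
                 paths = paths))
}
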