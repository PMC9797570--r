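# ---- CSV readers/writers -----------------------------------------------
#
# File dialects (all UTF-8, headers required, weeks 1-based):
#   populations.csv : id, early_week, late_week, required_gdu, hq_case1,
#                     hq_case2
#   gdu_weekly.csv  : scenario, week, gdu   (long; one row per pair)
#   temps_daily.csv : date (ISO-8601), tmax_c, tmin_c

#' Read a population table
#'
#' @param path CSV path
#' @param horizon horizon T the windows are validated against (default 70)
#' @return validated population data.frame
#' @export
read_populations <- function(path, horizon = 70) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tryCatch(validate_populations(df, horizon),
           error = function(e) stop("reading ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
}

#' @rdname read_populations
#' @param populations validated population table
#' @export
write_populations <- function(populations, path) {
  utils::write.csv(populations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read weekly GDU scenarios (long format)
#'
#' Validates that every scenario covers weeks \code{1..T} exactly once.
#'
#' @param path CSV path with columns scenario, week, gdu
#' @param horizon expected weeks per scenario; default: the maximum week
#'   found
#' @return list of [gdu_scenario()]
#' @export
read_gdu_weekly <- function(path, horizon = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scenario", "week", "gdu")
  if (!all(need %in% names(df)))
    stop("reading ", path, ": columns scenario, week, gdu required")
  if (is.null(horizon)) horizon <- max(df$week)
  bad <- which(!is.finite(df$gdu) | df$gdu < 0)
  if (length(bad))
    stop("reading ", path, ": row(s) ", paste(utils::head(bad + 1L, 5),
                                              collapse = ", "),
         ": gdu must be finite and >= 0")
  lapply(split(df, df$scenario)[unique(df$scenario)], function(d) {
    d <- d[order(d$week), ]
    if (!identical(as.integer(d$week), seq_len(horizon)))
      stop("reading ", path, ": scenario '", d$scenario[1],
           "' does not cover weeks 1..", horizon, " exactly once")
    gdu_scenario(d$gdu, label = d$scenario[1])
  })
}

#' @rdname read_gdu_weekly
#' @param scenarios list of [gdu_scenario()]
#' @export
write_gdu_weekly <- function(scenarios, path) {
  df <- do.call(rbind, lapply(scenarios, function(s)
    data.frame(scenario = s$label, week = seq_along(s$weekly),
               gdu = s$weekly)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read daily temperatures and convert to a weekly GDU scenario
#'
#' @param path CSV with columns date, tmax_c, tmin_c
#' @param horizon,planning_year,label passed to [aggregate_weekly()]
#' @export
read_temps_daily <- function(path, horizon = NULL, planning_year = NULL,
                             label = "temps") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmax_c", "tmin_c")
  if (!all(need %in% names(df)))
    stop("reading ", path, ": columns date, tmax_c, tmin_c required")
  dates <- as.Date(df$date)
  bad <- which(is.na(dates))
  if (length(bad))
    stop("reading ", path, ": row(s) ", paste(utils::head(bad + 1L, 5),
                                              collapse = ", "),
         ": unparseable ISO-8601 date")
  daily <- daily_gdu(df$tmax_c, df$tmin_c)
  aggregate_weekly(daily, dates, horizon = horizon,
                   planning_year = planning_year, label = label)
}

#' Write a solved schedule
#'
#' One row per population: id, plant_week, then one
#' \code{harvest_week_<scenario>} column per scenario. Unreached cells are
#' an error unless \code{allow_unreached}.
#'
#' @param result a \code{gdu_solve_result} with a schedule
#' @param path output CSV
#' @param allow_unreached write NA harvest cells instead of failing
#' @export
write_schedule <- function(result, path, allow_unreached = FALSE) {
  if (is.null(result$schedule))
    stop("write_schedule: result has no feasible schedule (status ",
         result$status, ")")
  H <- result$profile$harvest_week
  if (!allow_unreached && anyNA(H))
    stop("write_schedule: unreached harvest cells present; ",
         "pass allow_unreached = TRUE to write them as NA")
  df <- data.frame(id = as.integer(names(result$schedule)),
                   plant_week = as.integer(result$schedule))
  for (k in seq_len(ncol(H)))
    df[[paste0("harvest_week_", colnames(H)[k])]] <- H[, k]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a schedule written by [write_schedule()]
#'
#' @param path CSV path
#' @param instance the instance it belongs to (for validation)
#' @return named planting-week vector
#' @export
read_schedule <- function(path, instance) {
  df <- utils::read.csv(path)
  if (!all(c("id", "plant_week") %in% names(df)))
    stop("reading ", path, ": columns id, plant_week required")
  df <- df[match(instance$populations$id, df$id), ]
  validate_schedule(stats::setNames(df$plant_week, df$id), instance)
}

#' Weekly harvest report
#'
#' Writes a per-week CSV of the weekly harvest quantities (per scenario
#' plus the max envelope when K > 1) for the solved schedule and, when
#' given, a comparison ("original planting") schedule, with the capacity
#' as a column. Returns (and writes as a JSON sidecar
#' \code{<path>.summary.json}) the summary block: objective, peak week,
#' active-week count, median and max absolute deviation from capacity over
#' harvesting weeks, and for capacity sizing the lowest capacity required
#' (the envelope peak).
#'
#' @param result a feasible \code{gdu_solve_result}
#' @param instance the [gdu_instance()]
#' @param path output CSV path
#' @param comparison optional second schedule (planting-week vector)
#' @return the summary list, invisibly
#' @export
report_weekly <- function(result, instance, path, comparison = NULL) {
  prof <- result$profile
  df <- data.frame(week = seq_len(instance$T))
  for (k in seq_len(ncol(prof$A)))
    df[[paste0("A_", colnames(prof$A)[k])]] <- prof$A[, k]
  if (ncol(prof$A) > 1) df$A_max <- prof$A_max
  if (!is.na(instance$capacity)) df$capacity <- instance$capacity
  if (!is.null(comparison)) {
    cprof <- evaluate_profile(comparison, instance)
    for (k in seq_len(ncol(cprof$A)))
      df[[paste0("A_comparison_", colnames(cprof$A)[k])]] <- cprof$A[, k]
    if (ncol(cprof$A) > 1) df$A_comparison_max <- cprof$A_max
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  act <- prof$A_max[prof$A_max > 0]
  dev <- if (!is.na(instance$capacity)) abs(instance$capacity - act)
         else numeric()
  summary <- list(
    objective = result$objective,
    status = result$status,
    peak_week = if (length(act)) which.max(prof$A_max) else NA_integer_,
    active_weeks = length(act),
    lowest_capacity_required = if (length(act)) max(act) else 0,
    median_abs_deviation = if (length(dev)) stats::median(dev) else NA_real_,
    max_abs_deviation = if (length(dev)) max(dev) else NA_real_)
  jsonlite::write_json(summary, paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
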