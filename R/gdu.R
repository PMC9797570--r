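#' Daily growing degree units from min/max temperature
#'
#' Computes the standard corn heat-unit increment
#' \deqn{GDU = (clamp(T_{max}) + clamp(T_{min}))/2 - T_{base}}
#' where both temperatures are clamped into the interval
#' \code{[base, cap]} before averaging: corn does not grow below the base
#' temperature (10 degrees C) and its growth rate saturates above the cap
#' (30 degrees C).
#'
#' @param tmax daily maximum air temperature, degrees C (vectorized)
#' @param tmin daily minimum air temperature, degrees C
#' @param base base temperature, degrees C (default 10)
#' @param cap upper temperature cap, degrees C (default 30)
#' @return non-negative heat units, same length as the inputs
#' @examples
#' daily_gdu(30, 10) # 10
#' daily_gdu(35, 30) # both clamp to 30 -> 20
#' daily_gdu(8, 2)   # below base -> 0
#' @export
daily_gdu <- function(tmax, tmin, base = 10, cap = 30) {
  if (!all(is.finite(tmax)) || !all(is.finite(tmin)))
    stop("daily_gdu: temperatures must be finite")
  if (cap <= base) stop("daily_gdu: cap must exceed base")
  hi <- pmin(pmax(tmax, base), cap)
  lo <- pmin(pmax(tmin, base), cap)
  (hi + lo) / 2 - base
}

#' Week number within a planning horizon
#'
#' Week 1 starts on January 1 of the planning year and runs through the
#' first Saturday; every subsequent week starts on a Sunday (the Excel
#' WEEKNUM convention, return type 1). Unlike WEEKNUM itself the count does
#' not reset at the following January 1: a 70-week horizon keeps counting
#' into the next year, which is what "weeks after January 1st of the
#' planning year" requires.
#'
#' @param dates a \code{Date} vector (or anything coercible via
#'   \code{as.Date})
#' @param planning_year the year whose January 1 anchors week 1; defaults to
#'   the year of the earliest date supplied
#' @return integer week indices (>= 1)
#' @export
week_number <- function(dates, planning_year = NULL) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("week_number: unparseable date")
  if (is.null(planning_year))
    planning_year <- as.integer(format(min(dates), "%Y"))
  jan1 <- as.Date(sprintf("%d-01-01", planning_year))
  days_since <- as.integer(dates - jan1)
  if (any(days_since < 0))
    stop("week_number: dates before Jan 1 of the planning year (",
         planning_year, ") are not in the horizon")
  # Sunday-based weekday of Jan 1 (Sunday = 0)
  dow0 <- as.integer(format(jan1, "%w"))
  as.integer((days_since + dow0) %/% 7L + 1L)
}

#' Aggregate a daily GDU series into weekly bins
#'
#' Sums contiguous daily heat units into the week bins defined by
#' [week_number()]. The first and last bins may cover fewer than seven days.
#'
#' @param daily numeric vector of daily GDUs, one per date
#' @param dates contiguous \code{Date} vector matching \code{daily}
#' @param horizon optional horizon T in weeks; extra trailing weeks are
#'   truncated, while a series too short to fill T weeks is an error
#'   (weekly values are never invented by padding)
#' @param planning_year passed to [week_number()]
#' @return a [gdu_scenario()] whose \code{weekly} component holds the weekly
#'   totals
#' @export
aggregate_weekly <- function(daily, dates, horizon = NULL,
                             planning_year = NULL, label = "weekly") {
  dates <- as.Date(dates)
  if (length(daily) != length(dates))
    stop("aggregate_weekly: one daily value per date required")
  if (length(dates) > 1 && any(diff(as.integer(dates)) != 1L))
    stop("aggregate_weekly: gaps in the date series")
  if (!all(is.finite(daily)) || any(daily < 0))
    stop("aggregate_weekly: daily GDUs must be finite and non-negative")
  wk <- week_number(dates, planning_year)
  totals <- as.numeric(rowsum(daily, wk))
  weeks <- sort(unique(wk))
  # bins are contiguous because the dates are
  weekly <- numeric(max(weeks))
  weekly[weeks] <- totals
  if (min(weeks) > 1L)
    stop("aggregate_weekly: series does not start in week 1")
  if (!is.null(horizon)) {
    if (length(weekly) < horizon)
      stop("aggregate_weekly: series covers ", length(weekly),
           " weeks but horizon is ", horizon, "; refusing to pad")
    weekly <- weekly[seq_len(horizon)]
  }
  gdu_scenario(weekly, label = label)
}

#' A weekly GDU scenario
#'
#' One heat-unit series over the horizon, typically one historical year
#' extended to the scheduling horizon.
#'
#' @param weekly non-negative weekly GDU values
#' @param label scenario name (year or similar)
#' @return an object of class \code{gdu_scenario}
#' @export
gdu_scenario <- function(weekly, label = "scenario") {
  weekly <- as.numeric(weekly)
  if (!all(is.finite(weekly)) || any(weekly < 0))
    stop("gdu_scenario: weekly GDUs must be finite and non-negative")
  structure(list(label = as.character(label), weekly = weekly),
            class = "gdu_scenario")
}

#' @export
print.gdu_scenario <- function(x, ...) {
  cat(sprintf("<gdu_scenario '%s': %d weeks, total %.1f GDU>\n",
              x$label, length(x$weekly), sum(x$weekly)))
  invisible(x)
}

#' Extend a 52-week scenario to the scheduling horizon
#'
#' Historical scenarios are calendar years (52 weeks) but the horizon is
#' longer (70 weeks by default). The default extension wraps back to the
#' start of the same series, preserving the year's climate identity; a
#' longer-than-needed series is truncated.
#'
#' @param scenario a [gdu_scenario()] or numeric vector
#' @param horizon target length T
#' @param method \code{"wrap"} (default) recycles the series from week 1;
#'   \code{"error"} refuses to extend
#' @export
extend_scenario <- function(scenario, horizon = 70, method = c("wrap", "error")) {
  method <- match.arg(method)
  weekly <- if (inherits(scenario, "gdu_scenario")) scenario$weekly else as.numeric(scenario)
  label <- if (inherits(scenario, "gdu_scenario")) scenario$label else "scenario"
  n <- length(weekly)
  if (n >= horizon) return(gdu_scenario(weekly[seq_len(horizon)], label))
  if (method == "error")
    stop("extend_scenario: series has ", n, " weeks, horizon is ", horizon)
  gdu_scenario(rep_len(weekly, horizon), label)
}

#' Cumulative GDU with a zero sentinel
#'
#' Returns the running sum \eqn{GDU_0, GDU_1, \dots, GDU_T} with
#' \eqn{GDU_0 = 0}; element \code{j + 1} of the result is the heat
#' accumulated through week \code{j}. The sentinel is what the
#' earliest-harvest constraint needs at \code{j = 1}.
#'
#' @param scenario a [gdu_scenario()] or numeric weekly vector
#' @return numeric vector of length T + 1, non-decreasing, starting at 0
#' @export
cumulative_gdu <- function(scenario) {
  weekly <- if (inherits(scenario, "gdu_scenario")) scenario$weekly else as.numeric(scenario)
  if (!all(is.finite(weekly)) || any(weekly < 0))
    stop("cumulative_gdu: weekly GDUs must be finite and non-negative")
  c(0, cumsum(weekly))
}

#' Earliest harvest week under the earliest-harvest rule
#'
#' A population planted in week \code{p} accumulates heat from the week
#' after planting onward and is harvested in the first week \code{h} with
#' \eqn{cum_h - cum_p \ge G^{min}}; by minimality
#' \eqn{cum_{h-1} - cum_p < G^{min}}. If no week within the horizon
#' reaches the requirement the population is unreached, encoded as
#' \code{NA}.
#'
#' @param plant_week planting week index (1-based, may be a vector)
#' @param required_gdu required heat units G_min (> 0)
#' @param cum cumulative series from [cumulative_gdu()] (length T + 1,
#'   leading 0)
#' @return integer harvest week(s); \code{NA_integer_} when unreached
#' @export
harvest_week <- function(plant_week, required_gdu, cum) {
  T_ <- length(cum) - 1L
  if (any(plant_week < 1L | plant_week > T_))
    stop("harvest_week: plant_week outside 1..T")
  if (!is.finite(required_gdu) || required_gdu <= 0)
    stop("harvest_week: required_gdu must be positive")
  target <- required_gdu + cum[plant_week + 1L]
  # smallest m with cum[m] >= target  (left-open: largest j with cum[j] < target)
  m <- findInterval(target, cum, left.open = TRUE) + 1L
  h <- m - 1L  # cum index -> week index
  h[h > T_] <- NA_integer_
  as.integer(h)
}

# Harvest week for every planting week 1..T of one population under one
# scenario; vectorized form of harvest_week used to precompute instance
# lookup tables.
harvest_lookup_row <- function(required_gdu, cum) {
  T_ <- length(cum) - 1L
  target <- required_gdu + cum[seq_len(T_) + 1L]
  h <- findInterval(target, cum, left.open = TRUE)
  h[h > T_] <- NA_integer_
  as.integer(h)
}
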