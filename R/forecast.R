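# ---- lagged weekly GDU forecasting skeleton ---------------------------
#
# The forecasting stage predicts each week's GDU from the same calendar
# week of the k previous years. Sequence models plug in through the
# fit/predict regressor contract; the climatology baseline (mean of the
# lagged values) is bundled and is all the scheduling pipeline needs.

#' Build a lagged same-week supervised dataset
#'
#' One sample per (year, week) with year beyond the first \code{lag} years:
#' features are the GDUs of the same week in the \code{lag} previous years
#' (oldest first), the target is that week's GDU. Chronological order is
#' preserved (week-major within year).
#'
#' @param weekly_by_year 52 x Y numeric matrix, one column per year in
#'   chronological order (column names = year labels); or a list of 52-week
#'   vectors
#' @param lag number of prior years k (>= 1)
#' @return object of class \code{lagged_dataset}: list with
#'   \code{features} (n x k matrix), \code{target}, \code{year},
#'   \code{week}
#' @export
build_lagged_dataset <- function(weekly_by_year, lag) {
  m <- .as_year_matrix(weekly_by_year)
  Y <- ncol(m)
  if (lag < 1 || lag != as.integer(lag)) stop("lag must be a positive integer")
  if (Y < lag + 1)
    stop("need at least lag + 1 = ", lag + 1, " complete years, have ", Y)
  years <- colnames(m)
  feats <- list(); targ <- numeric(); yy <- character(); ww <- integer()
  for (y in (lag + 1):Y) {
    feats[[length(feats) + 1L]] <- t(m[, (y - lag):(y - 1), drop = FALSE])
    targ <- c(targ, m[, y])
    yy <- c(yy, rep(years[y], 52L))
    ww <- c(ww, 1:52)
  }
  features <- t(do.call(cbind, feats))  # n x lag, oldest lag first
  colnames(features) <- paste0("lag", lag:1)
  structure(list(features = features, target = targ, year = yy, week = ww),
            class = "lagged_dataset")
}

.as_year_matrix <- function(weekly_by_year) {
  if (is.list(weekly_by_year) && !is.data.frame(weekly_by_year))
    weekly_by_year <- do.call(cbind, weekly_by_year)
  m <- as.matrix(weekly_by_year)
  if (nrow(m) != 52L)
    stop("each year must have exactly 52 weekly values (got ", nrow(m), ")")
  if (anyNA(m)) stop("incomplete years (NA values) are rejected")
  if (is.null(colnames(m))) colnames(m) <- paste0("y", seq_len(ncol(m)))
  m
}

#' Climatology baseline regressor
#'
#' Implements the pluggable regressor contract — a list with
#' \code{fit(features, target)} returning a fitted state and
#' \code{predict(state, features)} returning one value per row — as the
#' mean of the lagged same-week values. With \code{lag = 1} this is the
#' persistence forecast. Any object honoring the contract (e.g. a wrapper
#' around a neural sequence model) can replace it in
#' [rolling_forecast()].
#'
#' @return a regressor (list of \code{fit} and \code{predict})
#' @export
climatology_regressor <- function() {
  list(fit = function(features, target) list(),
       predict = function(state, features) rowMeans(features))
}

#' Forecast accuracy metrics
#'
#' Root mean square error, mean absolute error and Pearson correlation.
#' Correlation is reported as NA (with a warning) when either series has
#' zero variance.
#'
#' @param predictions,actuals equal-length numeric vectors (n >= 2)
#' @return list(rmse, mae, correlation)
#' @export
evaluate_forecast <- function(predictions, actuals) {
  if (length(predictions) != length(actuals) || length(actuals) < 2)
    stop("evaluate_forecast: need two equal-length series of n >= 2")
  err <- predictions - actuals
  r <- if (stats::sd(predictions) == 0 || stats::sd(actuals) == 0) {
    warning("correlation undefined for zero-variance input")
    NA_real_
  } else stats::cor(predictions, actuals)
  list(rmse = sqrt(mean(err^2)), mae = mean(abs(err)), correlation = r)
}

#' Roll a week-by-week forecast out to the scheduling horizon
#'
#' Fits the regressor on the lagged dataset of the history, predicts the
#' next year's 52 weeks from the last \code{lag} observed years, then —
#' for horizons beyond one year — appends the predicted year to the
#' history and predicts the opening weeks of the year after from lagged
#' features that include the first-year predictions. A 70-week horizon
#' yields the standard scheduling scenario.
#'
#' @param weekly_by_year 52 x Y history matrix (see
#'   [build_lagged_dataset()])
#' @param lag lag k in years
#' @param horizon_weeks forecast length (<= 104, i.e. two years)
#' @param regressor a fit/predict pair; default [climatology_regressor()]
#' @return a [gdu_scenario()] of length \code{horizon_weeks}
#' @export
rolling_forecast <- function(weekly_by_year, lag, horizon_weeks = 70,
                             regressor = climatology_regressor()) {
  if (horizon_weeks > 104) stop("horizon_weeks > 104 (two years) rejected")
  if (horizon_weeks < 1) stop("horizon_weeks must be >= 1")
  m <- .as_year_matrix(weekly_by_year)
  ds <- build_lagged_dataset(m, lag)
  state <- regressor$fit(ds$features, ds$target)
  lag_feats <- function(hist) {
    f <- hist[, (ncol(hist) - lag + 1):ncol(hist), drop = FALSE]
    colnames(f) <- paste0("lag", lag:1)  # 52 x lag, oldest first
    f
  }
  y1 <- as.numeric(regressor$predict(state, lag_feats(m)))
  out <- y1
  if (horizon_weeks > 52) {
    m2 <- cbind(m, y1)
    y2 <- as.numeric(regressor$predict(state, lag_feats(m2)))
    out <- c(out, y2)
  }
  gdu_scenario(pmax(out[seq_len(horizon_weeks)], 0), label = "forecast")
}
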