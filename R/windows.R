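#' Case/control lag-window specification
#'
#' In the 1:1 case-crossover design each exposure lag `k` in the case window
#' (day `-k` relative to onset) is matched with the same lag one week earlier
#' in the control window (day `-(k+7)`). The default case lags 0, 1 and 3 give
#' the pairs (0,7), (1,8) and (3,10).
#'
#' @param case_lags Integer vector of nonnegative case-window lags in days.
#'   Control lags are always `case_lags + 7`; the largest control lag may not
#'   exceed 13 (the control week spans days -13 to -7).
#' @return A `window_spec` object: a data frame with columns `case_lag` and
#'   `control_lag`.
#' @export
window_spec <- function(case_lags = c(0L, 1L, 3L)) {
  case_lags <- as.integer(case_lags)
  if (length(case_lags) == 0L || anyNA(case_lags) || any(case_lags < 0L)) {
    config_error("case lags must be nonnegative integers")
  }
  if (anyDuplicated(case_lags)) config_error("case lags must be unique")
  control_lags <- case_lags + 7L
  if (any(control_lags > 13L)) {
    config_error("control lag exceeds 13 days; case lags must be <= 6")
  }
  structure(
    data.frame(case_lag = case_lags, control_lag = control_lags),
    class = c("window_spec", "data.frame")
  )
}

#' @rdname window_spec
#' @export
default_window_spec <- function() window_spec()

# Days of series history an onset requires: the full case week (days -6..0)
# plus control week (days -13..-7), or more if a custom spec needs it.
required_history <- function(spec) max(13L, max(spec$control_lag))

#' Extract paired case/control exposures for one onset date
#'
#' For each lag pair in `spec`, returns the exposure of every environmental
#' variable on the case day (`onset - case_lag`) and the matched control day
#' (`onset - control_lag`, exactly 7 days earlier than the case day).
#'
#' @param onset_date A single `Date`: the disease onset day (day 0).
#' @param series An environmental series as returned by
#'   [simulate_environment()] or [read_series_csv()] (single region).
#' @param spec A [window_spec()].
#' @return Data frame with one row per (lag pair, variable): columns
#'   `case_lag`, `control_lag`, `case_date`, `control_date`, `variable`,
#'   `case_value`, `control_value`.
#' @export
extract_window_pairs <- function(onset_date, series, spec = default_window_spec()) {
  onset_date <- as.Date(onset_date)
  stopifnot(length(onset_date) == 1L)
  dates <- as.Date(series$date)
  vars <- intersect(c("min_temp", "max_temp", "ave_rh", "max_rh", "ave_o3"),
                    names(series))
  required <- onset_date - seq(0L, required_history(spec))
  covered <- required %in% dates
  if (any(!covered)) {
    stop_window(paste0(
      "series does not cover required day(s): ",
      paste(format(required[!covered]), collapse = ", ")
    ))
  }
  case_dates <- onset_date - spec$case_lag
  control_dates <- onset_date - spec$control_lag
  idx_case <- match(case_dates, dates)
  idx_control <- match(control_dates, dates)
  out <- do.call(rbind, lapply(seq_along(vars), function(v) {
    data.frame(
      case_lag = spec$case_lag,
      control_lag = spec$control_lag,
      case_date = case_dates,
      control_date = control_dates,
      variable = vars[v],
      case_value = series[[vars[v]]][idx_case],
      control_value = series[[vars[v]]][idx_control]
    )
  }))
  rownames(out) <- NULL
  out
}

#' Fit a 365.25-day sinusoid to a daily series
#'
#' Ordinary least squares of `value ~ a0 + a1 sin(w d) + a2 cos(w d)` with the
#' angular frequency fixed at `w = 2 * pi / 365.25` per day and `d` the number
#' of days since the series start. The sin+cos basis is equivalent to an
#' amplitude-and-phase parameterisation but keeps the fit linear and exact on
#' pure sinusoids.
#'
#' @param series An environmental series (single region).
#' @param variable Name of the column to fit (default `"min_temp"`).
#' @return A `sine_fit` object with coefficients `a0`, `a1`, `a2`, the fixed
#'   angular frequency `omega`, the origin date and the fitted variable name.
#' @export
fit_seasonal_sine <- function(series, variable = "min_temp") {
  if (!variable %in% names(series)) {
    config_error(paste0("variable '", variable, "' not present in series"))
  }
  y <- series[[variable]]
  if (all(is.na(y))) config_error(paste0("variable '", variable, "' is all missing"))
  dates <- as.Date(series$date)
  if (as.numeric(max(dates) - min(dates)) + 1 < 365) {
    warning("series spans less than one year; seasonal sine fit may be unstable")
  }
  omega <- 2 * pi / 365.25
  d <- as.numeric(dates - dates[1L])
  fit <- stats::lm(y ~ sin(omega * d) + cos(omega * d))
  co <- unname(stats::coef(fit))
  co[is.na(co)] <- 0
  structure(
    list(variable = variable, a0 = co[1L], a1 = co[2L], a2 = co[3L],
         omega = omega, origin = dates[1L]),
    class = "sine_fit"
  )
}

#' Evaluate a fitted seasonal sinusoid at given dates
#'
#' @param object A `sine_fit` from [fit_seasonal_sine()].
#' @param dates A `Date` vector.
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.sine_fit <- function(object, dates, ...) {
  d <- as.numeric(as.Date(dates) - object$origin)
  object$a0 + object$a1 * sin(object$omega * d) + object$a2 * cos(object$omega * d)
}

#' Seasonally adjust a control-window temperature
#'
#' The control day lies one week before the case day, so a seasonal trend in
#' temperature biases the case-minus-control difference. The fitted sinusoid
#' predicts the 7-day seasonal change, and the control value is shifted by
#' `fitted(case_date) - fitted(control_date)` so that the remaining difference
#' reflects weather anomalies rather than the time of year. On a purely
#' sinusoidal series the adjusted case-minus-control difference is exactly 0.
#'
#' @param control_value Raw control-day value(s).
#' @param case_date,control_date `Date` vectors matching `control_value`.
#' @param fit A `sine_fit` for the same variable.
#' @return Adjusted control value(s).
#' @export
adjust_control_temperature <- function(control_value, case_date, control_date, fit) {
  stopifnot(inherits(fit, "sine_fit"))
  control_value + (predict(fit, case_date) - predict(fit, control_date))
}

#' @export
print.sine_fit <- function(x, ...) {
  cat(sprintf(
    "Seasonal sine fit for '%s' (period 365.25 d):\n  a0 = %.4f, a1 = %.4f, a2 = %.4f (origin %s)\n",
    x$variable, x$a0, x$a1, x$a2, format(x$origin)
  ))
  invisible(x)
}
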