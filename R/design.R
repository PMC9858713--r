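#' Covariate specification for one region
#'
#' Each term names an environmental variable at a case-window lag and says
#' whether it is crossed with season. Season-crossed terms expand into four
#' design columns (one per season), nonzero only for events whose onset falls
#' in that season; plain terms contribute a single column.
#'
#' @param region Region label the specification applies to.
#' @param variable Character vector of variable names
#'   (`min_temp`, `max_temp`, `ave_rh`, `max_rh`, `ave_o3`).
#' @param lag Integer vector of case-window lags (must be lags of the
#'   accompanying [window_spec()]).
#' @param season_crossed Logical vector: cross the term with season?
#' @return A `covariate_spec` object (data frame with attribute `region`).
#' @export
covariate_spec <- function(region, variable, lag, season_crossed) {
  n <- length(variable)
  stopifnot(length(lag) == n, length(season_crossed) == n, n >= 1L)
  lag <- as.integer(lag)
  spec <- data.frame(
    variable = as.character(variable),
    lag = lag,
    season_crossed = as.logical(season_crossed)
  )
  if (anyDuplicated(spec[c("variable", "lag")])) {
    config_error("duplicate (variable, lag) pair in covariate specification")
  }
  structure(spec, region = region, class = c("covariate_spec", "data.frame"))
}

#' Default regional covariate specifications
#'
#' Three template term structures mirroring the three Taiwanese regional
#' models: the "northern" style has six season-crossed terms (24 columns),
#' the "central_southern" style adds a plain day-0 average-ozone term
#' (25 columns), and the "eastern" style has five season-crossed terms
#' (20 columns, with maximum relative humidity replacing the day -1 maximum
#' temperature and day-0 average humidity terms).
#'
#' @param style One of `"northern"`, `"central_southern"`, `"eastern"`.
#' @param region Region label; defaults to the style name.
#' @return A [covariate_spec()].
#' @export
default_covariate_spec <- function(style = c("northern", "central_southern", "eastern"),
                                   region = NULL) {
  style <- match.arg(style)
  region <- region %||% style
  base <- switch(style,
    northern = data.frame(
      variable = c("min_temp", "min_temp", "max_temp", "max_temp", "ave_rh", "max_rh"),
      lag = c(0L, 3L, 0L, 1L, 0L, 3L),
      season_crossed = TRUE
    ),
    central_southern = data.frame(
      variable = c("min_temp", "min_temp", "max_temp", "max_temp", "ave_rh", "max_rh",
                   "ave_o3"),
      lag = c(0L, 3L, 0L, 1L, 0L, 3L, 0L),
      season_crossed = c(rep(TRUE, 6L), FALSE)
    ),
    eastern = data.frame(
      variable = c("min_temp", "min_temp", "max_temp", "max_rh", "max_rh"),
      lag = c(0L, 3L, 0L, 0L, 3L),
      season_crossed = TRUE
    )
  )
  covariate_spec(region, base$variable, base$lag, base$season_crossed)
}

# Deterministic expanded column names: base terms in specification order,
# seasons in the fixed Spring/Summer/Autumn/Winter order.
expand_term_names <- function(cov_spec) {
  unlist(lapply(seq_len(nrow(cov_spec)), function(i) {
    base <- paste0(cov_spec$variable[i], "_lag", cov_spec$lag[i])
    if (cov_spec$season_crossed[i]) paste(base, season_levels(), sep = "_") else base
  }), use.names = FALSE)
}

# Meta columns preceding the term columns in a matched design data frame.
design_meta_cols <- c("event_id", "region", "season", "label")

#' Term (column) names of a matched design
#'
#' @param design A `matched_design`.
#' @return Character vector of expanded term names, in design order.
#' @export
design_terms <- function(design) {
  attr(design, "terms") %||% setdiff(names(design), design_meta_cols)
}

#' Events excluded while building a design
#'
#' @param design A `matched_design`.
#' @return Data frame with columns `event_id` and `reason` (zero rows if no
#'   event was excluded).
#' @export
design_exclusions <- function(design) {
  attr(design, "exclusions") %||%
    data.frame(event_id = character(), reason = character())
}

new_matched_design <- function(df, terms, exclusions) {
  structure(df, terms = terms, exclusions = exclusions,
            class = c("matched_design", "data.frame"))
}

#' Build the matched case-minus-control design matrix
#'
#' Turns onset records plus an environmental series into one row per event:
#' the difference between case-day and control-day exposure for every
#' covariate term, with season-crossed terms expanded into four columns that
#' are nonzero only in the event's onset-day season. Temperature differences
#' use seasonally adjusted control values (see
#' [adjust_control_temperature()]) unless detrending is disabled. Events
#' whose exposure window is not fully covered by the series are excluded and
#' logged (retrievable via [design_exclusions()]), never imputed.
#'
#' @param onsets Data frame with columns `subject_id` (or `event_id`),
#'   `region`, `onset_date`.
#' @param series Environmental series for the same region.
#' @param cov_spec A [covariate_spec()].
#' @param season_map A [season_map()].
#' @param wspec A [window_spec()]; every covariate lag must be one of its
#'   case lags.
#' @param detrend Character vector of variables whose control values receive
#'   the seasonal sine adjustment (default: the two temperature variables).
#'   Use `character()` to disable.
#' @param sine_fits Optional named list of `sine_fit` objects keyed by
#'   variable; fitted from `series` when missing.
#' @return A `matched_design`: data frame with columns `event_id`, `region`,
#'   `season`, `label` (always 1 for observed onsets) and one column per
#'   expanded term, plus attributes `terms` and `exclusions`.
#' @export
build_design_matrix <- function(onsets, series, cov_spec,
                                season_map = default_season_map(),
                                wspec = default_window_spec(),
                                detrend = c("min_temp", "max_temp"),
                                sine_fits = NULL) {
  stopifnot(inherits(cov_spec, "covariate_spec"))
  if (!all(cov_spec$lag %in% wspec$case_lag)) {
    config_error("covariate lag not present in window specification")
  }
  missing_vars <- setdiff(unique(cov_spec$variable), names(series))
  if (length(missing_vars)) {
    config_error(paste0("series lacks variable(s): ",
                        paste(missing_vars, collapse = ", ")))
  }
  if (length(unique(series$region)) > 1L) {
    config_error("series contains multiple regions; build one region at a time")
  }

  detrend <- intersect(detrend, unique(cov_spec$variable))
  if (is.null(sine_fits) && length(detrend)) {
    sine_fits <- lapply(stats::setNames(detrend, detrend), function(v) {
      fit_seasonal_sine(series, v)
    })
  }

  event_id <- as.character(onsets[["event_id"]] %||% onsets[["subject_id"]])
  onset_date <- as.Date(onsets$onset_date)
  dates <- as.Date(series$date)
  idx0 <- match(onset_date, dates)

  # An event is retained only if the series covers every required lag day.
  need <- required_history(wspec)
  ok <- !is.na(idx0) & (idx0 - need) >= 1L
  exclusions <- data.frame(
    event_id = event_id[!ok],
    reason = rep("incomplete exposure window", sum(!ok))
  )
  idx0 <- idx0[ok]
  kept_id <- event_id[ok]
  kept_date <- onset_date[ok]
  season <- assign_season(kept_date, season_map)

  terms <- expand_term_names(cov_spec)
  n <- length(idx0)
  X <- matrix(0, nrow = n, ncol = length(terms),
              dimnames = list(NULL, terms))
  for (i in seq_len(nrow(cov_spec))) {
    v <- cov_spec$variable[i]
    k <- cov_spec$lag[i]
    case_val <- series[[v]][idx0 - k]
    ctrl_val <- series[[v]][idx0 - k - 7L]
    if (!is.null(sine_fits[[v]])) {
      ctrl_val <- adjust_control_temperature(
        ctrl_val, kept_date - k, kept_date - k - 7L, sine_fits[[v]]
      )
    }
    d <- case_val - ctrl_val
    base <- paste0(v, "_lag", k)
    if (cov_spec$season_crossed[i]) {
      for (s in season_levels()) {
        col <- paste(base, s, sep = "_")
        X[, col] <- d * (season == s)
      }
    } else {
      X[, base] <- d
    }
  }

  df <- data.frame(
    event_id = kept_id,
    region = rep(attr(cov_spec, "region"), n),
    season = season,
    label = rep(1L, n)
  )
  df <- cbind(df, as.data.frame(X, check.names = FALSE))
  new_matched_design(df, terms, exclusions)
}

#' @export
print.matched_design <- function(x, ...) {
  cat(sprintf("Matched case-crossover design: %d events, %d terms (%d excluded)\n",
              nrow(x), length(design_terms(x)), nrow(design_exclusions(x))))
  NextMethod()
}

# Numeric term matrix and labels of a design (shared by the fitting code).
design_matrix_parts <- function(design) {
  terms <- design_terms(design)
  X <- as.matrix(as.data.frame(design)[, terms, drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, y = as.numeric(design$label), terms = terms)
}
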