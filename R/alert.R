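#' Predict the log odds ratio for exposure-difference vectors
#'
#' The per-event log odds ratio is the dot product of the coefficient vector
#' with the case-minus-control difference vector:
#' `lnOR = sum_p beta_p * d_p`.
#'
#' @param beta Named coefficient vector (e.g. the `mean` column of a
#'   [summarize_posterior()] result).
#' @param d A named numeric difference vector, a numeric matrix with term
#'   columns, or a `matched_design` / data frame containing the term columns.
#' @return Numeric vector of lnOR values (one per row of `d`).
#' @export
predict_lnor <- function(beta, d) {
  if (is.null(names(beta))) stop("beta must be a named coefficient vector")
  terms <- names(beta)
  if (inherits(d, "matched_design") || is.data.frame(d)) {
    missing_terms <- setdiff(terms, names(d))
    if (length(missing_terms)) {
      stop(paste0("difference data lacks term(s): ",
                  paste(missing_terms, collapse = ", ")))
    }
    D <- as.matrix(as.data.frame(d)[, terms, drop = FALSE])
  } else if (is.matrix(d)) {
    D <- d[, terms, drop = FALSE]
  } else {
    if (is.null(names(d)) || !setequal(names(d), terms)) {
      stop("difference vector names do not match coefficient names")
    }
    D <- matrix(as.numeric(d[terms]), nrow = 1L, dimnames = list(NULL, terms))
  }
  storage.mode(D) <- "double"
  drop(D %*% unname(as.numeric(beta[terms])))
}

# Critical values c_g = exp(median + 0.5 * (g - 2) * sd), g = 1..6.
critical_values <- function(median_lnor, sd_lnor) {
  g <- 1:6
  stats::setNames(exp(median_lnor + 0.5 * (g - 2) * sd_lnor), paste0("c", g))
}

#' Construct alert thresholds from log-OR location and spread
#'
#' The six critical values form a geometric progression on the OR scale:
#' `c_g = exp(median(lnOR) + 0.5 * (g - 2) * SD(lnOR))` for g = 1..6, so
#' `c2 = exp(median)` and consecutive thresholds differ by the constant
#' factor `exp(0.5 * SD)`.
#'
#' @param median_lnor Median of the log odds ratios.
#' @param sd_lnor Standard deviation of the log odds ratios (>= 0).
#' @param region,season Stratum labels.
#' @return An `alert_thresholds` object with fields `region`, `season`,
#'   `median_lnor`, `sd_lnor` and `critical` (named vector `c1`..`c6`).
#' @export
alert_thresholds <- function(median_lnor, sd_lnor, region = NA_character_,
                             season = NA_character_) {
  if (!is_scalar_number(median_lnor) || !is_scalar_number(sd_lnor) || sd_lnor < 0) {
    stop("median and SD of lnOR must be finite (SD >= 0)")
  }
  structure(
    list(region = region, season = season,
         median_lnor = median_lnor, sd_lnor = sd_lnor,
         critical = critical_values(median_lnor, sd_lnor)),
    class = "alert_thresholds"
  )
}

#' Compute alert thresholds from predicted case-day log odds ratios
#'
#' The alert intervals for a region-season stratum are anchored at the
#' median and sample standard deviation of the lnOR values predicted on the
#' stratum's observed case days.
#'
#' @param lnor_values Numeric vector of lnOR values (length >= 2, needed for
#'   the standard deviation).
#' @inheritParams alert_thresholds
#' @return An `alert_thresholds` object.
#' @export
compute_thresholds <- function(lnor_values, region = NA_character_,
                               season = NA_character_) {
  lnor_values <- lnor_values[is.finite(lnor_values)]
  if (length(lnor_values) < 2L) {
    stop("at least two lnOR values are required to estimate the spread")
  }
  alert_thresholds(stats::median(lnor_values), stats::sd(lnor_values),
                   region = region, season = season)
}

#' @export
print.alert_thresholds <- function(x, ...) {
  cat(sprintf(
    "Alert thresholds [%s, %s]: median lnOR = %.4f, SD lnOR = %.4f\n",
    x$region, x$season, x$median_lnor, x$sd_lnor
  ))
  print(signif(x$critical, 6))
  invisible(x)
}

#' Classify an odds ratio into an alert level
#'
#' Level g occupies the OR interval `[c_{g-1}, c_g)` with `c_0 = 0`; values
#' at or above `c_6` are capped at level 6. Equivalently the level is the
#' smallest g with `OR < c_g` (6 if none). This is the only interval
#' convention under which an OR between `c_2` and `c_3` yields level 3.
#'
#' @param or_value Positive odds ratio(s).
#' @param thresholds An `alert_thresholds` object.
#' @return Integer level(s) in 1..6.
#' @export
classify_alert <- function(or_value, thresholds) {
  stopifnot(inherits(thresholds, "alert_thresholds"))
  if (any(!is.finite(or_value)) || any(or_value <= 0)) {
    stop("odds ratios must be positive and finite")
  }
  pmin(findInterval(or_value, thresholds$critical) + 1L, 6L)
}

#' Posterior probabilities of each alert level
#'
#' Propagates posterior coefficient uncertainty into the alert level: each
#' retained draw's odds ratio `exp(beta_s . d)` is classified, and the
#' relative frequency of each level is returned.
#'
#' @param draws A `posterior_draws` object.
#' @param d A named difference vector (or single-row data frame) for the
#'   forecast day.
#' @param thresholds An `alert_thresholds` object.
#' @return Named numeric vector `p_level1`..`p_level6` summing to 1.
#' @export
level_probabilities <- function(draws, d, thresholds) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (is.data.frame(d)) {
    stopifnot(nrow(d) == 1L)
    d <- unlist(d[intersect(names(d), draws$terms)])
  }
  if (is.null(names(d)) || !setequal(names(d), draws$terms)) {
    stop("difference vector names do not match the draw terms")
  }
  lnor <- drop(draws$draws[, draws$terms, drop = FALSE] %*%
                 as.numeric(d[draws$terms]))
  lev <- classify_alert(exp(lnor), thresholds)
  stats::setNames(tabulate(lev, nbins = 6L) / length(lev),
                  paste0("p_level", 1:6))
}

#' Tabulate alert thresholds across strata
#'
#' One row per region-season stratum with the OR-scale median
#' (`exp(median_lnor)`), a dispersion column and the six critical values.
#' By default the dispersion is reported as `exp(SD(lnOR))` so that, like
#' the median column, it is an OR-scale quantity; `raw_log_stats = TRUE`
#' reports the log-scale median and SD instead.
#'
#' @param thresholds_list List of `alert_thresholds` objects.
#' @param raw_log_stats Report log-scale statistics instead of OR-scale.
#' @return Data frame with columns `region`, `season`, `median_OR` (or
#'   `median_lnOR`), `dispersion` (or `sd_lnOR`), `c1`..`c6`.
#' @export
threshold_table <- function(thresholds_list, raw_log_stats = FALSE) {
  if (inherits(thresholds_list, "alert_thresholds")) {
    thresholds_list <- list(thresholds_list)
  }
  rows <- lapply(thresholds_list, function(th) {
    stats_cols <- if (raw_log_stats) {
      data.frame(median_lnOR = th$median_lnor, sd_lnOR = th$sd_lnor)
    } else {
      data.frame(median_OR = exp(th$median_lnor), dispersion = exp(th$sd_lnor))
    }
    cbind(data.frame(region = th$region, season = th$season), stats_cols,
          as.data.frame(as.list(th$critical)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predict per-event risk with alert classification
#'
#' Convenience wrapper: computes lnOR and OR from the posterior-mean
#' coefficients for each row of `newdata`, classifies the OR into an alert
#' level, and (when draws are supplied) appends posterior level
#' probabilities.
#'
#' @param beta Named coefficient vector (posterior means).
#' @param newdata A `matched_design` or data frame with the term columns and
#'   an `event_id` column (generated when absent).
#' @param thresholds An `alert_thresholds` object.
#' @param draws Optional `posterior_draws` for level probabilities.
#' @return Data frame `event_id`, `lnOR`, `OR`, `level` and, with draws,
#'   `p_level1`..`p_level6`.
#' @export
predict_risk <- function(beta, newdata, thresholds, draws = NULL) {
  lnor <- predict_lnor(beta, newdata)
  ids <- if ("event_id" %in% names(newdata)) as.character(newdata$event_id) else
    sprintf("F%05d", seq_along(lnor))
  out <- data.frame(
    event_id = ids, lnOR = lnor, OR = exp(lnor),
    level = classify_alert(exp(lnor), thresholds)
  )
  if (!is.null(draws)) {
    terms <- draws$terms
    D <- as.matrix(as.data.frame(newdata)[, terms, drop = FALSE])
    probs <- t(apply(D, 1, function(drow) {
      level_probabilities(draws, stats::setNames(drow, terms), thresholds)
    }))
    out <- cbind(out, as.data.frame(probs))
  }
  out
}
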