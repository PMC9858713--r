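# CSV/JSON readers and writers. All floating-point output is rounded to 6
# significant digits so artifacts diff stably across platforms.

signif_df <- function(df, digits = 6) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  df
}

#' Write / read an environmental-series CSV
#'
#' Columns: `date` (ISO-8601), `region`, `min_temp`, `max_temp`, `ave_rh`,
#' `max_rh`, `ave_o3`.
#'
#' @param series An `env_series` data frame.
#' @param path File path.
#' @return `write_series_csv` returns `path` invisibly; `read_series_csv`
#'   returns an `env_series` data frame.
#' @export
write_series_csv <- function(series, path) {
  out <- as.data.frame(series)
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  utils::write.csv(signif_df(out), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @param region Optional region filter applied on read.
#' @export
read_series_csv <- function(path, region = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  if (!is.null(region)) df <- df[df$region == region, , drop = FALSE]
  df <- df[order(df$region, df$date), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("env_series", "data.frame"))
}

#' Write / read an onset-records CSV
#'
#' Columns: `subject_id`, `region`, `onset_date` (ISO-8601).
#'
#' @param onsets Onset data frame.
#' @param path File path.
#' @export
write_onsets_csv <- function(onsets, path) {
  out <- as.data.frame(onsets)
  out$onset_date <- format(as.Date(out$onset_date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_onsets_csv
#' @param region Optional region filter applied on read.
#' @export
read_onsets_csv <- function(path, region = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$onset_date <- as.Date(df$onset_date)
  if (!is.null(region)) df <- df[df$region == region, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write / read a matched-design CSV
#'
#' Columns: `event_id`, `region`, `season`, `label`, then one column per
#' expanded covariate term.
#'
#' @param design A `matched_design`.
#' @param path File path.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(signif_df(as.data.frame(design)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  terms <- setdiff(names(df), design_meta_cols)
  new_matched_design(df, terms,
                     data.frame(event_id = character(), reason = character()))
}

#' Write a posterior summary (CSV plus JSON sidecar)
#'
#' The CSV holds `term`, `mean`, `ci_2.5`, `ci_97.5`; the sidecar JSON holds
#' N, DIC, pD, the sampler settings, seed and acceptance rates.
#'
#' @param summary A `posterior_summary`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path-without-ext>.json`.
#' @param draws Optional `posterior_draws` (adds acceptance rates to the
#'   sidecar).
#' @export
write_posterior_csv <- function(summary, path, draws = NULL) {
  utils::write.csv(signif_df(as.data.frame(summary)), path,
                   row.names = FALSE, quote = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  meta <- list(
    N = attr(summary, "N"), DIC = attr(summary, "DIC"), pD = attr(summary, "pD")
  )
  if (!is.null(draws)) {
    meta$settings <- unclass(draws$settings)
    meta$seed <- draws$settings$seed
    meta$acceptance <- as.list(signif(draws$acceptance, 6))
  }
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_posterior_csv
#' @export
read_posterior_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(df, "N") <- meta$N
    attr(df, "DIC") <- meta$DIC
  }
  structure(df, class = c("posterior_summary", "data.frame"))
}

#' Extract the posterior-mean coefficient vector from a summary
#'
#' @param summary A `posterior_summary`.
#' @return Named numeric vector of posterior means.
#' @export
posterior_mean_beta <- function(summary) {
  stats::setNames(summary$mean, summary$term)
}

#' Write / read retained posterior draws as CSV (one column per term)
#'
#' @param draws A `posterior_draws`.
#' @param path File path.
#' @export
write_draws_csv <- function(draws, path) {
  utils::write.csv(signif_df(as.data.frame(draws$draws)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a thresholds table CSV
#'
#' @param table A data frame from [threshold_table()].
#' @param path File path.
#' @export
write_thresholds_csv <- function(table, path) {
  utils::write.csv(signif_df(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_thresholds_csv
#' @export
read_thresholds_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
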