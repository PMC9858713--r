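# Pipeline orchestration: configuration parsing and the simulate / fit /
# alert stages the command-line entry point wraps.

#' Read a pipeline configuration file
#'
#' YAML (`.yaml`/`.yml`) or JSON (`.json`). Relative input paths are resolved
#' against the configuration file's directory.
#'
#' @param path Configuration file path.
#' @return A named list with the file's directory in attribute `dir`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) config_error(paste0("configuration file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  config <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    config_error("configuration must be YAML or JSON")
  )
  attr(config, "dir") <- dirname(normalizePath(path))
  config
}

resolve_path <- function(path, config) {
  if (is.null(path)) return(NULL)
  if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(attr(config, "dir") %||% ".", path)
}

config_season_map <- function(config) {
  if (is.null(config$season_map) || identical(config$season_map, "default")) {
    default_season_map()
  } else {
    season_map(unlist(config$season_map))
  }
}

config_window_spec <- function(config) {
  if (is.null(config$window)) default_window_spec()
  else window_spec(unlist(config$window$case_lags))
}

config_prior <- function(config) {
  if (is.null(config$prior)) prior_spec()
  else prior_spec(config$prior$mean %||% 0, config$prior$variance %||% 100)
}

config_mcmc <- function(config, seed = NULL) {
  m <- config$mcmc %||% list()
  mcmc_settings(
    iterations = m$iterations %||% 60000L,
    burnin = m$burnin %||% 10000L,
    thin = m$thin %||% 10L,
    seed = seed %||% m$seed %||% 1L,
    init_scale = m$init_scale %||% 0.5
  )
}

config_covariate_spec <- function(region_entry) {
  if (!is.null(region_entry$style)) {
    default_covariate_spec(region_entry$style, region = region_entry$name)
  } else {
    terms <- region_entry$covariates
    covariate_spec(
      region_entry$name,
      vapply(terms, `[[`, character(1), "variable"),
      vapply(terms, function(t) as.integer(t$lag), integer(1)),
      vapply(terms, function(t) isTRUE(t$season_crossed), logical(1))
    )
  }
}

ensure_dir <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir
}

pipeline_log <- function(...) message("[crossrisk] ", sprintf(...))

#' Simulate stage: write a synthetic fixture bundle
#'
#' @param config Pipeline configuration list (see the package vignette);
#'   only its `simulate` section is consulted.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed (overrides the configuration's).
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(config = list(), out_dir, seed = NULL) {
  sim <- config$simulate %||% list()
  seed <- as.integer(seed %||% sim$seed %||% 1L)
  ensure_dir(out_dir)
  pipeline_log("simulate: seed = %d, out = %s", seed, out_dir)
  paths <- generate_fixture_bundle(
    out_dir, seed = seed,
    n_events_per_season = sim$n_events_per_season %||% 50L
  )
  pipeline_log("simulate: wrote %s", paste(basename(unlist(paths)), collapse = ", "))
  invisible(paths)
}

#' Fit stage: design matrices and Bayesian fits per region
#'
#' For every region in the configuration: builds the matched design from the
#' series and onset CSVs, runs the Metropolis sampler, and writes
#' `design_<region>.csv`, `posterior_<region>.csv` (+ JSON sidecar) and
#' `draws_<region>.csv`. N, exclusion counts, acceptance range and DIC are
#' logged.
#'
#' @param config Pipeline configuration list.
#' @param out_dir Output directory.
#' @param seed Optional sampler seed override.
#' @return Invisibly, a named list per region with `design`, `draws`,
#'   `summary`.
#' @export
run_fit <- function(config, out_dir, seed = NULL) {
  ensure_dir(out_dir)
  series_all <- read_series_csv(resolve_path(config$series_csv, config))
  onsets_all <- read_onsets_csv(resolve_path(config$onsets_csv, config))
  smap <- config_season_map(config)
  wspec <- config_window_spec(config)
  prior <- config_prior(config)
  detrend <- unlist(config$detrend %||% c("min_temp", "max_temp"))

  results <- list()
  for (entry in config$regions) {
    region <- entry$name
    cov <- config_covariate_spec(entry)
    series <- series_all[series_all$region == region, , drop = FALSE]
    onsets <- onsets_all[onsets_all$region == region, , drop = FALSE]
    if (nrow(series) == 0L || nrow(onsets) == 0L) {
      config_error(paste0("no series or onset rows for region ", region))
    }
    design <- build_design_matrix(onsets, series, cov, season_map = smap,
                                  wspec = wspec, detrend = detrend)
    if (nrow(design) == 0L) stop(paste0("empty design for region ", region))
    settings <- config_mcmc(config, seed = seed)
    draws <- run_mcmc(design, prior, settings)
    summ <- summarize_posterior(draws, design)
    pipeline_log(
      "fit[%s]: N = %d (%d excluded), %d terms, acceptance %.2f-%.2f, DIC = %.1f",
      region, nrow(design), nrow(design_exclusions(design)),
      length(design_terms(design)), min(draws$acceptance), max(draws$acceptance),
      attr(summ, "DIC")
    )
    write_design_csv(design, file.path(out_dir, paste0("design_", region, ".csv")))
    write_posterior_csv(summ, file.path(out_dir, paste0("posterior_", region, ".csv")),
                        draws = draws)
    write_draws_csv(draws, file.path(out_dir, paste0("draws_", region, ".csv")))
    results[[region]] <- list(design = design, draws = draws, summary = summ)
  }
  invisible(results)
}

#' Alert stage: thresholds per region-season and forecast classification
#'
#' Reads each region's fitted summary, draws and design from `fit_dir`,
#' predicts the case-day lnOR values with the posterior-mean coefficients,
#' computes per region-season [compute_thresholds()], writes
#' `thresholds.csv`, and classifies any forecast rows into
#' `predictions_<region>.csv`.
#'
#' @param config Pipeline configuration list.
#' @param fit_dir Directory holding the fit-stage artifacts.
#' @param out_dir Output directory (defaults to `fit_dir`).
#' @param forecasts Optional data frame of forecast difference rows (term
#'   columns plus `region`); defaults to the configuration's
#'   `forecast_csv` when set.
#' @param raw_log_stats Report log-scale statistics in the thresholds table.
#' @return Invisibly, a list with `thresholds` (table) and `predictions`.
#' @export
run_alert <- function(config, fit_dir, out_dir = fit_dir, forecasts = NULL,
                      raw_log_stats = isTRUE(config$flags$raw_log_stats)) {
  ensure_dir(out_dir)
  if (is.null(forecasts) && !is.null(config$forecast_csv)) {
    forecasts <- utils::read.csv(resolve_path(config$forecast_csv, config),
                                 check.names = FALSE)
  }
  thresholds <- list()
  predictions <- list()
  for (entry in config$regions) {
    region <- entry$name
    summ_path <- file.path(fit_dir, paste0("posterior_", region, ".csv"))
    design_path <- file.path(fit_dir, paste0("design_", region, ".csv"))
    if (!file.exists(summ_path) || !file.exists(design_path)) {
      stop(paste0("fit artifacts for region ", region,
                  " not found in ", fit_dir, "; run the fit stage first"))
    }
    summ <- read_posterior_csv(summ_path)
    design <- read_design_csv(design_path)
    beta <- posterior_mean_beta(summ)
    lnor <- predict_lnor(beta, design)
    region_th <- list()
    for (s in season_levels()) {
      vals <- lnor[design$season == s]
      if (length(vals) >= 2L) {
        region_th[[s]] <- compute_thresholds(vals, region = region, season = s)
      } else {
        pipeline_log("alert[%s]: season %s has %d case day(s); no thresholds",
                     region, s, length(vals))
      }
    }
    thresholds <- c(thresholds, region_th)
    if (!is.null(forecasts)) {
      fc <- if ("region" %in% names(forecasts)) {
        forecasts[forecasts$region == region, , drop = FALSE]
      } else forecasts
      if (nrow(fc)) {
        draws_path <- file.path(fit_dir, paste0("draws_", region, ".csv"))
        draws <- NULL
        if (file.exists(draws_path)) {
          dmat <- as.matrix(utils::read.csv(draws_path, check.names = FALSE))
          draws <- structure(list(draws = dmat, terms = colnames(dmat)),
                             class = "posterior_draws")
        }
        season_of <- if ("season" %in% names(fc)) fc$season else
          rep(names(region_th)[1L], nrow(fc))
        pred <- do.call(rbind, lapply(seq_len(nrow(fc)), function(r) {
          th <- region_th[[season_of[r]]]
          if (is.null(th)) return(NULL)
          predict_risk(beta, fc[r, , drop = FALSE], th, draws = draws)
        }))
        if (!is.null(pred)) {
          pred <- cbind(region = region, pred)
          utils::write.csv(signif_df(pred),
                           file.path(out_dir, paste0("predictions_", region, ".csv")),
                           row.names = FALSE, quote = FALSE)
          predictions[[region]] <- pred
        }
      }
    }
  }
  table <- threshold_table(thresholds, raw_log_stats = raw_log_stats)
  write_thresholds_csv(table, file.path(out_dir, "thresholds.csv"))
  pipeline_log("alert: wrote thresholds for %d region-season strata", nrow(table))
  invisible(list(thresholds = table, predictions = predictions))
}

#' Run the full pipeline: simulate, fit, alert
#'
#' @param config Pipeline configuration list; when it lacks `series_csv` /
#'   `onsets_csv`, the simulate stage's outputs are used.
#' @param out_dir Output directory.
#' @param seed Integer seed applied to simulation and sampling.
#' @return Invisibly, the alert-stage result.
#' @export
run_all <- function(config = list(), out_dir, seed = 1L) {
  paths <- run_simulate(config, out_dir, seed = seed)
  if (is.null(config$series_csv)) {
    config$series_csv <- paths$series
    config$onsets_csv <- paths$onsets
  }
  if (is.null(config$regions)) {
    config$regions <- list(
      list(name = "Northern", style = "northern"),
      list(name = "CentralSouthern", style = "central_southern"),
      list(name = "Eastern", style = "eastern")
    )
  }
  run_fit(config, out_dir, seed = seed)
  invisible(run_alert(config, out_dir))
}
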