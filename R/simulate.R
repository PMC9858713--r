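#' Parameters for one simulated environmental variable
#'
#' Daily values are generated as
#' `mean + amplitude * sin(2*pi*day/365.25 + phase) + e(day)` where `e` is a
#' stationary AR(1) process with autoregressive coefficient `ar` and
#' innovation standard deviation `sd`.
#'
#' @param mean Mean level (degrees C, percent RH, or concentration units).
#' @param amplitude Seasonal amplitude, same units as `mean`.
#' @param phase Seasonal phase in radians.
#' @param ar AR(1) coefficient in `[0, 1)`.
#' @param sd Innovation standard deviation (>= 0).
#' @return A list of validated parameters.
#' @export
env_var_params <- function(mean, amplitude = 0, phase = 0, ar = 0, sd = 0) {
  for (x in list(mean, amplitude, phase, ar, sd)) {
    if (!is_scalar_number(x)) config_error("environmental parameters must be finite scalars")
  }
  if (ar < 0 || ar >= 1) config_error("AR(1) coefficient must lie in [0, 1)")
  if (sd < 0) config_error("innovation SD must be nonnegative")
  list(mean = mean, amplitude = amplitude, phase = phase, ar = ar, sd = sd)
}

#' Configuration for the environmental-series simulator
#'
#' Defaults emulate a subtropical daily climate: minimum temperature around
#' 18 degrees C with a 6-degree seasonal swing peaking in July, relative
#' humidity in the 70--95 percent range, and ozone around 30 concentration
#' units, all with moderately autocorrelated day-to-day noise.
#'
#' @param region Region label written into the series.
#' @param n_days Number of consecutive days (>= 15).
#' @param start_date First calendar day.
#' @param min_temp,ave_rh,max_rh,ave_o3 Per-variable [env_var_params()].
#' @param temp_spread List with `mean`, `sd` and `floor` (> 0) for the daily
#'   max-minus-min temperature gap; `max_temp` is constructed as
#'   `min_temp + max(floor, draw)` so the ordering invariant holds.
#' @param seed Integer seed for the simulation stream.
#' @return An `env_sim_config` object.
#' @export
env_sim_config <- function(region = "Northern",
                           n_days = 731L,
                           start_date = as.Date("2008-01-01"),
                           min_temp = env_var_params(18, 6, -pi / 2, 0.7, 1.5),
                           ave_rh = env_var_params(76, 4, pi / 2, 0.5, 4),
                           max_rh = env_var_params(92, 3, pi / 2, 0.5, 3),
                           ave_o3 = env_var_params(30, 8, pi, 0.6, 6),
                           temp_spread = list(mean = 8, sd = 2, floor = 1),
                           seed = 1L) {
  n_days <- as.integer(n_days)
  if (is.na(n_days) || n_days < 15L) config_error("n_days must be at least 15")
  if (!is_scalar_number(temp_spread$floor) || temp_spread$floor <= 0) {
    config_error("temperature spread floor must be positive")
  }
  if (!is_scalar_number(temp_spread$mean) || !is_scalar_number(temp_spread$sd) ||
      temp_spread$sd < 0) {
    config_error("temperature spread mean/sd must be finite (sd >= 0)")
  }
  structure(
    list(region = region, n_days = n_days, start_date = as.Date(start_date),
         min_temp = min_temp, ave_rh = ave_rh, max_rh = max_rh, ave_o3 = ave_o3,
         temp_spread = temp_spread, seed = as.integer(seed)),
    class = "env_sim_config"
  )
}

# Stationary AR(1) noise of length n (first value drawn from the stationary
# distribution so the mean check has no start-up transient).
ar1_noise <- function(n, ar, sd) {
  if (sd == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd)
  if (ar == 0) return(innov)
  init <- stats::rnorm(1, 0, sd / sqrt(1 - ar^2))
  as.numeric(stats::filter(innov, ar, method = "recursive", init = init))
}

seasonal_signal <- function(day, p) {
  p$mean + p$amplitude * sin(2 * pi * day / 365.25 + p$phase)
}

#' Simulate a daily environmental series
#'
#' Generates a contiguous daily record of minimum/maximum temperature,
#' average/maximum relative humidity and average ozone, each as a sinusoid
#' with period 365.25 days plus stationary AR(1) noise. Humidity is clipped
#' to `[0, 100]` (then `max_rh` raised to at least `ave_rh`), ozone clipped
#' at 0, and `max_temp = min_temp + max(floor, spread draw)`; clip counts are
#' stored in the `clip_counts` attribute.
#'
#' @param config An [env_sim_config()].
#' @return An `env_series` data frame with columns `date`, `region`,
#'   `min_temp`, `max_temp`, `ave_rh`, `max_rh`, `ave_o3`.
#' @export
simulate_environment <- function(config) {
  stopifnot(inherits(config, "env_sim_config"))
  n <- config$n_days
  day <- seq_len(n) - 1
  with_rng_seed(config$seed, {
    min_temp <- seasonal_signal(day, config$min_temp) +
      ar1_noise(n, config$min_temp$ar, config$min_temp$sd)
    spread <- pmax(config$temp_spread$floor,
                   stats::rnorm(n, config$temp_spread$mean, config$temp_spread$sd))
    max_temp <- min_temp + spread
    ave_rh <- seasonal_signal(day, config$ave_rh) +
      ar1_noise(n, config$ave_rh$ar, config$ave_rh$sd)
    max_rh <- seasonal_signal(day, config$max_rh) +
      ar1_noise(n, config$max_rh$ar, config$max_rh$sd)
    ave_o3 <- seasonal_signal(day, config$ave_o3) +
      ar1_noise(n, config$ave_o3$ar, config$ave_o3$sd)
  })

  clip <- c(
    rh_low = sum(ave_rh < 0) + sum(max_rh < 0),
    rh_high = sum(ave_rh > 100) + sum(max_rh > 100),
    o3_low = sum(ave_o3 < 0)
  )
  ave_rh <- pmin(pmax(ave_rh, 0), 100)
  max_rh <- pmin(pmax(max_rh, 0), 100)
  clip["rh_order"] <- sum(max_rh < ave_rh)
  max_rh <- pmax(max_rh, ave_rh)
  ave_o3 <- pmax(ave_o3, 0)

  structure(
    data.frame(
      date = config$start_date + day,
      region = config$region,
      min_temp = min_temp, max_temp = max_temp,
      ave_rh = ave_rh, max_rh = max_rh, ave_o3 = ave_o3
    ),
    clip_counts = clip,
    class = c("env_series", "data.frame")
  )
}

#' Configuration for simulated case-crossover events
#'
#' Holds the true coefficient vector used to place events. These are the
#' data-generating values that downstream fitting should recover; they are
#' unrelated to the Normal(0, 100) prior used in estimation.
#'
#' @param n_events Number of events: total in pair mode, per season in study
#'   mode.
#' @param beta_true Named numeric vector of true coefficients keyed by
#'   expanded design-term name (e.g. `min_temp_lag0` or
#'   `min_temp_lag0_Spring`).
#' @param seed Integer seed.
#' @return An `event_sim_config` object.
#' @export
event_sim_config <- function(n_events, beta_true, seed = 1L) {
  n_events <- as.integer(n_events)
  if (is.na(n_events) || n_events < 1L) config_error("n_events must be >= 1")
  if (length(beta_true) && (is.null(names(beta_true)) || any(!nzchar(names(beta_true))))) {
    config_error("beta_true must be a named vector of coefficients")
  }
  if (length(beta_true) && any(!is.finite(beta_true))) {
    config_error("beta_true must be finite")
  }
  structure(list(n_events = n_events, beta_true = beta_true, seed = as.integer(seed)),
            class = "event_sim_config")
}

# Map a named coefficient vector onto the expanded term ordering, erroring on
# unknown keys; terms without a coefficient get 0.
align_beta_true <- function(beta_true, terms) {
  unknown <- setdiff(names(beta_true), terms)
  if (length(unknown)) {
    config_error(paste0("beta_true key(s) not among design terms: ",
                        paste(unknown, collapse = ", ")))
  }
  full <- stats::setNames(numeric(length(terms)), terms)
  full[names(beta_true)] <- beta_true
  full
}

#' Simulate labelled case/control day pairs (exact-likelihood mode)
#'
#' For each event a candidate index day `t` is drawn uniformly among days
#' with full lag history, paired with the referent day `t - 7`. The
#' case-minus-referent difference vector `d` is computed with the same window
#' and season-expansion machinery as [build_design_matrix()] (without
#' seasonal detrending, so generation and fitting see identical covariates),
#' and the event is placed at `t` with probability `plogis(d . beta_true)`,
#' else at the referent day. The emitted rows with their 0/1 labels are an
#' exact draw from the matched-pair conditional likelihood, which makes this
#' the parameter-recovery surface for the fitting module.
#'
#' @param series An environmental series (single region).
#' @param cov_spec A [covariate_spec()].
#' @param ev An [event_sim_config()].
#' @param season_map,wspec Window and season configuration.
#' @return A `matched_design` data frame with `label` 0/1 and attribute
#'   `beta_true`.
#' @export
simulate_events_pair_mode <- function(series, cov_spec, ev,
                                      season_map = default_season_map(),
                                      wspec = default_window_spec()) {
  stopifnot(inherits(ev, "event_sim_config"))
  dates <- as.Date(series$date)
  need <- required_history(wspec)
  eligible <- dates[(need + 1L):length(dates)]
  if (length(eligible) < 1L) config_error("series too short for the lag windows")

  n <- ev$n_events
  with_rng_seed(ev$seed, {
    onset <- sample(eligible, n, replace = TRUE)
    u <- stats::runif(n)
  })
  onsets <- data.frame(event_id = sprintf("P%05d", seq_len(n)),
                       region = series$region[1L], onset_date = onset)
  design <- build_design_matrix(onsets, series, cov_spec,
                                season_map = season_map, wspec = wspec,
                                detrend = character())
  parts <- design_matrix_parts(design)
  beta <- align_beta_true(ev$beta_true, parts$terms)
  eta <- drop(parts$X %*% beta)
  design$label <- as.integer(u[match(design$event_id, onsets$event_id)] < stats::plogis(eta))
  attr(design, "beta_true") <- beta
  attr(design, "n_skipped") <- nrow(design_exclusions(design))
  design
}

#' Simulate onset records over the study timeline
#'
#' End-to-end emulation surface: onset days are sampled (within each season)
#' with probability proportional to `exp(x_day . beta_true)`, where `x_day`
#' is the day's case-window covariate vector in the expanded term basis.
#' With `beta_true = 0` onsets are uniform over eligible days.
#'
#' @inheritParams simulate_events_pair_mode
#' @return An onset data frame with columns `subject_id`, `region`,
#'   `onset_date`.
#' @export
simulate_events_study_mode <- function(series, cov_spec, ev,
                                       season_map = default_season_map(),
                                       wspec = default_window_spec()) {
  stopifnot(inherits(ev, "event_sim_config"))
  dates <- as.Date(series$date)
  need <- required_history(wspec)
  if (length(dates) <= need) config_error("series too short for the lag windows")
  idx <- (need + 1L):length(dates)
  eligible <- dates[idx]
  season <- assign_season(eligible, season_map)

  terms <- expand_term_names(cov_spec)
  beta <- align_beta_true(ev$beta_true, terms)
  # Case-window covariate value of each eligible day, in the expanded basis.
  X <- matrix(0, nrow = length(idx), ncol = length(terms),
              dimnames = list(NULL, terms))
  for (i in seq_len(nrow(cov_spec))) {
    v <- cov_spec$variable[i]
    k <- cov_spec$lag[i]
    val <- series[[v]][idx - k]
    base <- paste0(v, "_lag", k)
    if (cov_spec$season_crossed[i]) {
      for (s in season_levels()) {
        X[, paste(base, s, sep = "_")] <- val * (season == s)
      }
    } else {
      X[, base] <- val
    }
  }
  eta <- drop(X %*% beta)

  with_rng_seed(ev$seed, {
    onset <- do.call(c, lapply(season_levels(), function(s) {
      in_s <- which(season == s)
      if (!length(in_s)) return(as.Date(character()))
      w <- exp(eta[in_s] - max(eta[in_s]))
      sample(eligible[in_s], ev$n_events, replace = TRUE, prob = w)
    }))
  })
  onset <- sort(onset)
  data.frame(
    subject_id = sprintf("S%05d", seq_along(onset)),
    region = series$region[1L],
    onset_date = onset
  )
}

#' Write a self-contained synthetic fixture bundle
#'
#' Generates three regions (northern, central-southern and eastern term
#' structures) of two years of daily environment, study-mode onset records,
#' a pair-mode validation table for the northern region, and a pipeline
#' configuration file referencing them. Everything is deterministic in
#' `seed`.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param n_events_per_season Study-mode events per region and season.
#' @return Invisibly, a named list of file paths (`series`, `onsets`,
#'   `pairs`, `config`).
#' @export
generate_fixture_bundle <- function(dir, seed = 1L, n_events_per_season = 50L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  styles <- c(Northern = "northern", CentralSouthern = "central_southern",
              Eastern = "eastern")
  offsets <- c(Northern = 0, CentralSouthern = 2, Eastern = -1)
  series_list <- list()
  onset_list <- list()
  for (i in seq_along(styles)) {
    region <- names(styles)[i]
    cfg <- env_sim_config(
      region = region, n_days = 731L,
      min_temp = env_var_params(18 + offsets[[region]], 6, -pi / 2, 0.7, 1.5),
      seed = seed + 100L * i
    )
    ser <- simulate_environment(cfg)
    spec <- default_covariate_spec(styles[[i]], region = region)
    beta_true <- stats::setNames(c(-0.1, 0.05), c(
      paste0("min_temp_lag0_", "Spring"), paste0("min_temp_lag0_", "Autumn")
    ))
    ev <- event_sim_config(n_events_per_season, beta_true, seed = seed + 100L * i + 1L)
    onset_list[[region]] <- simulate_events_study_mode(ser, spec, ev)
    series_list[[region]] <- ser
  }
  series <- do.call(rbind, series_list)
  onsets <- do.call(rbind, onset_list)
  rownames(series) <- rownames(onsets) <- NULL

  pair_spec <- covariate_spec("Northern", c("min_temp", "ave_rh"), c(0L, 0L),
                              c(FALSE, FALSE))
  pairs <- simulate_events_pair_mode(
    series_list$Northern, pair_spec,
    event_sim_config(500L, c(min_temp_lag0 = -0.3, ave_rh_lag0 = 0.1),
                     seed = seed + 7L)
  )

  paths <- list(
    series = file.path(dir, "series.csv"),
    onsets = file.path(dir, "onsets.csv"),
    pairs = file.path(dir, "pairs_northern.csv"),
    config = file.path(dir, "config.yaml")
  )
  write_series_csv(series, paths$series)
  write_onsets_csv(onsets, paths$onsets)
  write_design_csv(pairs, paths$pairs)

  config <- list(
    series_csv = "series.csv",
    onsets_csv = "onsets.csv",
    regions = lapply(seq_along(styles), function(i) {
      list(name = names(styles)[i], style = unname(styles[[i]]))
    }),
    mcmc = list(iterations = 4000L, burnin = 1000L, thin = 3L, seed = seed),
    prior = list(mean = 0, variance = 100),
    detrend = c("min_temp", "max_temp")
  )
  yaml::write_yaml(config, paths$config)
  invisible(paths)
}
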