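# Shared fixture builders. All randomness is seeded so the suite is
# deterministic.

quiet <- function(expr) suppressMessages(expr)

# Small environmental series with the default subtropical parameters.
make_series <- function(n_days = 420L, seed = 11L, region = "Northern", ...) {
  simulate_environment(env_sim_config(region = region, n_days = n_days,
                                      seed = seed, ...))
}

# A deterministic, noise-free series whose min_temp is a pure 365.25-day
# sinusoid (other variables constant).
make_sinusoid_series <- function(n_days = 800L, mean = 20, amplitude = 5,
                                 phase = 0) {
  simulate_environment(env_sim_config(
    n_days = n_days,
    min_temp = env_var_params(mean, amplitude, phase, 0, 0),
    ave_rh = env_var_params(70), max_rh = env_var_params(90),
    ave_o3 = env_var_params(30),
    temp_spread = list(mean = 8, sd = 0, floor = 1),
    seed = 1L
  ))
}

# Wrap a numeric matrix of difference vectors (plus labels) as a matched
# design, bypassing the window machinery for likelihood-level tests.
make_design <- function(X, label = rep(1L, nrow(X)), season = "Spring") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  df <- data.frame(
    event_id = sprintf("E%04d", seq_len(nrow(X))),
    region = "TestRegion", season = season, label = as.integer(label)
  )
  df <- cbind(df, as.data.frame(X, check.names = FALSE))
  crossrisk:::new_matched_design(
    df, colnames(X),
    data.frame(event_id = character(), reason = character())
  )
}

# Two-term pair-mode fixture: plain (non-crossed) day-0 minimum temperature
# and average humidity, with known coefficients.
pair_beta_true <- c(min_temp_lag0 = -0.3, ave_rh_lag0 = 0.1)

pair_cov_spec <- function() {
  covariate_spec("Northern", c("min_temp", "ave_rh"), c(0L, 0L), c(FALSE, FALSE))
}

make_pair_design <- function(n_events, beta_true = pair_beta_true,
                             event_seed = 7L, series = NULL) {
  if (is.null(series)) series <- make_series(n_days = 1100L, seed = 5L)
  simulate_events_pair_mode(
    series, pair_cov_spec(),
    event_sim_config(n_events, beta_true, seed = event_seed)
  )
}

# Reduced sampler schedule for unit tests.
small_settings <- function(iterations = 4000L, burnin = 1000L, thin = 3L,
                           seed = 42L, ...) {
  mcmc_settings(iterations = iterations, burnin = burnin, thin = thin,
                seed = seed, ...)
}
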