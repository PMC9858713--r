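test_that("season assignment follows the configured month map", {
  expect_equal(assign_season(as.Date("2010-04-15")), "Spring")
  expect_equal(assign_season(as.Date("2010-12-31")), "Winter")
  expect_equal(assign_season(as.Date("2010-08-01")), "Summer")
  # Exhaustive sweep of a leap year: every day maps to exactly one season
  # and the counts match the month lengths of the map.
  days <- seq(as.Date("2012-01-01"), as.Date("2012-12-31"), by = "day")
  s <- assign_season(days)
  expect_equal(length(s), 366L)
  expect_false(anyNA(s))
  expect_equal(as.vector(table(factor(s, season_levels()))),
               c(92L, 92L, 91L, 91L))  # MAM, JJA, SON, DJF(leap Feb)
})

test_that("custom season maps are validated and honoured", {
  flipped <- season_map(rep(c("Summer", "Winter"), each = 6))
  expect_equal(assign_season(as.Date("2010-01-15"), flipped), "Summer")
  expect_error(season_map(rep("Spring", 11)), class = "crossrisk_config_error")
  expect_error(season_map(c(rep("Spring", 11), "Monsoon")),
               class = "crossrisk_config_error")
})

test_that("window pairs use the day -0/-1/-3 vs -7/-8/-10 scheme", {
  ser <- make_series(n_days = 400L, seed = 2L,
                     start_date = as.Date("2010-01-01"))
  pairs <- extract_window_pairs(as.Date("2010-06-10"), ser)
  one_var <- pairs[pairs$variable == "min_temp", ]
  expect_equal(one_var$case_date,
               as.Date(c("2010-06-10", "2010-06-09", "2010-06-07")))
  expect_equal(one_var$control_date,
               as.Date(c("2010-06-03", "2010-06-02", "2010-05-31")))
  # Control day is exactly one week before the case day for every pair.
  expect_true(all(pairs$control_date == pairs$case_date - 7))
  # Values round-trip against direct series lookup.
  expect_equal(one_var$case_value, ser$min_temp[match(one_var$case_date, ser$date)])
})

test_that("onsets without full 14-day history are rejected", {
  ser <- make_series(n_days = 60L, start_date = as.Date("2010-01-01"))
  expect_error(extract_window_pairs(as.Date("2010-01-12"), ser),
               class = "crossrisk_window_error")
  expect_silent(extract_window_pairs(as.Date("2010-01-14"), ser))
})

test_that("a constant series yields equal case and control exposure", {
  ser <- make_sinusoid_series(n_days = 60L, amplitude = 0)
  pairs <- extract_window_pairs(ser$date[30], ser)
  expect_equal(pairs$case_value, pairs$control_value)
})

test_that("the sine fit recovers a pure sinusoid and a constant exactly", {
  omega <- 2 * pi / 365.25
  ser <- make_sinusoid_series(mean = 20, amplitude = 5, phase = 0)
  fit <- fit_seasonal_sine(ser, "min_temp")
  expect_equal(fit$a0, 20, tolerance = 1e-8)
  expect_equal(fit$a1, 5, tolerance = 1e-8)
  expect_equal(fit$a2, 0, tolerance = 1e-8)
  expect_equal(fit$omega, omega)

  flat <- make_sinusoid_series(mean = 20, amplitude = 0)
  ffit <- fit_seasonal_sine(flat, "min_temp")
  expect_equal(c(ffit$a0, ffit$a1, ffit$a2), c(20, 0, 0), tolerance = 1e-8)
})

test_that("the sine fit recovers noisy coefficients within 3 analytic SEs", {
  n <- 1461L  # four years
  ser <- simulate_environment(env_sim_config(
    n_days = n,
    min_temp = env_var_params(20, 5, 0, 0, 1),  # iid N(0,1) noise
    temp_spread = list(mean = 8, sd = 0, floor = 1), seed = 17L
  ))
  fit <- fit_seasonal_sine(ser, "min_temp")
  # OLS on an orthogonal-ish harmonic basis: SE(a1) = SE(a2) ~ sd*sqrt(2/n).
  se <- sqrt(2 / n)
  expect_lt(abs(fit$a0 - 20), 3 / sqrt(n))
  expect_lt(abs(fit$a1 - 5), 3 * se)
  expect_lt(abs(fit$a2 - 0), 3 * se)
})

test_that("seasonal adjustment cancels a pure sinusoid and matches its closed form", {
  omega <- 2 * pi / 365.25
  ser <- make_sinusoid_series(mean = 20, amplitude = 5, phase = 0.7)
  fit <- fit_seasonal_sine(ser, "min_temp")
  case_date <- ser$date[300]
  control_date <- case_date - 7
  raw_control <- ser$min_temp[ser$date == control_date]
  adj <- adjust_control_temperature(raw_control, case_date, control_date, fit)
  case_value <- ser$min_temp[ser$date == case_date]
  expect_equal(case_value - adj, 0, tolerance = 1e-9)

  # Closed form of the applied shift.
  d1 <- as.numeric(case_date - ser$date[1])
  d2 <- as.numeric(control_date - ser$date[1])
  shift <- fit$a1 * (sin(omega * d1) - sin(omega * d2)) +
    fit$a2 * (cos(omega * d1) - cos(omega * d2))
  expect_equal(adj - raw_control, shift, tolerance = 1e-9)

  # A flat fit leaves the raw value untouched.
  flat_fit <- fit_seasonal_sine(make_sinusoid_series(amplitude = 0), "min_temp")
  expect_equal(adjust_control_temperature(12.3, case_date, control_date, flat_fit),
               12.3)
})

test_that("design matrices have the documented column structure", {
  expect_length(crossrisk:::expand_term_names(default_covariate_spec("northern")), 24L)
  expect_length(crossrisk:::expand_term_names(default_covariate_spec("central_southern")), 25L)
  expect_length(crossrisk:::expand_term_names(default_covariate_spec("eastern")), 20L)

  ser <- make_series(n_days = 500L, seed = 4L)
  onsets <- data.frame(subject_id = "A", region = "Northern",
                       onset_date = as.Date("2008-04-20"))  # Spring
  design <- build_design_matrix(onsets, ser, default_covariate_spec("northern"))
  terms <- design_terms(design)
  expect_length(terms, 24L)
  vals <- unlist(design[1, terms])
  nonzero <- names(vals)[vals != 0]
  expect_lte(length(nonzero), 6L)
  expect_true(all(grepl("_Spring$", nonzero)))
})

test_that("design differences are invariant to constant shifts of a variable", {
  ser <- make_series(n_days = 500L, seed = 12L)
  onsets <- data.frame(subject_id = sprintf("S%02d", 1:20), region = "Northern",
                       onset_date = ser$date[seq(30, 450, length.out = 20)])
  d1 <- build_design_matrix(onsets, ser, default_covariate_spec("northern"))
  ser2 <- ser
  ser2$min_temp <- ser2$min_temp + 5
  ser2$max_temp <- ser2$max_temp + 5
  d2 <- build_design_matrix(onsets, ser2, default_covariate_spec("northern"))
  expect_equal(
    as.matrix(as.data.frame(d1)[, design_terms(d1)]),
    as.matrix(as.data.frame(d2)[, design_terms(d2)]),
    tolerance = 1e-9
  )
})

test_that("events with incomplete windows are excluded and logged", {
  ser <- make_series(n_days = 200L, seed = 6L)
  onset_dates <- c(ser$date[c(3, 8, 13)],                  # < 14 days history
                   ser$date[seq(20, 190, length.out = 97)])
  onsets <- data.frame(subject_id = sprintf("S%03d", 1:100),
                       region = "Northern", onset_date = onset_dates)
  # A 200-day series triggers the documented short-series detrending warning
  # once per detrended temperature variable.
  w <- capture_warnings(
    design <- build_design_matrix(onsets, ser, default_covariate_spec("northern"))
  )
  expect_length(w, 2L)
  expect_true(all(grepl("less than one year", w)))
  expect_equal(nrow(design), 97L)
  excl <- design_exclusions(design)
  expect_equal(nrow(excl), 3L)
  expect_setequal(excl$event_id, c("S001", "S002", "S003"))
  expect_true(all(excl$reason == "incomplete exposure window"))
})

test_that("design construction validates its configuration", {
  ser <- make_series(n_days = 100L)
  onsets <- data.frame(subject_id = "A", region = "Northern",
                       onset_date = ser$date[50])
  bad_var <- covariate_spec("Northern", "pm25", 0L, TRUE)
  expect_error(build_design_matrix(onsets, ser, bad_var),
               class = "crossrisk_config_error")
  bad_lag <- covariate_spec("Northern", "min_temp", 2L, TRUE)
  expect_error(build_design_matrix(onsets, ser, bad_lag),
               class = "crossrisk_config_error")
  expect_error(window_spec(c(0, 7)), class = "crossrisk_config_error")
  expect_error(window_spec(-1), class = "crossrisk_config_error")
})

test_that("detrending changes only temperature columns", {
  ser <- make_series(n_days = 500L, seed = 13L)
  onsets <- data.frame(subject_id = sprintf("S%02d", 1:10), region = "Northern",
                       onset_date = ser$date[seq(40, 460, length.out = 10)])
  spec <- default_covariate_spec("northern")
  with_adj <- build_design_matrix(onsets, ser, spec)
  without <- build_design_matrix(onsets, ser, spec, detrend = character())
  temp_cols <- grep("temp", design_terms(with_adj), value = TRUE)
  other_cols <- setdiff(design_terms(with_adj), temp_cols)
  expect_equal(as.data.frame(with_adj)[other_cols],
               as.data.frame(without)[other_cols])
  expect_false(isTRUE(all.equal(as.data.frame(with_adj)[temp_cols],
                                as.data.frame(without)[temp_cols])))
})
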