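# crossrisk

Bayesian case-crossover modelling of environmental disease risk, with
six-level risk-alert construction.

`crossrisk` is for epidemiologists and public-health modellers who want to
turn daily environmental series (temperature, relative humidity, ozone) and
disease-onset records into a graded, probabilistic disease-risk alert
system. It implements the full pipeline:

1. **Matched exposure windows.** Each onset is self-matched one week back:
   case exposures at lags 0/−1/−3 days are paired with control exposures at
   −7/−8/−10. Control-window temperature is seasonally adjusted by an OLS
   sinusoid with period 365.25 d, removing the deterministic 7-day seasonal
   drift from the case-minus-control contrast.
2. **Bayesian conditional logistic regression.** For 1:1 matched data the
   conditional likelihood is an intercept-free logistic model on the
   difference vectors *d*ᵢ:
   log OR
   ᵢ = βᵀdᵢ, with independent Normal(0, 100) priors on β. The posterior
   is sampled by adaptive component-wise random-walk Metropolis (default
   schedule 60,000 iterations, 10,000 burn-in, thinning 10 → exactly 5000
   retained draws), summarised by posterior means, equal-tailed 95%
   credible intervals and DIC.
3. **Risk alerts.** Per-stratum (region × season) critical values form a
   geometric ladder on the OR scale,
   *c*₉ = exp{median(lnOR) + 0.5 (g−2) SD(lnOR)}, g = 1…6, computed from
   the lnOR values of the stratum's observed case days; a predicted OR in
   [*c*₉₋₁, *c*₉) is a level-g alert, and posterior level probabilities
   quantify the classification's uncertainty.
4. **Synthetic data.** A generator produces environmental series
   (sinusoidal seasonality + AR(1) noise, bounded humidity, nonnegative
   ozone) and case-crossover events with known coefficients, in both an
   exact-likelihood "pair" mode for parameter recovery and an end-to-end
   "study" mode.

## Worked example

```r
library(crossrisk)

# 1. Simulate two years of daily environment and onset records
series <- simulate_environment(env_sim_config(region = "Northern", n_days = 731, seed = 1))
spec   <- default_covariate_spec("northern", region = "Northern")
onsets <- simulate_events_study_mode(
  series, spec,
  event_sim_config(50, c(min_temp_lag0_Spring = -0.15), seed = 2)
)

# 2. Matched case-minus-control design with seasonal detrending
design <- build_design_matrix(onsets, series, spec)

# 3. Bayesian conditional logistic regression
draws <- run_mcmc(design, prior_spec(0, 100),
                  mcmc_settings(iterations = 20000, burnin = 5000, thin = 5, seed = 3))
summ <- summarize_posterior(draws, design)
head(as.data.frame(summ), 3)
#>                   term       mean     ci_2.5     ci_97.5
#> 1 min_temp_lag0_Spring -0.4144410 -0.8183283 -0.05077703
#> 2 min_temp_lag0_Summer -0.1099499 -0.4630027  0.23984507
#> 3 min_temp_lag0_Autumn -0.5219095 -0.9859881 -0.05896042
attr(summ, "DIC")   # 289.0943
attr(summ, "N")     # 200
```

Each row is a coefficient of the 24-column northern-style design (term ×
season); e.g. the Spring day-0 minimum-temperature coefficient −0.41 means
each 1 °C *drop* relative to the same day a week earlier multiplies the
disease odds by exp(0.41) ≈ 1.51 in Spring.

```r
# 4. Six-level alert thresholds for Spring, and a forecast classification
beta <- posterior_mean_beta(summ)
lnor <- predict_lnor(beta, design)
th <- compute_thresholds(lnor[design$season == "Spring"], "Northern", "Spring")
th
#> Alert thresholds [Northern, Spring]: median lnOR = 0.2739, SD lnOR = 1.0176
#>        c1        c2        c3        c4        c5        c6
#>  0.790679  1.315130  2.187460  3.638390  6.051720 10.065800

# A forecast day 4 degrees colder than the week before, in Spring:
d_new <- setNames(numeric(24), summ$term)
d_new["min_temp_lag0_Spring"] <- -4
exp(predict_lnor(beta, d_new))          # OR = 5.247565
classify_alert(exp(predict_lnor(beta, d_new)), th)   # level 5
level_probabilities(draws, d_new, th)
#>  p_level1  p_level2  p_level3  p_level4  p_level5  p_level6
#>     0.005    0.0267    0.0973      0.21    0.2487    0.4123
```

The predicted OR of 5.25 falls in [c₄, c₅) → a level-5 alert, and the
posterior puts ~87% probability on level 4 or above: cold snaps of this
size in Spring are flagged as high risk.

The same pipeline is scriptable: `run_simulate()`, `run_fit()`,
`run_alert()` / `run_all()` read a YAML or JSON configuration and write
CSV/JSON artifacts, and `inst/cli/crossrisk.R` wraps them as a
`simulate|fit|alert|run-all` command-line tool.

See `vignettes/methods.Rmd` for the model, its assumptions, the
synthetic-data generator's scope, and the numerical conventions.

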