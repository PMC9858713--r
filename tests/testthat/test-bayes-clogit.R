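test_that("log-likelihood closed forms hold", {
  d <- make_design(matrix(rnorm(40), ncol = 2))
  expect_equal(clogit_loglik(c(0, 0), d), -20 * log(2))

  one <- make_design(matrix(1, 1, 1, dimnames = list(NULL, "x1")), label = 1L)
  expect_equal(clogit_loglik(log(3), one), log(3 / 4), tolerance = 1e-12)
  expect_equal(clogit_loglik(c(x1 = log(3)), one), log(3 / 4), tolerance = 1e-12)
})

test_that("differenced likelihood equals the brute-force two-day computation", {
  # Oracle: P(case day) = exp(x_case . b) / (exp(x_case . b) + exp(x_ctrl . b))
  # from raw, un-differenced exposures.
  set.seed(71)
  n <- 25L
  x_case <- matrix(rnorm(n * 3, 20, 4), ncol = 3)
  x_ctrl <- matrix(rnorm(n * 3, 20, 4), ncol = 3)
  beta <- c(-0.2, 0.05, 0.1)
  oracle <- sum(vapply(seq_len(n), function(i) {
    e1 <- exp(sum(x_case[i, ] * beta))
    e2 <- exp(sum(x_ctrl[i, ] * beta))
    log(e1 / (e1 + e2))
  }, numeric(1)))
  design <- make_design(x_case - x_ctrl)
  expect_equal(clogit_loglik(beta, design), oracle, tolerance = 1e-10)
})

test_that("log-posterior decomposes into likelihood plus prior and flattens correctly", {
  d <- make_design(matrix(rnorm(60), ncol = 2))
  beta <- c(0.3, -0.2)
  prior <- prior_spec(0, 100)
  expect_equal(
    clogit_logpost(beta, d, prior),
    clogit_loglik(beta, d) + sum(dnorm(beta, 0, 10, log = TRUE))
  )
  # At the prior mean the prior contributes only its normalising constant.
  expect_equal(
    clogit_logpost(c(0, 0), d, prior) - clogit_loglik(c(0, 0), d),
    sum(dnorm(c(0, 0), 0, 10, log = TRUE))
  )
  # Diffuse-prior limit: posterior differences converge to likelihood differences.
  flat <- prior_spec(0, 1e12)
  b2 <- c(-0.1, 0.4)
  expect_equal(
    clogit_logpost(beta, d, flat) - clogit_logpost(b2, d, flat),
    clogit_loglik(beta, d) - clogit_loglik(b2, d),
    tolerance = 1e-8
  )
})

test_that("log-likelihood stays finite for extreme linear predictors", {
  one <- make_design(matrix(1, 1, 1), label = 1L)
  expect_true(is.finite(clogit_loglik(700, one)))
  expect_true(is.finite(clogit_loglik(-700, one)))
  expect_equal(clogit_loglik(-700, one), -700)
})

test_that("the sampler is deterministic in its seed and honours the schedule", {
  d <- make_pair_design(120L)
  s <- small_settings()
  a <- run_mcmc(d, settings = s)
  b <- run_mcmc(d, settings = s)
  expect_identical(a$draws, b$draws)
  expect_equal(nrow(a$draws), retained_draws(s))
  expect_equal(nrow(a$draws), (4000L - 1000L) %/% 3L)
  # Post-burn-in acceptance in a healthy range after adaptation.
  expect_true(all(a$acceptance > 0.1 & a$acceptance < 0.6))
})

test_that("MLE matches the reference conditional-logistic implementation", {
  withr::local_package("survival")
  d <- make_pair_design(400L)
  fit <- fit_clogit_mle(d)
  # 1:1 conditional logistic regression in long format: the index day carries
  # the difference vector, the referent day zeros.
  X <- as.matrix(as.data.frame(d)[, design_terms(d)])
  long <- data.frame(
    y = c(d$label, 1L - d$label),
    x1 = c(X[, 1], numeric(nrow(X))),
    x2 = c(X[, 2], numeric(nrow(X))),
    id = rep(seq_len(nrow(X)), 2)
  )
  ref <- survival::clogit(y ~ x1 + x2 + strata(id), data = long)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
})

test_that("MLE is antisymmetric and the posterior reflects under negation", {
  d <- make_pair_design(300L)
  X <- as.matrix(as.data.frame(d)[, design_terms(d)])
  neg <- make_design(-X, label = d$label)
  fit_pos <- fit_clogit_mle(d)
  fit_neg <- fit_clogit_mle(neg)
  expect_equal(unname(fit_pos$coefficients), -unname(fit_neg$coefficients),
               tolerance = 1e-6)

  draws_pos <- run_mcmc(d, settings = small_settings(seed = 1L))
  draws_neg <- run_mcmc(neg, settings = small_settings(seed = 2L))
  expect_equal(unname(colMeans(draws_pos$draws)),
               -unname(colMeans(draws_neg$draws)), tolerance = 0.05)
})

test_that("MLE recovers zero on null pair-mode data", {
  d <- make_pair_design(1500L, beta_true = c(min_temp_lag0 = 0, ave_rh_lag0 = 0))
  fit <- fit_clogit_mle(d)
  expect_true(all(abs(fit$coefficients) < 3 * fit$se))
})

test_that("posterior mean under a diffuse prior agrees with the MLE", {
  d <- make_pair_design(500L)
  fit <- fit_clogit_mle(d)
  draws <- run_mcmc(d, prior = prior_spec(0, 1e6),
                    settings = small_settings(iterations = 8000L, burnin = 2000L,
                                              thin = 2L))
  post_mean <- colMeans(draws$draws)
  # Agreement within a few posterior-SD-scaled Monte-Carlo errors.
  expect_true(all(abs(post_mean - fit$coefficients) < 4 * fit$se / sqrt(10)))
})

test_that("posterior summaries match closed forms on synthetic draws", {
  set.seed(55)
  S <- 4000L
  sims <- cbind(a = rnorm(S, 0.3, 0.05), b = rnorm(S, -0.1, 0.02))
  d <- make_design(matrix(rnorm(100), ncol = 2,
                          dimnames = list(NULL, c("a", "b"))))
  draws <- structure(
    list(draws = sims, terms = c("a", "b"),
         acceptance = c(a = 0.4, b = 0.4),
         settings = small_settings()),
    class = "posterior_draws"
  )
  summ <- summarize_posterior(draws, d)
  expect_lt(abs(summ$mean[1] - 0.3), 3 * 0.05 / sqrt(S))
  expect_lt(abs(summ$`ci_2.5`[1] - (0.3 - 1.96 * 0.05)), 0.01)
  expect_lt(abs(summ$`ci_97.5`[1] - (0.3 + 1.96 * 0.05)), 0.01)
  expect_equal(attr(summ, "N"), nrow(d))

  # DIC decomposition recomputed by hand from the same draws.
  dev <- apply(sims, 1, function(b) -2 * clogit_loglik(b, d))
  expect_equal(attr(summ, "DIC"),
               2 * mean(dev) - (-2 * clogit_loglik(colMeans(sims), d)),
               tolerance = 1e-8)
})

test_that("identical draws give a degenerate interval and zero effective parameters", {
  d <- make_design(matrix(rnorm(40), ncol = 2,
                          dimnames = list(NULL, c("a", "b"))))
  bhat <- c(a = 0.25, b = -0.4)
  sims <- matrix(rep(bhat, each = 100), ncol = 2, dimnames = list(NULL, c("a", "b")))
  draws <- structure(
    list(draws = sims, terms = c("a", "b"),
         acceptance = c(a = 1, b = 1), settings = small_settings()),
    class = "posterior_draws"
  )
  summ <- summarize_posterior(draws, d)
  expect_equal(summ$`ci_2.5`, unname(bhat))
  expect_equal(summ$`ci_97.5`, unname(bhat))
  expect_equal(attr(summ, "pD"), 0, tolerance = 1e-10)
  expect_equal(attr(summ, "DIC"), -2 * clogit_loglik(bhat, d), tolerance = 1e-10)
})

test_that("degenerate designs are diagnosed", {
  zero_col <- make_design(cbind(x1 = rnorm(30), x2 = 0))
  expect_warning(run_mcmc(zero_col, settings = small_settings(iterations = 200L,
                                                              burnin = 50L, thin = 1L)),
                 "posterior equals the prior")
  all_zero <- make_design(matrix(0, 10, 2))
  expect_error(run_mcmc(all_zero), "no nonzero column")
  expect_error(mcmc_settings(iterations = 100L, burnin = 100L),
               class = "crossrisk_config_error")
  expect_error(mcmc_settings(thin = 0L), class = "crossrisk_config_error")
})
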