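#' Independent Normal prior on the regression coefficients
#'
#' @param mean Prior mean, recycled across coefficients (default 0).
#' @param variance Prior variance, recycled (default 100, i.e. SD 10 -- a
#'   weakly informative prior on the log-odds scale).
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(mean = 0, variance = 100) {
  if (any(!is.finite(mean)) || any(!is.finite(variance)) || any(variance <= 0)) {
    config_error("prior variance must be positive and finite")
  }
  structure(list(mean = mean, variance = variance), class = "prior_spec")
}

#' Metropolis sampler settings
#'
#' The default schedule (60,000 iterations, 10,000 burn-in, thinning 10)
#' retains exactly 5000 posterior draws per coefficient.
#'
#' @param iterations Total MCMC iterations.
#' @param burnin Burn-in iterations discarded (and used for adaptation).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed for the sampling stream.
#' @param init_scale Initial per-coordinate proposal SD.
#' @param target_accept Acceptance rate targeted by burn-in adaptation
#'   (0.44, the component-wise random-walk optimum).
#' @param adapt_window Iterations between adaptation updates during burn-in.
#' @param init Either `"zero"` (deterministic default) or `"mle"`.
#' @return An `mcmc_settings` object.
#' @export
mcmc_settings <- function(iterations = 60000L, burnin = 10000L, thin = 10L,
                          seed = 1L, init_scale = 0.5, target_accept = 0.44,
                          adapt_window = 50L, init = c("zero", "mle")) {
  iterations <- as.integer(iterations); burnin <- as.integer(burnin)
  thin <- as.integer(thin)
  if (burnin >= iterations) config_error("burn-in must be smaller than total iterations")
  if (thin < 1L) config_error("thinning must be >= 1")
  if (!is_scalar_number(init_scale) || init_scale <= 0) {
    config_error("initial proposal scale must be positive")
  }
  structure(
    list(iterations = iterations, burnin = burnin, thin = thin,
         seed = as.integer(seed), init_scale = init_scale,
         target_accept = target_accept, adapt_window = as.integer(adapt_window),
         init = match.arg(init)),
    class = "mcmc_settings"
  )
}

#' Retained draw count implied by a sampler schedule
#'
#' @param settings An [mcmc_settings()].
#' @return `floor((iterations - burnin) / thin)`.
#' @export
retained_draws <- function(settings) {
  (settings$iterations - settings$burnin) %/% settings$thin
}

# Align a coefficient vector with the design's term order. Unnamed vectors
# are accepted positionally.
align_beta <- function(beta, terms) {
  if (length(beta) != length(terms)) {
    stop("coefficient vector length does not match number of design terms")
  }
  if (!is.null(names(beta))) {
    if (!setequal(names(beta), terms)) {
      stop("coefficient names do not match design terms")
    }
    beta <- beta[terms]
  }
  unname(as.numeric(beta))
}

#' Matched-pair conditional log-likelihood
#'
#' For 1:1 self-matched data the conditional likelihood of the case day is
#' an intercept-free logistic model on the case-minus-control difference
#' vectors `d_i`: `sum_i [ y_i * (d_i . beta) - log(1 + exp(d_i . beta)) ]`,
#' with `y_i` the row label (1 for all observed study rows; 0/1 in pair-mode
#' validation data). Evaluated with a log1p/exp guard so it stays finite for
#' linear predictors up to the double overflow range.
#'
#' @param beta Coefficient vector (named by term, or positional).
#' @param design A `matched_design`.
#' @return Scalar log-likelihood.
#' @export
clogit_loglik <- function(beta, design) {
  parts <- design_matrix_parts(design)
  b <- align_beta(beta, parts$terms)
  eta <- drop(parts$X %*% b)
  sum(parts$y * eta - softplus(eta))
}

#' Unnormalised log-posterior
#'
#' Log-likelihood plus the independent Normal log prior density (constants
#' included, so differences and absolute decompositions both hold).
#'
#' @inheritParams clogit_loglik
#' @param prior A [prior_spec()].
#' @return Scalar unnormalised log-posterior.
#' @export
clogit_logpost <- function(beta, design, prior = prior_spec()) {
  terms <- design_terms(design)
  b <- align_beta(beta, terms)
  m <- rep_len(prior$mean, length(b))
  v <- rep_len(prior$variance, length(b))
  clogit_loglik(b, design) + sum(stats::dnorm(b, m, sqrt(v), log = TRUE))
}

#' Sample the posterior by adaptive random-walk Metropolis
#'
#' Component-wise Gaussian random-walk Metropolis on the coefficient vector.
#' Per-coordinate proposal scales are adapted toward `target_accept` during
#' burn-in only and frozen afterwards, preserving detailed balance for the
#' retained draws. Every `thin`-th post-burn-in draw is kept.
#'
#' @param design A `matched_design` (non-empty, at least one nonzero column).
#' @param prior A [prior_spec()].
#' @param settings An [mcmc_settings()].
#' @return A `posterior_draws` object: list with `draws` (retained x P
#'   matrix, columns named by term), `terms`, `acceptance` (per-term
#'   post-burn-in acceptance rates), `scales` and `settings`.
#' @export
run_mcmc <- function(design, prior = prior_spec(), settings = mcmc_settings()) {
  parts <- design_matrix_parts(design)
  X <- parts$X; y <- parts$y; terms <- parts$terms
  n <- nrow(X); P <- ncol(X)
  if (n == 0L) stop("design is empty")
  col_sd <- apply(X, 2, function(col) max(abs(col)))
  if (all(col_sd == 0)) stop("design has no nonzero column")
  if (any(col_sd == 0)) {
    warning(sprintf(
      "all-zero design column(s) %s: their posterior equals the prior",
      paste(terms[col_sd == 0], collapse = ", ")
    ))
  }

  pm <- rep_len(prior$mean, P)
  pv <- rep_len(prior$variance, P)

  beta <- numeric(P)
  if (settings$init == "mle") {
    beta <- unname(fit_clogit_mle(design)$coefficients)
  }
  eta <- drop(X %*% beta)
  ll <- sum(y * eta - softplus(eta))
  if (!is.finite(ll)) stop("non-finite log-likelihood at the initial state")

  total <- settings$iterations
  burn <- settings$burnin
  thin <- settings$thin
  n_keep <- retained_draws(settings)
  draws <- matrix(NA_real_, nrow = n_keep, ncol = P,
                  dimnames = list(NULL, terms))
  scales <- rep(settings$init_scale, P)
  acc_win <- integer(P)
  acc_post <- integer(P)
  keep_i <- 0L
  Xcols <- lapply(seq_len(P), function(j) X[, j])

  with_rng_seed(settings$seed, {
    for (iter in seq_len(total)) {
      for (j in seq_len(P)) {
        prop_j <- beta[j] + scales[j] * stats::rnorm(1)
        eta_prop <- eta + (prop_j - beta[j]) * Xcols[[j]]
        ll_prop <- sum(y * eta_prop - softplus(eta_prop))
        if (!is.finite(ll_prop)) next
        log_ratio <- (ll_prop - ll) +
          stats::dnorm(prop_j, pm[j], sqrt(pv[j]), log = TRUE) -
          stats::dnorm(beta[j], pm[j], sqrt(pv[j]), log = TRUE)
        if (log(stats::runif(1)) < log_ratio) {
          beta[j] <- prop_j
          eta <- eta_prop
          ll <- ll_prop
          if (iter <= burn) acc_win[j] <- acc_win[j] + 1L else acc_post[j] <- acc_post[j] + 1L
        }
      }
      if (iter <= burn && iter %% settings$adapt_window == 0L) {
        rate <- acc_win / settings$adapt_window
        scales <- pmin(pmax(scales * exp(2 * (rate - settings$target_accept)),
                            1e-6), 1e3)
        acc_win[] <- 0L
      }
      if (iter > burn && (iter - burn) %% thin == 0L) {
        keep_i <- keep_i + 1L
        if (keep_i <= n_keep) draws[keep_i, ] <- beta
      }
    }
  })

  structure(
    list(draws = draws, terms = terms,
         acceptance = stats::setNames(acc_post / (total - burn), terms),
         scales = stats::setNames(scales, terms), settings = settings),
    class = "posterior_draws"
  )
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf(
    "Posterior draws: %d retained x %d terms (acceptance %.2f-%.2f)\n",
    nrow(x$draws), length(x$terms), min(x$acceptance), max(x$acceptance)
  ))
  invisible(x)
}

# Deviance -2 * loglik of each draw, computed in chunks to bound memory.
draw_deviances <- function(draws, design, chunk = 500L) {
  parts <- design_matrix_parts(design)
  B <- draws$draws[, parts$terms, drop = FALSE]
  S <- nrow(B)
  out <- numeric(S)
  for (s0 in seq(1L, S, by = chunk)) {
    s1 <- min(s0 + chunk - 1L, S)
    ETA <- parts$X %*% t(B[s0:s1, , drop = FALSE])
    out[s0:s1] <- -2 * colSums(parts$y * ETA - softplus(ETA))
  }
  out
}

#' Summarise posterior draws
#'
#' Per-term posterior mean and equal-tailed 95% credible interval, plus the
#' deviance information criterion
#' `DIC = 2 * mean(D(beta_s)) - D(mean(beta))` with deviance
#' `D(beta) = -2 * loglik(beta)`, and the number of events N.
#'
#' @param draws A `posterior_draws` object.
#' @param design The `matched_design` the draws were fitted to.
#' @return A `posterior_summary`: data frame with columns `term`, `mean`,
#'   `ci_2.5`, `ci_97.5` and attributes `N`, `DIC`, `pD`, `Dbar`.
#' @export
summarize_posterior <- function(draws, design) {
  stopifnot(inherits(draws, "posterior_draws"))
  B <- draws$draws
  if (nrow(B) == 0L) stop("no retained draws to summarise")
  est <- colMeans(B)
  qs <- apply(B, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  dev <- draw_deviances(draws, design)
  Dbar <- mean(dev)
  Dhat <- -2 * clogit_loglik(est, design)
  out <- data.frame(
    term = draws$terms,
    mean = unname(est),
    `ci_2.5` = qs[1L, ],
    `ci_97.5` = qs[2L, ],
    check.names = FALSE
  )
  rownames(out) <- NULL
  structure(out,
            N = nrow(design), DIC = 2 * Dbar - Dhat, pD = Dbar - Dhat, Dbar = Dbar,
            class = c("posterior_summary", "data.frame"))
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("Bayesian conditional logistic regression (N = %d, DIC = %.1f)\n",
              attr(x, "N"), attr(x, "DIC")))
  NextMethod()
}

#' Conditional-likelihood maximum-likelihood fit
#'
#' Maximises [clogit_loglik()] by quasi-Newton (BFGS) iteration with the
#' analytic gradient; equivalent to an intercept-free logistic regression of
#' the row labels on the differenced covariates. Used as a frequentist
#' cross-check of the Bayesian fit (the two agree under a diffuse prior).
#'
#' @param design A `matched_design`, full rank on its nonzero columns.
#' @return A `clogit_mle` list: `coefficients` (named), `se`, `vcov`,
#'   `loglik`, `converged`, `separation` (logical flag, with a warning when
#'   quasi-separation pushes a coefficient beyond +-15).
#' @export
fit_clogit_mle <- function(design) {
  parts <- design_matrix_parts(design)
  X <- parts$X; y <- parts$y
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - softplus(eta))
  }
  grad <- function(b) {
    eta <- drop(X %*% b)
    drop(crossprod(X, stats::plogis(eta) - y))
  }
  opt <- stats::optim(numeric(ncol(X)), nll, grad, method = "BFGS",
                      hessian = TRUE, control = list(maxit = 500, reltol = 1e-12))
  beta <- stats::setNames(opt$par, parts$terms)
  separation <- any(abs(beta) > 15)
  if (separation) {
    warning("possible separation: coefficient magnitude exceeds 15; estimates unreliable")
  }
  vc <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(vc) <- list(parts$terms, parts$terms)
  structure(
    list(coefficients = beta, se = sqrt(pmax(diag(vc), 0)), vcov = vc,
         loglik = -opt$value, converged = opt$convergence == 0L,
         separation = separation),
    class = "clogit_mle"
  )
}

#' @export
print.clogit_mle <- function(x, ...) {
  cat("Conditional logistic MLE (intercept-free logistic on differences)\n")
  print(data.frame(term = names(x$coefficients),
                   estimate = unname(x$coefficients), se = unname(x$se)))
  invisible(x)
}
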