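# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so simulation calls do not perturb each other.
with_rng_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (is.null(old)) {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  } else {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# log(1 + exp(eta)) without overflow for |eta| up to the double range.
softplus <- function(eta) {
  pmax(eta, 0) + log1p(exp(-abs(eta)))
}

config_error <- function(msg) {
  stop(errorCondition(msg, class = c("crossrisk_config_error", "error")))
}

stop_window <- function(msg) {
  stop(errorCondition(msg, class = c("crossrisk_window_error", "error")))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
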