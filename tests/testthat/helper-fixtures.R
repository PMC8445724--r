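# Small reproducible count-data problems used across the suite.

rand_problem <- function(n = 30, p = 2, seed = 1, rho2 = 0, beta0 = 0.5,
                         beta_sd = 0.4) {
  set.seed(seed)
  X <- gen_regressors(n, p, rho2)
  beta <- stats::rnorm(p, 0, beta_sd)
  y <- stats::rpois(n, exp(beta0 + drop(X %*% beta)))
  colnames(X) <- paste0("x", seq_len(p))
  dplyr::bind_cols(tibble::tibble(y = y), tibble::as_tibble(X))
}

rand_fit <- function(...) poisson_fit(rand_problem(...), response = y)

# intercept-only data with constant counts: every residual is exactly zero
flat_data <- function(n = 8, value = 3) tibble::tibble(y = rep(value, n))

football <- function() english_league()

expect_same_vec <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(a - b)), tol)
}
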