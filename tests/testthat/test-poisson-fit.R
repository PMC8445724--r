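test_that("intercept-only fit recovers the closed-form solution", {
  fit <- poisson_fit(flat_data(4, 3), response = y)
  expect_equal(unname(coef(fit)), log(3), tolerance = 1e-10)
  expect_equal(unname(fitted(fit)), rep(3, 4), tolerance = 1e-10)
  expect_true(fit$converged)
  expect_equal(fit$weights, fit$mu)
})

test_that("IRLS agrees with stats::glm on random problems", {
  for (s in 1:20) {
    dat <- rand_problem(n = 25 + s, p = 1 + s %% 3, seed = s, rho2 = 0.3)
    fit <- poisson_fit(dat, response = y)
    ora <- stats::glm(y ~ ., data = dat, family = stats::poisson())
    expect_equal(unname(coef(fit)), unname(coef(ora)), tolerance = 1e-6)
    expect_equal(fit$deviance, unname(ora$deviance), tolerance = 1e-6)
  }
})

test_that("IRLS solution maximizes the log-likelihood (independent optimizer)", {
  dat <- rand_problem(n = 30, p = 2, seed = 42)
  fit <- poisson_fit(dat, response = y)
  X <- cbind(1, as.matrix(dat[c("x1", "x2")]))
  y <- dat$y
  nll <- function(b) -sum(y * drop(X %*% b) - exp(drop(X %*% b)) - lgamma(y + 1))
  grad <- function(b) -drop(crossprod(X, y - exp(drop(X %*% b))))
  opt <- stats::optim(c(0, 0, 0), nll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-15))
  expect_equal(unname(coef(fit)), opt$par, tolerance = 1e-6)
})

test_that("IRLS is a self-consistent fixed point of the weighted solve", {
  fit <- rand_fit(n = 40, p = 3, seed = 7)
  X <- fit$design
  mu <- exp(drop(X %*% coef(fit)))
  z <- log(mu) + (fit$y - mu) / mu
  beta_once <- solve(crossprod(X, mu * X), crossprod(X, mu * z))
  expect_equal(unname(coef(fit)), unname(drop(beta_once)), tolerance = 1e-7)
})

test_that("hat matrix is a projection with trace p + 1", {
  fit <- rand_fit(n = 25, p = 2, seed = 3)
  H <- hat_matrix(fit)
  expect_equal(sum(diag(H)), fit$p + 1, tolerance = 1e-9)
  expect_lt(max(abs(H %*% H - H)), 1e-8)
  expect_lt(max(abs(H - t(H))), 1e-12)
  h <- hatvalues(fit)
  expect_true(all(h >= 0 & h <= 1))
  expect_equal(unname(diag(H)), unname(h), tolerance = 1e-12)
})

test_that("leverages match a dense element-wise evaluation on a toy fit", {
  dat <- rand_problem(n = 5, p = 1, seed = 11)
  fit <- poisson_fit(dat, response = y)
  W <- diag(fit$mu)
  X <- fit$design
  H_dense <- sqrt(W) %*% X %*% solve(t(X) %*% W %*% X) %*% t(X) %*% sqrt(W)
  expect_equal(unname(hatvalues(fit)), unname(diag(H_dense)), tolerance = 1e-10)
})

test_that("residual identities hold, including zero counts", {
  dat <- rand_problem(n = 40, p = 2, seed = 5, beta0 = -0.5) # guarantees some y = 0
  expect_true(any(dat$y == 0))
  fit <- poisson_fit(dat, response = y)
  d <- residuals(fit, "deviance")
  expect_equal(sum(d^2), fit$deviance, tolerance = 1e-10)
  expect_true(all(sign(d) == sign(fit$y - fit$mu) | d == 0))
  chi <- residuals(fit, "pearson")
  expect_equal(chi, (fit$y - fit$mu) / sqrt(fit$mu))
  expect_equal(residuals(fit, "pearson_raw"), (fit$y - fit$mu) / fit$mu)
  expect_equal(residuals(fit, "standardized"),
               chi / sqrt(1 - hatvalues(fit)))
})

test_that("deviance equals the likelihood-ratio against the saturated model", {
  dat <- rand_problem(n = 12, p = 1, seed = 9)
  fit <- poisson_fit(dat, response = y)
  y <- dat$y
  ll_sat <- sum(ifelse(y == 0, 0, y * log(y)) - y - lgamma(y + 1))
  expect_equal(fit$deviance, 2 * (ll_sat - fit$loglik), tolerance = 1e-9)
})

test_that("zero-residual fits give identically zero residuals", {
  fit <- poisson_fit(flat_data(6, 4), response = y)
  for (type in c("pearson", "standardized", "deviance")) {
    expect_equal(residuals(fit, type), rep(0, 6))
  }
})

test_that("observation order does not matter", {
  dat <- rand_problem(n = 20, p = 2, seed = 13)
  fit <- poisson_fit(dat, response = y)
  set.seed(1)
  perm <- sample(20)
  fitp <- poisson_fit(dat[perm, ], response = y)
  expect_equal(coef(fitp), coef(fit), tolerance = 1e-9)
  expect_equal(hatvalues(fitp), hatvalues(fit)[perm], tolerance = 1e-9)
  expect_equal(residuals(fitp, "standardized"),
               residuals(fit, "standardized")[perm], tolerance = 1e-9)
})

test_that("non-convergence is an explicit state, not a silent answer", {
  dat <- rand_problem(n = 30, p = 2, seed = 2)
  expect_warning(fit <- poisson_fit(dat, response = y, max_iter = 1),
                 "did not converge")
  expect_false(fit$converged)
  expect_type(fit$coefficients, "double") # last iterate is carried
  expect_error(hatvalues(fit), class = "liudiag_not_converged")
})

test_that("input validation rejects bad responses and designs", {
  expect_error(poisson_fit(tibble::tibble(y = c(-1, 2, 3), x = 1:3), y),
               "nonnegative")
  expect_error(poisson_fit(tibble::tibble(y = c(1.5, 2, 3), x = 1:3), y),
               "integer")
  expect_error(poisson_fit(tibble::tibble(y = 1:3, x = c(1, NA, 3)), y),
               "non-finite")
  expect_error(poisson_fit(tibble::tibble(y = 1:3, x1 = 1:3, x2 = 3:1), y),
               "degrees of freedom")
})

test_that("condition index: orthogonal centred design gives 1, duplicates error", {
  X <- stats::contr.helmert(6) # centred, mutually orthogonal columns
  dat <- tibble::tibble(y = rep(2L, 6), as.data.frame(X) |>
                          stats::setNames(paste0("x", 1:5)))
  expect_equal(condition_index(dat, response = y, convention = "correlation"), 1,
               tolerance = 1e-9)
  dat2 <- tibble::tibble(y = rep(2L, 6), x1 = rnorm(6))
  dat2$x2 <- dat2$x1
  expect_error(condition_index(dat2, response = y), class = "liudiag_collinear")
})

test_that("condition index conventions match direct eigen computations", {
  dat <- football()
  X <- as.matrix(dat[paste0("x", 1:5)])
  ci_of <- function(M) {
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    sqrt(max(ev) / min(ev))
  }
  expect_equal(condition_index(dat, y, "correlation"), ci_of(cor(X)),
               tolerance = 1e-12)
  expect_equal(condition_index(dat, y, "correlation_all"),
               ci_of(cor(cbind(dat$y, X))), tolerance = 1e-12)
  expect_equal(condition_index(dat, y, "raw"), ci_of(crossprod(cbind(1, X))),
               tolerance = 1e-12)
  fit <- poisson_fit(dat, y)
  expect_equal(condition_index(dat, y, "weighted"),
               ci_of(crossprod(fit$design, fit$weights * fit$design)),
               tolerance = 1e-10)
  expect_gt(condition_index(dat, y), 1)
})

test_that("tidy, glance and augment return well-formed tibbles", {
  fit <- rand_fit(n = 30, p = 2, seed = 21)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 3)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$nobs, 30)
  au <- augment(fit)
  expect_equal(nrow(au), 30)
  expect_true(all(c(".fitted", ".resid", ".hat") %in% names(au)))
})
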