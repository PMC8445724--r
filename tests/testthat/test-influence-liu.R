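test_that("SMW rank-one update reproduces the brute-force deleted inverse", {
  # the engine behind the Liu one-step deletion, checked directly
  set.seed(77)
  for (r in 1:50) {
    n <- sample(6:12, 1)
    q <- sample(2:4, 1)
    K <- matrix(stats::rnorm(n * q), n, q)
    B <- crossprod(K) + diag(q)
    Binv <- solve(B)
    i <- sample(n, 1)
    k <- K[i, ]
    m_di <- drop(t(k) %*% Binv %*% k)
    smw <- Binv + (Binv %*% k %*% t(k) %*% Binv) / (1 - m_di)
    brute <- solve(crossprod(K[-i, , drop = FALSE]) + diag(q))
    expect_lt(max(abs(smw - brute)), 1e-10)
  }
})

test_that("exact Liu one-step matches brute-force deletion of the frozen problem", {
  dat <- rand_problem(n = 10, p = 2, seed = 51, rho2 = 0.6)
  fit <- poisson_fit(dat, response = y)
  X <- fit$design
  W <- fit$weights
  z <- fit$working
  A <- crossprod(X, W * X)
  for (d in c(0, 0.3, 1)) {
    lf <- liu_fit(fit, d = d)
    bd <- coef(lf)
    for (i in 1:10) {
      Xi <- X[-i, , drop = FALSE]
      Wi <- W[-i]
      Ai <- crossprod(Xi, Wi * Xi)
      bml_i <- solve(Ai, crossprod(Xi, Wi * z[-i]))
      bdi <- drop(solve(Ai + diag(3), (Ai + d * diag(3)) %*% bml_i))
      expect_same_vec(one_step_delete(lf, i), bd - bdi, tol = 1e-10)
    }
  }
  # at d = 1 the Liu one-step is exactly the ML one-step
  lf1 <- liu_fit(fit, d = 1)
  for (i in c(2, 7)) {
    expect_same_vec(one_step_delete(lf1, i), one_step_delete(fit, i),
                    tol = 1e-10)
  }
})

test_that("collapsed Liu one-step equals its rank-one closed form", {
  dat <- rand_problem(n = 10, p = 2, seed = 51, rho2 = 0.6)
  fit <- poisson_fit(dat, response = y)
  lf <- liu_fit(fit, d = 0.3)
  X <- fit$design
  A <- crossprod(X, fit$weights * X)
  chi_d <- residuals(lf, "pearson")
  for (i in 1:10) {
    # (A + I - w_i x_i x_i')^{-1} x_i sqrt(w_i) chi_di == Eq with 1/(1 - m_di)
    brute <- drop(solve(A + diag(3) - fit$weights[i] * tcrossprod(X[i, ]),
                        X[i, ])) * sqrt(fit$weights[i]) * chi_d[i]
    expect_same_vec(one_step_delete(lf, i, method = "collapsed"), brute,
                    tol = 1e-10)
  }
  # a zero Liu residual gives a zero collapsed change vector
  zr <- chi_d * 0
  expect_equal(unname(liudiag:::delta_beta_onestep(solve(A + diag(3)),
                                                   X[1, ], fit$weights[1],
                                                   0, 0.4, NULL)),
               rep(0, 3))
})

test_that("deletion leverages are ordered 0 <= m_del < m < 1", {
  lf <- liu_fit(rand_fit(n = 30, p = 3, seed = 52, rho2 = 0.9), d = 0.5)
  dl <- deletion_leverages(lf)
  expect_true(all(dl$m_del >= 0))
  expect_true(all(dl$m_del < dl$m))
  expect_true(all(dl$m < 1))
  expect_equal(dl$m, unname(hatvalues(lf$base_fit)), tolerance = 1e-10)
})

test_that("every Liu diagnostic reduces to its ML counterpart at d = 1", {
  fit <- rand_fit(n = 30, p = 2, seed = 53, rho2 = 0.8)
  lf <- liu_fit(fit, d = 1)
  expect_equal(cooks.distance(lf), cooks.distance(fit), tolerance = 1e-9)
  expect_equal(delta_chisq(lf), delta_chisq(fit), tolerance = 1e-9)
  expect_equal(delta_deviance(lf), delta_deviance(fit), tolerance = 1e-9)
  expect_equal(dffits_stat(lf), dffits_stat(fit), tolerance = 1e-9)
  expect_equal(hatvalues(lf), hatvalues(fit), tolerance = 1e-10)
})

test_that("all Liu diagnostics are continuous in d near 1", {
  fit <- rand_fit(n = 30, p = 2, seed = 54, rho2 = 0.8)
  a <- liu_fit(fit, d = 1)
  b <- liu_fit(fit, d = 1 - 1e-6)
  expect_equal(cooks.distance(b), cooks.distance(a), tolerance = 1e-4)
  expect_equal(delta_chisq(b), delta_chisq(a), tolerance = 1e-4)
  expect_equal(delta_deviance(b), delta_deviance(a), tolerance = 1e-4)
  expect_equal(dffits_stat(b), dffits_stat(a), tolerance = 1e-4)
})

test_that("Liu Cook's distance: displacement and sandwich forms behave", {
  lf <- liu_fit(rand_fit(n = 20, p = 2, seed = 55, rho2 = 0.7), d = 0.4)
  base <- lf$base_fit
  X <- base$design
  A <- crossprod(X, base$weights * X)
  # dense oracle for the displacement form
  oracle <- vapply(1:20, function(i) {
    db <- one_step_delete(lf, i)
    drop(t(db) %*% A %*% db) / 3
  }, numeric(1))
  expect_same_vec(cooks.distance(lf, "displacement"), oracle, tol = 1e-10)
  # sandwich oracle
  Ip <- diag(3)
  S <- solve(A + lf$d * Ip) %*% (A + Ip)
  M <- t(S) %*% A %*% S
  oracle2 <- vapply(1:20, function(i) {
    db <- one_step_delete(lf, i)
    drop(t(db) %*% M %*% db) / 3
  }, numeric(1))
  expect_same_vec(cooks.distance(lf, "sandwich"), oracle2, tol = 1e-10)
  # the two coincide at d = 1
  lf1 <- liu_fit(lf$base_fit, d = 1)
  expect_same_vec(cooks.distance(lf1, "displacement"),
                  cooks.distance(lf1, "sandwich"), tol = 1e-9)
})

test_that("zero Liu residual implies zero influence on every measure", {
  fit <- poisson_fit(flat_data(8, 5), response = y)
  lf <- liu_fit(fit, d = 1) # mu_d = y exactly: all residuals zero
  tab <- influence_table(lf)
  expect_equal(tab$cook, rep(0, 8))
  expect_equal(tab$delta_chisq, rep(0, 8))
  expect_equal(tab$delta_dev, rep(0, 8))
  expect_equal(tab$dffits, rep(0, 8))
})

test_that("Liu influence tables carry d metadata and the deletion leverage", {
  lf <- liu_fit(poisson_fit(football(), response = y), d = "d1")
  tab <- influence_table(lf)
  expect_identical(attr(tab, "estimator"), "Liu")
  expect_identical(attr(tab, "d_rule"), "d1")
  expect_equal(attr(tab, "d"), lf$d)
  expect_true("m_del" %in% names(tab))
  expect_true(all(tab$m_del <= tab$h | tab$m_del < hatvalues(lf$base_fit)))
})
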