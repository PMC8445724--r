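#' Fit a Poisson log-linear model by iteratively reweighted least squares
#'
#' Fits the Poisson regression model \eqn{y_i \sim \mathrm{Pois}(\mu_i)},
#' \eqn{\log \mu_i = x_i'\beta}, by Fisher scoring: repeated weighted
#' least-squares solves with canonical-link weights \eqn{\hat W =
#' \mathrm{diag}(\hat\mu_i)} and working response \eqn{\hat z_i = \log\hat\mu_i
#' + (y_i - \hat\mu_i)/\hat\mu_i}, iterated to a fixed point of
#' \eqn{\hat\beta = (X'\hat WX)^{-1}X'\hat W\hat z}.
#'
#' Starting values use \eqn{\hat\mu^{(0)}_i = y_i + 0.5} so zero counts are
#' safe under the log link. Convergence is declared when the largest absolute
#' coefficient change falls below `tol`. On non-convergence the last iterate is
#' returned with `converged = FALSE` and a warning, never silently.
#'
#' @param data Data frame holding the count response and numeric regressors
#'   (every non-response column is used as a regressor).
#' @param response Count response column (bare name or string).
#' @param intercept Include an intercept as the first coefficient (default
#'   `TRUE`).
#' @param tol Convergence tolerance on the max absolute coefficient change.
#' @param max_iter Maximum Fisher-scoring iterations.
#' @return An object of class `poisson_fit`: coefficients (intercept first),
#'   fitted means `mu`, IRLS weights (`= mu`), working response, log-likelihood,
#'   deviance, iteration count and convergence flag, plus the design matrix.
#' @examples
#' fit <- poisson_fit(english_league(), response = y)
#' coef(fit)
#' glance(fit)
#' @seealso [liu_fit()] for the shrinkage estimator, [influence_table()] for
#'   case-deletion diagnostics.
#' @export
poisson_fit <- function(data, response, intercept = TRUE,
                        tol = 1e-8, max_iter = 50L) {
  md <- build_design(data, {{ response }}, intercept = intercept)
  fit <- irls(md$y, md$X, tol = tol, max_iter = max_iter)
  structure(
    c(fit, md[c("xnames", "response_name", "intercept", "n", "p")]),
    class = "poisson_fit"
  )
}

# Fisher scoring for the Poisson log link. X is the full design
# (intercept column already present when requested).
irls <- function(y, X, tol = 1e-8, max_iter = 50L) {
  stopifnot(tol > 0, max_iter >= 1L)
  n <- length(y)
  mu <- y + 0.5
  beta <- numeric(ncol(X))
  converged <- FALSE
  ll_prev <- -Inf
  iter <- 0L
  z <- log(mu)
  repeat {
    iter <- iter + 1L
    z <- log(mu) + (y - mu) / mu
    A <- crossprod(X, mu * X)
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) {
      rlang::abort("Weighted cross-product X'WX is rank deficient.",
                   class = "liudiag_rank_deficient")
    }
    beta_new <- drop(backsolve(R, backsolve(R, crossprod(X, mu * z),
                                            transpose = TRUE)))
    step <- max(abs(beta_new - beta))
    beta <- beta_new
    eta <- drop(X %*% beta)
    if (max(eta) > 700) {
      # diverging linear predictor: exp() would overflow
      break
    }
    mu <- exp(eta)
    ll <- poisson_loglik(y, mu)
    if (ll < ll_prev - 1e-8 * (abs(ll_prev) + 1)) {
      rlang::warn("Log-likelihood decreased during IRLS; fit may be unstable.")
    }
    ll_prev <- ll
    if (step < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  if (!converged) {
    rlang::warn(sprintf("IRLS did not converge in %d iterations.", iter))
  }
  names(beta) <- colnames(X)
  list(
    coefficients = beta,
    mu = mu,
    weights = mu,
    working = z,
    design = X,
    y = y,
    loglik = poisson_loglik(y, mu),
    deviance = poisson_deviance(y, mu),
    n_iter = iter,
    converged = converged,
    tol = tol
  )
}

poisson_loglik <- function(y, mu) {
  sum(y * log(mu) - mu - lgamma(y + 1))
}

# Unit deviances use the y log(y/mu) -> 0 convention at y = 0.
poisson_unit_deviance <- function(y, mu) {
  ylogy <- ifelse(y == 0, 0, y * log(y / mu))
  pmax(2 * (ylogy - (y - mu)), 0)
}

poisson_deviance <- function(y, mu) {
  sum(poisson_unit_deviance(y, mu))
}

stop_if_not_converged <- function(fit) {
  if (!isTRUE(fit$converged)) {
    rlang::abort("Fit did not converge; diagnostics are not available.",
                 class = "liudiag_not_converged")
  }
  invisible(fit)
}

#' Hat matrix of a fitted model
#'
#' For the maximum-likelihood fit this is the weighted projection
#' \eqn{H = \hat W^{1/2}X(X'\hat WX)^{-1}X'\hat W^{1/2}} (symmetric and
#' idempotent, trace = number of coefficients). For a Liu fit see
#' [hat_matrix.liu_fit()].
#'
#' @param fit A `poisson_fit` or `liu_fit` object.
#' @param ... Unused.
#' @return An n-by-n matrix.
#' @export
hat_matrix <- function(fit, ...) UseMethod("hat_matrix")

#' @rdname hat_matrix
#' @export
hat_matrix.poisson_fit <- function(fit, ...) {
  stop_if_not_converged(fit)
  K <- sqrt(fit$weights) * fit$design
  A <- crossprod(K)
  H <- K %*% solve(A, t(K))
  (H + t(H)) / 2
}

#' @export
hatvalues.poisson_fit <- function(model, ...) {
  stop_if_not_converged(model)
  K <- sqrt(model$weights) * model$design
  A <- crossprod(K)
  h <- rowSums((K %*% solve(A)) * K)
  pmin(pmax(h, 0), 1)
}

#' @export
coef.poisson_fit <- function(object, ...) object$coefficients

#' @export
fitted.poisson_fit <- function(object, ...) object$mu

#' @export
logLik.poisson_fit <- function(object, ...) {
  structure(object$loglik,
            df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' Residuals for a Poisson IRLS fit
#'
#' `"pearson"` is \eqn{(y_i-\hat\mu_i)/\sqrt{\hat\mu_i}}, `"standardized"`
#' divides further by \eqn{\sqrt{1-h_{ii}}}, `"deviance"` is the signed root of
#' the unit deviance, and `"jackknife"` applies the rescaling
#' \eqn{t_i = \chi_i'\sqrt{(n-p-1)/(n-p-\chi_i'^2)}} to the standardized
#' Pearson residual (reported as `Inf` with the sign of the residual when the
#' radicand is non-positive). `"pearson_raw"` is the ratio
#' \eqn{(y_i-\hat\mu_i)/\hat\mu_i}, kept as an accessor because some accounts
#' of the Poisson Pearson residual print the unsquare-rooted denominator; the
#' square-root form is the one whose sum of squares is the Pearson statistic
#' and is used everywhere downstream.
#'
#' Observations with \eqn{h_{ii} = 1} get an infinite standardized residual
#' (flagged value, not an error).
#'
#' @param object A `poisson_fit`.
#' @param type One of `"pearson"`, `"standardized"`, `"deviance"`,
#'   `"jackknife"`, `"pearson_raw"`, `"response"`, `"working"`.
#' @param ... Unused.
#' @return Numeric vector of length n.
#' @export
residuals.poisson_fit <- function(object,
                                  type = c("pearson", "standardized",
                                           "deviance", "jackknife",
                                           "pearson_raw", "response",
                                           "working"),
                                  ...) {
  type <- match.arg(type)
  stop_if_not_converged(object)
  y <- object$y
  mu <- object$mu
  switch(type,
    response = y - mu,
    working = object$working - log(mu),
    pearson = (y - mu) / sqrt(mu),
    pearson_raw = (y - mu) / mu,
    standardized = standardized_pearson(y, mu, hatvalues(object)),
    deviance = sign(y - mu) * sqrt(poisson_unit_deviance(y, mu)),
    jackknife = jackknife_pearson(
      standardized_pearson(y, mu, hatvalues(object)), object$n, object$p
    )
  )
}

standardized_pearson <- function(y, mu, h) {
  chi <- (y - mu) / sqrt(mu)
  out <- ifelse(h < 1, chi / sqrt(pmax(1 - h, 0)), Inf * sign(chi))
  out[h >= 1 & chi == 0] <- 0
  out
}

# t_i = chi'_i sqrt((n - p - 1)/(n - p - chi'^2)); infinite when the
# radicand closes (treated downstream as an infinite-influence flag).
jackknife_pearson <- function(chs, n, p) {
  rad <- n - p - chs^2
  out <- Inf * sign(chs)
  pos <- is.finite(rad) & rad > 0
  out[pos] <- chs[pos] * sqrt((n - p - 1) / rad[pos])
  out
}

#' @export
print.poisson_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Poisson regression fit by IRLS (n = %d, p = %d)\n", x$n, x$p))
  print(round(x$coefficients, digits))
  cat(sprintf("deviance: %.4g  logLik: %.4g  iterations: %d%s\n",
              x$deviance, x$loglik, x$n_iter,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @method tidy poisson_fit
#' @export
tidy.poisson_fit <- function(x, ...) {
  A <- crossprod(x$design, x$weights * x$design)
  se <- sqrt(diag(solve(A)))
  est <- x$coefficients
  stat <- est / se
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = 2 * stats::pnorm(-abs(unname(stat)))
  )
}

#' @method glance poisson_fit
#' @export
glance.poisson_fit <- function(x, ...) {
  tibble::tibble(
    nobs = x$n,
    df.residual = x$n - length(x$coefficients),
    deviance = x$deviance,
    logLik = x$loglik,
    AIC = -2 * x$loglik + 2 * length(x$coefficients),
    n_iter = x$n_iter,
    converged = x$converged
  )
}

#' @method augment poisson_fit
#' @export
augment.poisson_fit <- function(x, ...) {
  tibble::tibble(
    !!x$response_name := x$y,
    tibble::as_tibble(x$design[, setdiff(colnames(x$design), "(Intercept)"),
                               drop = FALSE]),
    .fitted = x$mu,
    .resid = residuals(x, "pearson"),
    .std.resid = residuals(x, "standardized"),
    .hat = hatvalues(x)
  )
}

#' Condition index of a regressor set
#'
#' Computes \eqn{\mathrm{CI} = \sqrt{\lambda_{\max}/\lambda_{\min}}} of a
#' cross-product matrix as a collinearity screen; values above roughly 10--30
#' indicate moderate to severe collinearity. Several scaling conventions are
#' in circulation, so the convention is explicit:
#'
#' * `"correlation"` (default): correlation matrix of the regressors
#'   (centred and scaled, no intercept);
#' * `"correlation_all"`: correlation matrix of the response *and* the
#'   regressors — the convention under which the bundled football data most
#'   nearly reproduce the condition index reported for them (see the package
#'   vignette);
#' * `"raw"`: \eqn{X'X} with an intercept column, unscaled;
#' * `"weighted"`: \eqn{X'\hat WX} at the converged ML fit (intercept
#'   included).
#'
#' @param data Data frame with the regressors (and the response when a
#'   convention needs it).
#' @param response Response column; required for `"correlation_all"` and
#'   `"weighted"`, otherwise excluded from the regressor block if present.
#' @param convention Scaling convention, see above.
#' @return A single number, `>= 1`.
#' @examples
#' condition_index(english_league(), response = y)
#' condition_index(english_league(), response = y, convention = "correlation_all")
#' @export
condition_index <- function(data, response = NULL,
                            convention = c("correlation", "correlation_all",
                                           "raw", "weighted")) {
  convention <- match.arg(convention)
  resp_quo <- rlang::enquo(response)
  has_resp <- !rlang::quo_is_null(resp_quo)
  resp <- if (has_resp) rlang::as_name(resp_quo) else NULL
  if (convention %in% c("correlation_all", "weighted") && !has_resp) {
    rlang::abort(sprintf("`response` is required for convention '%s'.", convention))
  }
  Xall <- as.matrix(data[setdiff(names(data), resp)])
  storage.mode(Xall) <- "double"
  M <- switch(convention,
    correlation = stats::cor(Xall),
    correlation_all = stats::cor(cbind(data[[resp]], Xall)),
    raw = crossprod(cbind(1, Xall)),
    weighted = {
      fit <- poisson_fit(data, response = !!resp_quo, intercept = TRUE)
      crossprod(fit$design, fit$weights * fit$design)
    }
  )
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-12) {
    rlang::abort("Cross-product matrix is (numerically) singular: exact collinearity.",
                 class = "liudiag_collinear")
  }
  sqrt(max(ev) / min(ev))
}
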