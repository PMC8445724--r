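#' Liu shrinkage estimator for a fitted Poisson regression
#'
#' Applies the Liu estimator
#' \deqn{\hat\beta_d = (X'\hat WX + I)^{-1}(X'\hat WX + dI)\,\hat\beta_{ML},
#'   \qquad 0 \le d \le 1,}
#' to a converged IRLS fit. The weight matrix \eqn{\hat W} is frozen at the ML
#' solution: the estimator is a one-shot linear transform of
#' \eqn{\hat\beta_{ML}}, not a re-iterated fit. `d = 1` returns the ML
#' coefficients exactly; `d = 0` gives the strongest shrinkage. In the rotated
#' eigenbasis of \eqn{X'\hat WX} each component is scaled by
#' \eqn{(\lambda_j + d)/(\lambda_j + 1)}.
#'
#' By default the transform acts on all coefficients including the intercept
#' (the design matrix in the estimator is the full design); set
#' `shrink_intercept = FALSE` to shrink only the regressor block and keep the
#' ML intercept.
#'
#' @param fit A converged [poisson_fit()].
#' @param d Either a number in `[0, 1]` or one of `"d1"`, `"d2"` to select the
#'   shrinkage parameter from the data via [select_d()].
#' @param shrink_intercept Apply the shrinkage to the intercept too (default
#'   `TRUE`).
#' @return An object of class `liu_fit`: `d`, `d_rule`, shrunk coefficients,
#'   Liu fitted means `mu`, the eigenvalues of \eqn{X'\hat WX} and the rotated
#'   ML coefficients `alpha` used by the d-rules, and the base fit.
#' @examples
#' fit <- poisson_fit(english_league(), response = y)
#' lfit <- liu_fit(fit, d = "d1")
#' lfit$d
#' @export
liu_fit <- function(fit, d = "d1", shrink_intercept = TRUE) {
  stopifnot(inherits(fit, "poisson_fit"))
  stop_if_not_converged(fit)
  if (is.character(d)) {
    d_rule <- match.arg(d, c("d1", "d2"))
    d <- select_d(fit, rule = d_rule)
  } else {
    d_rule <- "fixed"
    if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0 || d > 1) {
      rlang::abort("`d` must be a single number in [0, 1] or one of 'd1', 'd2'.")
    }
  }
  X <- fit$design
  A <- crossprod(X, fit$weights * X)
  eg <- eigen(A, symmetric = TRUE)
  if (min(eg$values) <= 0) {
    rlang::abort("X'WX is not positive definite.", class = "liudiag_rank_deficient")
  }
  beta <- fit$coefficients
  if (shrink_intercept || !fit$intercept) {
    beta_d <- drop(solve(A + diag(ncol(X)), (A + d * diag(ncol(X))) %*% beta))
  } else {
    As <- A[-1, -1, drop = FALSE]
    bs <- drop(solve(As + diag(ncol(X) - 1L), (As + d * diag(ncol(X) - 1L)) %*% beta[-1]))
    beta_d <- c(beta[1], bs)
  }
  names(beta_d) <- names(beta)
  structure(
    list(
      d = d,
      d_rule = d_rule,
      shrink_intercept = shrink_intercept,
      coefficients = beta_d,
      mu = exp(drop(X %*% beta_d)),
      eigenvalues = eg$values,
      eigenvectors = eg$vectors,
      alpha = drop(crossprod(eg$vectors, beta)),
      base_fit = fit
    ),
    class = "liu_fit"
  )
}

#' Data-driven selection of the Liu shrinkage parameter
#'
#' Implements the two selection rules built from the eigen-structure of
#' \eqn{X'\hat WX}. With eigenvalues \eqn{\lambda_j} and rotated ML
#' coefficients \eqn{\alpha_j} (components of \eqn{\gamma'\hat\beta_{ML}} where
#' \eqn{X'\hat WX = \gamma\Lambda\gamma'}):
#' \deqn{\hat d_1 = \max\Big(0, \min_j \frac{\alpha_j^2 - 1}{1/\lambda_j + \alpha_j^2}\Big), \qquad
#'       \hat d_2 = \max\Big(0, \min_j \frac{\alpha_j^2 - 1}{1/\lambda_j + \alpha_{\max}^2}\Big),}
#' with \eqn{\alpha_{\max}^2 = \max_j \alpha_j^2}. The result is additionally
#' capped at 1 so that the Liu constraint \eqn{0 \le d \le 1} always holds.
#' Both rules return 0 whenever any \eqn{\alpha_j^2 < 1}, which is the common
#' case in collinear designs; they are nonzero only when every rotated
#' coefficient exceeds 1 in magnitude.
#'
#' @param fit A converged [poisson_fit()].
#' @param rule `"d1"` or `"d2"`.
#' @return A number in `[0, 1]`.
#' @export
select_d <- function(fit, rule = c("d1", "d2")) {
  rule <- match.arg(rule)
  stop_if_not_converged(fit)
  X <- fit$design
  A <- crossprod(X, fit$weights * X)
  eg <- eigen(A, symmetric = TRUE)
  lambda <- eg$values
  alpha2 <- drop(crossprod(eg$vectors, fit$coefficients))^2
  cand <- if (rule == "d1") {
    (alpha2 - 1) / (1 / lambda + alpha2)
  } else {
    (alpha2 - 1) / (1 / lambda + max(alpha2))
  }
  min(1, max(0, min(cand)))
}

#' Hat matrix of a Liu fit
#'
#' The Liu analogue of the weighted projection, in the symmetric sandwich form
#' \deqn{H_d = \hat W^{1/2}X\,(X'\hat WX+I)^{-1}(X'\hat WX+dI)(X'\hat WX)^{-1}
#'   X'\hat W^{1/2}.}
#' It reduces to the ML hat matrix at \eqn{d = 1}; its diagonal satisfies
#' \eqn{0 \le h_{d,ii} \le h_{ii}} for \eqn{d \in [0,1]} and its trace equals
#' \eqn{\sum_j (\lambda_j + d)/(\lambda_j + 1)}. (`H_d` is a smoother, not a
#' projection: it is symmetric but not idempotent for `d < 1`.)
#'
#' @param fit A `liu_fit`.
#' @param ... Unused.
#' @return An n-by-n matrix.
#' @export
hat_matrix.liu_fit <- function(fit, ...) {
  base <- fit$base_fit
  K <- sqrt(base$weights) * base$design
  A <- crossprod(K)
  Ip <- diag(ncol(K))
  Fm <- solve(A + Ip, A + fit$d * Ip) %*% solve(A)
  H <- K %*% Fm %*% t(K)
  (H + t(H)) / 2
}

#' @export
hatvalues.liu_fit <- function(model, ...) {
  base <- model$base_fit
  K <- sqrt(base$weights) * base$design
  A <- crossprod(K)
  Ip <- diag(ncol(K))
  Fm <- solve(A + Ip, A + model$d * Ip) %*% solve(A)
  Fm <- (Fm + t(Fm)) / 2
  h <- rowSums((K %*% Fm) * K)
  pmin(pmax(h, 0), 1)
}

#' Leverage pair driving the Liu one-step deletion
#'
#' For row \eqn{k_i' = \hat W_{ii}^{1/2} x_i'} of \eqn{K = \hat W^{1/2}X},
#' returns \eqn{m_i = k_i(K'K)^{-1}k_i'} (which equals the ML leverage
#' \eqn{h_{ii}}) and the ridge-type deletion leverage
#' \eqn{m_{di} = k_i(K'K+I)^{-1}k_i'} appearing in the denominator of the
#' Sherman--Morrison--Woodbury one-step update. Always
#' \eqn{0 \le m_{di} < m_i < 1} on a valid fit.
#'
#' @param fit A `liu_fit`.
#' @return A tibble with columns `obs`, `m`, `m_del`.
#' @export
deletion_leverages <- function(fit) {
  stopifnot(inherits(fit, "liu_fit"))
  base <- fit$base_fit
  K <- sqrt(base$weights) * base$design
  A <- crossprod(K)
  m <- rowSums((K %*% solve(A)) * K)
  m_del <- rowSums((K %*% solve(A + diag(ncol(K)))) * K)
  tibble::tibble(obs = seq_len(nrow(K)), m = m, m_del = m_del)
}

#' Residuals for a Liu fit
#'
#' Same conventions as [residuals.poisson_fit()], with the Liu fitted means
#' \eqn{\hat\mu_{d,i}} and Liu leverages \eqn{h_{d,ii}} substituted: the
#' Pearson residual is \eqn{\chi_{di} = (y_i - \hat\mu_{di})/\sqrt{\hat\mu_{di}}},
#' the standardized version divides by \eqn{\sqrt{1 - h_{d,ii}}}, and the
#' deviance residual is the signed root of the unit deviance at
#' \eqn{\hat\mu_{di}}. At `d = 1` all three equal their ML counterparts.
#'
#' @param object A `liu_fit`.
#' @param type As in [residuals.poisson_fit()].
#' @param ... Unused.
#' @return Numeric vector of length n.
#' @export
residuals.liu_fit <- function(object,
                              type = c("pearson", "standardized", "deviance",
                                       "jackknife", "pearson_raw", "response"),
                              ...) {
  type <- match.arg(type)
  y <- object$base_fit$y
  mu <- object$mu
  switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu),
    pearson_raw = (y - mu) / mu,
    standardized = standardized_pearson(y, mu, hatvalues(object)),
    deviance = sign(y - mu) * sqrt(poisson_unit_deviance(y, mu)),
    jackknife = jackknife_pearson(
      standardized_pearson(y, mu, hatvalues(object)),
      object$base_fit$n, object$base_fit$p
    )
  )
}

#' @export
coef.liu_fit <- function(object, ...) object$coefficients

#' @export
fitted.liu_fit <- function(object, ...) object$mu

#' @export
print.liu_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Poisson Liu fit: d = %.4g (%s)\n", x$d,
              if (x$d_rule == "fixed") "fixed" else paste0("rule ", x$d_rule)))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @method tidy liu_fit
#' @export
tidy.liu_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    estimate_ml = unname(x$base_fit$coefficients)
  )
}

#' @method glance liu_fit
#' @export
glance.liu_fit <- function(x, ...) {
  y <- x$base_fit$y
  tibble::tibble(
    nobs = x$base_fit$n,
    d = x$d,
    d_rule = x$d_rule,
    deviance = poisson_deviance(y, x$mu),
    logLik = poisson_loglik(y, x$mu)
  )
}

#' @method augment liu_fit
#' @export
augment.liu_fit <- function(x, ...) {
  base <- x$base_fit
  tibble::tibble(
    !!base$response_name := base$y,
    tibble::as_tibble(base$design[, setdiff(colnames(base$design), "(Intercept)"),
                                  drop = FALSE]),
    .fitted = x$mu,
    .resid = residuals(x, "pearson"),
    .std.resid = residuals(x, "standardized"),
    .hat = hatvalues(x)
  )
}
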