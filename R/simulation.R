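#' Specification of one Monte Carlo detection cell
#'
#' Bundles the design of a detection-rate experiment: collinear regressors are
#' drawn, one observation is turned into an influential case, Poisson counts
#' are generated, and every replication records whether each of the eight
#' diagnostics flags the planted observation.
#'
#' Regressors follow \eqn{x_{ij} = \sqrt{1-\rho^2}\,z_{ij} + \rho\,z_{i,p+1}}
#' with i.i.d. standard normal \eqn{z}, so every pair of columns has population
#' correlation \eqn{\rho^2}. Counts are \eqn{y_i \sim
#' \mathrm{Pois}(\exp(\beta_0 + x_i'\beta))} with \eqn{\sum_j \beta_j^2 = 1}
#' (default \eqn{\beta_j = 1/\sqrt p}, \eqn{\beta_0 = 0}). The influential case
#' is created by adding \eqn{\bar x_j + } `shift_offset` to every regressor of
#' row `influential_index`. With `inject = "post_response"` (default) the shift
#' happens after the counts are drawn, so the planted row is a leverage point
#' whose count disagrees with its shifted regressors; `"pre_response"` makes
#' the shift generative (the count is drawn from the shifted row, which leaves
#' residual-based measures at their null detection rate).
#'
#' @param n Sample size.
#' @param p Number of regressors.
#' @param rho2 Pairwise regressor correlation \eqn{\rho^2 \in [0, 1)}.
#' @param n_reps Number of Monte Carlo replications.
#' @param seed Integer master seed; every replication derives its own
#'   substream, so results are reproducible and cells are independent.
#' @param d_rule `"d1"` or `"d2"`, the Liu shrinkage-selection rule.
#' @param beta Regression coefficients (length `p`, must satisfy
#'   \eqn{\sum\beta_j^2 = 1}); default `rep(1/sqrt(p), p)`.
#' @param beta0 Intercept of the generating model (default 0).
#' @param influential_index Row receiving the shift (default 15).
#' @param shift_offset Constant added on top of the column mean (default 6).
#' @param inject `"post_response"` (default) or `"pre_response"`.
#' @param dev_variant,dffits_form Diagnostic conventions, as in
#'   [influence_table()].
#' @return A `simulation_spec` object (validated list).
#' @examples
#' spec <- simulation_spec(n = 25, p = 2, rho2 = 0.75, n_reps = 50, seed = 1)
#' run_cell(spec)
#' @export
simulation_spec <- function(n = 25, p = 2, rho2 = 0.75, n_reps = 1000,
                            seed = 1L, d_rule = c("d1", "d2"),
                            beta = NULL, beta0 = 0,
                            influential_index = 15, shift_offset = 6,
                            inject = c("post_response", "pre_response"),
                            dev_variant = c("onestep", "scaled"),
                            dffits_form = c("ratio", "over_n")) {
  d_rule <- match.arg(d_rule)
  inject <- match.arg(inject)
  dev_variant <- match.arg(dev_variant)
  dffits_form <- match.arg(dffits_form)
  if (is.null(beta)) beta <- rep(1 / sqrt(p), p)
  stopifnot(
    n > p + 1, p >= 1, rho2 >= 0, rho2 < 1, n_reps >= 1,
    length(beta) == p, influential_index >= 1, influential_index <= n
  )
  if (abs(sum(beta^2) - 1) > 1e-12) {
    rlang::abort("`beta` must satisfy sum(beta^2) == 1.")
  }
  structure(
    list(n = as.integer(n), p = as.integer(p), rho2 = rho2,
         n_reps = as.integer(n_reps), seed = as.integer(seed),
         d_rule = d_rule, beta = beta, beta0 = beta0,
         influential_index = as.integer(influential_index),
         shift_offset = shift_offset, inject = inject,
         dev_variant = dev_variant, dffits_form = dffits_form),
    class = "simulation_spec"
  )
}

#' Generate collinear regressors
#'
#' Draws an \eqn{n \times p} matrix via \eqn{x_{ij} = \sqrt{1-\rho^2}\,z_{ij}
#' + \rho\,z_{i,p+1}} from i.i.d. standard normal \eqn{z_{ij}}; every pair of
#' columns then has population correlation \eqn{\rho^2}. Uses (and advances)
#' the current RNG state.
#'
#' @param n,p Dimensions.
#' @param rho2 Target pairwise correlation in `[0, 1)`.
#' @return An `n` by `p` numeric matrix.
#' @export
gen_regressors <- function(n, p, rho2) {
  stopifnot(rho2 >= 0, rho2 < 1)
  Z <- matrix(stats::rnorm(n * (p + 1)), n, p + 1)
  sqrt(1 - rho2) * Z[, seq_len(p), drop = FALSE] + sqrt(rho2) * Z[, p + 1]
}

#' Plant an influential observation in a regressor matrix
#'
#' Adds `colMeans(X)[j] + offset` to entry `(index, j)` for every column `j`;
#' all other rows are untouched. The column means are taken before the shift.
#'
#' @param X Regressor matrix.
#' @param index Row to shift (1-based).
#' @param offset Constant added on top of each column mean (default 6).
#' @return The shifted matrix.
#' @export
inject_influential <- function(X, index, offset = 6) {
  check_index(index, nrow(X))
  X[index, ] <- X[index, ] + colMeans(X) + offset
  X
}

# Build a poisson_fit object straight from a design matrix (simulation fast
# path; same irls engine as poisson_fit()).
fit_from_matrix <- function(y, X, intercept = TRUE, tol = 1e-8, max_iter = 50L) {
  xnames <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  colnames(X) <- xnames
  design <- if (intercept) cbind("(Intercept)" = 1, X) else X
  fit <- irls(y, design, tol = tol, max_iter = max_iter)
  structure(
    c(fit, list(xnames = xnames, response_name = "y", intercept = intercept,
                n = length(y), p = ncol(X))),
    class = "poisson_fit"
  )
}

#' Run one Monte Carlo detection cell
#'
#' Per replication: generate regressors, plant the influential case, draw the
#' counts, fit the ML model, select the Liu parameter by the spec's rule, fit
#' the Liu estimator, evaluate all eight diagnostics at the planted row and
#' record which ones flag it at their cutoffs. Replications whose IRLS fit
#' fails or does not converge are discarded and counted in `n_failed_fits`;
#' detection percentages are over converged replications. An infinite
#' diagnostic (unit leverage or a closed jackknife radicand) counts as a
#' detection.
#'
#' @param spec A [simulation_spec()].
#' @return A one-row tibble: the spec's factors, `n_failed_fits`, `d_mean`
#'   (average selected shrinkage), eight detection percentage columns
#'   (`cook_ml`, `delta_chisq_ml`, `delta_dev_ml`, `dffits_ml`, `cook_liu`,
#'   `delta_chisq_liu`, `delta_dev_liu`, `dffits_liu`) and their Monte Carlo
#'   standard errors (`se_` prefix).
#' @export
run_cell <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  measures <- c("cook_ml", "delta_chisq_ml", "delta_dev_ml", "dffits_ml",
                "cook_liu", "delta_chisq_liu", "delta_dev_liu", "dffits_liu")
  hits <- matrix(NA, spec$n_reps, 8, dimnames = list(NULL, measures))
  d_values <- rep(NA_real_, spec$n_reps)
  idx <- spec$influential_index
  cuts <- default_cutoffs(spec$n, spec$p, spec$dffits_form)
  set.seed(spec$seed)
  rep_seeds <- sample.int(.Machine$integer.max, spec$n_reps)
  for (r in seq_len(spec$n_reps)) {
    set.seed(rep_seeds[r])
    X <- gen_regressors(spec$n, spec$p, spec$rho2)
    if (spec$inject == "pre_response") {
      X <- inject_influential(X, idx, spec$shift_offset)
      y <- stats::rpois(spec$n, exp(spec$beta0 + drop(X %*% spec$beta)))
    } else {
      y <- stats::rpois(spec$n, exp(spec$beta0 + drop(X %*% spec$beta)))
      X <- inject_influential(X, idx, spec$shift_offset)
    }
    fit <- tryCatch(
      suppressWarnings(fit_from_matrix(y, X)),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) next
    lfit <- tryCatch(
      liu_fit(fit, d = spec$d_rule),
      error = function(e) NULL
    )
    if (is.null(lfit)) next
    d_values[r] <- lfit$d
    ml <- diag_at(fit, idx, spec$dev_variant)
    liu <- diag_at(lfit, idx, spec$dev_variant)
    hits[r, ] <- c(
      ml$cook > cuts$cook, ml$dchi > cuts$delta_chisq,
      ml$ddev > cuts$delta_dev, abs(ml$dffits) > cuts$dffits,
      liu$cook > cuts$cook, liu$dchi > cuts$delta_chisq,
      liu$ddev > cuts$delta_dev, abs(liu$dffits) > cuts$dffits
    )
  }
  ok <- !is.na(hits[, 1])
  m <- sum(ok)
  if (m == 0L) {
    rlang::abort("All replications failed to converge.", class = "liudiag_all_failed")
  }
  pct <- 100 * colMeans(hits[ok, , drop = FALSE])
  se <- 100 * sqrt(pct / 100 * (1 - pct / 100) / m)
  out <- tibble::tibble(
    n = spec$n, p = spec$p, rho2 = spec$rho2, d_rule = spec$d_rule,
    n_reps = spec$n_reps, n_failed_fits = spec$n_reps - m,
    d_mean = mean(d_values[ok]),
    !!!stats::setNames(as.list(pct), measures),
    !!!stats::setNames(as.list(se), paste0("se_", measures))
  )
  attr(out, "spec") <- spec
  out
}

# The four diagnostics of one estimator, evaluated at a single observation.
diag_at <- function(fit, i, dev_variant) {
  is_liu <- inherits(fit, "liu_fit")
  base <- if (is_liu) fit$base_fit else fit
  h <- hatvalues(fit)[i]
  chi <- residuals(fit, "pearson")[i]
  chs <- if (h < 1) chi / sqrt(1 - h) else Inf * sign(chi)
  d2 <- poisson_unit_deviance(base$y[i], fitted(fit)[i])
  p1 <- base$p + 1L
  cook <- if (is_liu) {
    X <- base$design
    A <- crossprod(X, base$weights * X)
    db <- suppressWarnings(drop(liu_deltas(fit, method = "exact", idx = i)))
    if (any(!is.finite(db))) Inf else drop(crossprod(db, A %*% db)) / p1
  } else {
    if (h < 1) chs^2 / p1 * h / (1 - h) else Inf
  }
  ddev <- if (dev_variant == "scaled") {
    if (h < 1) d2 / (1 - h) else Inf
  } else {
    if (h < 1) d2 + chi^2 * h / (1 - h) else Inf
  }
  t_i <- jackknife_pearson(chs, base$n, base$p)
  dffits <- if (h < 1) t_i * sqrt(h / (1 - h)) else Inf * sign(t_i)
  list(cook = cook, dchi = chs^2, ddev = ddev, dffits = dffits)
}

#' Run a grid of Monte Carlo detection cells
#'
#' Maps [run_cell()] over a factorial grid of sample sizes and collinearity
#' levels (all other settings shared), giving each cell its own deterministic
#' seed substream derived from `seed`. Failures are re-raised with the cell
#' identity attached.
#'
#' @param n,rho2 Vectors of sample sizes and correlation levels; the grid is
#'   their cross product.
#' @param p,n_reps,seed,d_rule,... Shared settings passed to
#'   [simulation_spec()].
#' @return A tibble with one row per cell in the [run_cell()] layout (the
#'   eight detection columns follow the conventional order: four ML measures,
#'   then four Liu measures).
#' @examples
#' run_grid(n = c(25, 50), rho2 = 0.75, p = 2, n_reps = 20, seed = 7)
#' @export
run_grid <- function(n, rho2, p = 2, n_reps = 1000, seed = 1L,
                     d_rule = "d1", ...) {
  cells <- tidyr::expand_grid(n = n, rho2 = rho2)
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max, nrow(cells))
  purrr::map_dfr(seq_len(nrow(cells)), function(k) {
    spec <- simulation_spec(n = cells$n[k], p = p, rho2 = cells$rho2[k],
                            n_reps = n_reps, seed = cell_seeds[k],
                            d_rule = d_rule, ...)
    tryCatch(run_cell(spec), error = function(e) {
      rlang::abort(sprintf("Cell n = %d, rho2 = %.3g failed: %s",
                           cells$n[k], cells$rho2[k], conditionMessage(e)))
    })
  })
}

#' Pivot a detection table to long format
#'
#' @param grid A tibble from [run_cell()] or [run_grid()].
#' @return Long tibble: `n`, `rho2`, `estimator`, `measure`, `detection`, `se`.
#' @export
detection_long <- function(grid) {
  measures <- c("cook", "delta_chisq", "delta_dev", "dffits")
  long <- tidyr::pivot_longer(
    grid,
    cols = tidyr::matches("^(se_)?(cook|delta_chisq|delta_dev|dffits)_(ml|liu)$"),
    names_to = c("stat", "measure", "estimator"),
    names_pattern = "^(se_)?(cook|delta_chisq|delta_dev|dffits)_(ml|liu)$",
    values_to = "value"
  )
  long$stat <- ifelse(long$stat == "se_", "se", "detection")
  out <- tidyr::pivot_wider(long, names_from = "stat", values_from = "value")
  out$estimator <- toupper(out$estimator)
  out$measure <- factor(out$measure, levels = measures)
  out
}
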