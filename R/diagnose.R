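#' One-call influence diagnosis of a count-data table
#'
#' Fits the requested estimator and returns its [influence_table()], with the
#' sample size, regressor count, condition index (correlation convention) and
#' -- for the Liu estimator -- the selected shrinkage parameter recorded in the
#' attributes.
#'
#' @param data Data frame with the count response and numeric regressors.
#' @param response Response column (bare name or string).
#' @param estimator `"ml"` or `"liu"`.
#' @param d Shrinkage parameter or rule for the Liu estimator (see
#'   [liu_fit()]).
#' @param cutoffs Named list of cutoff overrides, see [influence_table()].
#' @param dev_variant,dffits_form Passed to [influence_table()].
#' @param intercept Include an intercept (default `TRUE`).
#' @return An `influence_tbl` with an extra `condition_index` attribute.
#' @examples
#' diagnose(english_league(), response = y, estimator = "liu")
#' @export
diagnose <- function(data, response, estimator = c("ml", "liu"), d = "d1",
                     cutoffs = list(),
                     dev_variant = c("onestep", "scaled"),
                     dffits_form = c("ratio", "over_n"),
                     intercept = TRUE) {
  estimator <- match.arg(estimator)
  fit <- poisson_fit(data, {{ response }}, intercept = intercept)
  if (estimator == "liu") fit <- liu_fit(fit, d = d)
  out <- influence_table(fit, dev_variant = dev_variant, cutoffs = cutoffs,
                         dffits_form = dffits_form)
  attr(out, "condition_index") <-
    condition_index(data, {{ response }}, convention = "correlation")
  out
}

#' Absolute percentage change in coefficients after deleting observations
#'
#' Quantifies the leverage of suspected influential sets: for each requested
#' set of observations, the model is refitted without them (`refit_mode =
#' "exact"`) or updated by the closed-form one-step deletion (`refit_mode =
#' "one_step"`, single observations only), and the change in every coefficient
#' is reported as \eqn{100\,|\hat\beta_{full} - \hat\beta_{del}|/|\hat\beta_{full}|}.
#'
#' For the Liu estimator under exact refitting, `d_policy` controls the
#' shrinkage parameter on the reduced data: `"refit_d"` re-selects it by the
#' same rule, `"hold_d"` keeps the full-data value.
#'
#' @param data Data frame with the count response and numeric regressors.
#' @param response Response column.
#' @param sets List of integer vectors of 1-based observation indices (a bare
#'   integer vector is treated as one set).
#' @param estimator `"ml"` or `"liu"`.
#' @param refit_mode `"exact"` (default) or `"one_step"`.
#' @param d_policy `"refit_d"` (default) or `"hold_d"`; Liu + exact mode only.
#' @param d Shrinkage rule or value for the Liu estimator.
#' @param intercept Include an intercept (default `TRUE`).
#' @return A tibble with one row per (set, coefficient): `set`, `term`,
#'   `estimate_full`, `estimate_deleted`, `pct_change`, `estimator`.
#' @examples
#' deletion_impact(english_league(), response = y, sets = list(1, 19, c(1, 19)))
#' @export
deletion_impact <- function(data, response, sets,
                            estimator = c("ml", "liu"),
                            refit_mode = c("exact", "one_step"),
                            d_policy = c("refit_d", "hold_d"),
                            d = "d1", intercept = TRUE) {
  estimator <- match.arg(estimator)
  refit_mode <- match.arg(refit_mode)
  d_policy <- match.arg(d_policy)
  if (!is.list(sets)) sets <- list(sets)
  if (!length(sets)) rlang::abort("`sets` must contain at least one index set.")
  resp_quo <- rlang::enquo(response)
  full_ml <- poisson_fit(data, !!resp_quo, intercept = intercept)
  n <- full_ml$n
  p <- full_ml$p
  full_fit <- if (estimator == "liu") liu_fit(full_ml, d = d) else full_ml
  beta_full <- coef(full_fit)
  if (any(abs(beta_full) < 1e-8)) {
    rlang::warn("Some full-data coefficients are near zero; percentage changes may explode.")
  }
  purrr::map_dfr(sets, function(set) {
    set <- sort(unique(as.integer(set)))
    if (any(set < 1L) || any(set > n)) {
      rlang::abort("Deletion indices out of range.")
    }
    if (n - length(set) <= p + 1L) {
      rlang::abort("Deletion would leave too few observations to refit.")
    }
    beta_del <- if (refit_mode == "one_step") {
      if (length(set) != 1L) {
        rlang::abort("one_step mode supports single-observation sets only.",
                     class = "liudiag_unsupported_mode")
      }
      beta_full - one_step_delete(full_fit, set)
    } else {
      reduced <- data[-set, , drop = FALSE]
      red_ml <- poisson_fit(reduced, !!resp_quo, intercept = intercept)
      if (estimator == "liu") {
        d_red <- if (d_policy == "hold_d") full_fit$d else d
        coef(liu_fit(red_ml, d = d_red))
      } else {
        coef(red_ml)
      }
    }
    tibble::tibble(
      set = paste(set, collapse = ","),
      term = names(beta_full),
      estimate_full = unname(beta_full),
      estimate_deleted = unname(beta_del),
      pct_change = unname(100 * abs(beta_full - beta_del) / abs(beta_full)),
      estimator = toupper(estimator)
    )
  })
}
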