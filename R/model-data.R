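#' Build a response vector and design matrix from a data frame
#'
#' Internal workhorse behind all data-frame-first entry points. Validates the
#' count response and the regressor block, and (by default) prepends an
#' intercept column.
#'
#' @param data A data frame: one count-response column plus numeric regressors.
#' @param response Column holding the counts (bare name or string).
#' @param intercept Prepend a column of ones? (default `TRUE`).
#' @return List with `y`, `X` (full design including any intercept), `xnames`,
#'   `response_name`, `intercept`, `n`, `p` (regressors, intercept excluded).
#' @noRd
build_design <- function(data, response, intercept = TRUE) {
  if (!is.data.frame(data)) {
    rlang::abort("`data` must be a data frame.")
  }
  resp <- rlang::as_name(rlang::enquo(response))
  if (!resp %in% names(data)) {
    rlang::abort(sprintf("Response column '%s' not found in `data`.", resp))
  }
  y <- data[[resp]]
  xnames <- setdiff(names(data), resp)
  if (length(xnames) == 0L && !intercept) {
    rlang::abort("`data` must contain at least one regressor column.")
  }
  X <- as.matrix(data[xnames])
  storage.mode(X) <- "double"
  validate_counts(y)
  if (!all(is.finite(X))) {
    rlang::abort("Regressor matrix contains non-finite entries.")
  }
  n <- length(y)
  p <- ncol(X)
  if (intercept) {
    if (n <= p + 1L) {
      rlang::abort(sprintf(
        "Need n > p + 1 for positive residual degrees of freedom (n = %d, p = %d).",
        n, p
      ))
    }
    X <- cbind("(Intercept)" = 1, X)
  } else if (n <= p) {
    rlang::abort(sprintf("Need n > p (n = %d, p = %d).", n, p))
  }
  list(
    y = as.numeric(y), X = X, xnames = xnames, response_name = resp,
    intercept = intercept, n = n, p = p
  )
}

validate_counts <- function(y) {
  if (!is.numeric(y) || anyNA(y)) {
    rlang::abort("Response must be a numeric vector of counts without NAs.")
  }
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8)) {
    rlang::abort("Response must contain nonnegative integer counts.")
  }
  invisible(y)
}

#' Read a count-data table from delimited text
#'
#' Thin wrapper around [readr::read_delim()] that checks the named response
#' column exists and that all remaining columns are numeric regressors.
#'
#' @param path Path to a delimited text file with a header row.
#' @param response Name of the response (count) column.
#' @param delim Field delimiter (default `","`).
#' @return A tibble with the response column first.
#' @examples
#' path <- system.file("extdata", "english_league.csv", package = "liudiag")
#' read_count_data(path, response = "y")
#' @export
read_count_data <- function(path, response, delim = ",") {
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  if (!response %in% names(tbl)) {
    rlang::abort(sprintf("Response column '%s' not found in '%s'.", response, path))
  }
  bad <- names(tbl)[!vapply(tbl, is.numeric, logical(1))]
  if (length(bad)) {
    rlang::abort(paste0("Non-numeric columns: ", paste(bad, collapse = ", ")))
  }
  dplyr::relocate(tbl, dplyr::all_of(response))
}

#' English League football season table
#'
#' Twenty club-seasons from an English League table: the number of matches won
#' (`y`) together with five club statistics used as regressors -- `x1` yellow
#' cards, `x2` red cards, `x3` and `x4` goal tallies (the published column
#' labels call them goals scored and goals conceded; the printed values are
#' consistent with goals against and goal difference), and `x5` points earned.
#' The five regressors are strongly collinear, which is what makes the data a
#' useful test bed for shrinkage-aware influence diagnostics.
#'
#' @return A 20-row tibble with columns `y`, `x1`..`x5`.
#' @examples
#' english_league()
#' @export
english_league <- function() {
  path <- system.file("extdata", "english_league.csv", package = "liudiag")
  read_count_data(path, response = "y")
}
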