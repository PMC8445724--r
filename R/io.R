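#' Serialize an influence table
#'
#' `write_influence()` writes the per-observation table as CSV (values survive
#' a round trip exactly: readr writes shortest round-trip representations).
#' `write_influence_json()` writes a JSON document carrying the table plus its
#' metadata: estimator, cutoffs, flagged observation sets, and the shrinkage
#' parameter for Liu tables. `read_influence()` reads the CSV back into an
#' `influence_tbl` (metadata is restored from the companion JSON when given).
#'
#' @param table An `influence_tbl`.
#' @param path Output file path.
#' @return `path`, invisibly (writers); an `influence_tbl` (reader).
#' @export
write_influence <- function(table, path) {
  stopifnot(inherits(table, "influence_tbl"))
  readr::write_csv(as.data.frame(table), path)
  invisible(path)
}

#' @rdname write_influence
#' @export
write_influence_json <- function(table, path) {
  stopifnot(inherits(table, "influence_tbl"))
  payload <- list(
    estimator = attr(table, "estimator"),
    n = attr(table, "n"),
    p = attr(table, "p"),
    d = attr(table, "d"),
    d_rule = attr(table, "d_rule"),
    cutoffs = attr(table, "cutoffs"),
    flagged = influence_flags(table),
    table = as.data.frame(table)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_influence
#' @param json_path Optional companion JSON written by
#'   [write_influence_json()], used to restore the table metadata.
#' @export
read_influence <- function(path, json_path = NULL) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  meta <- if (!is.null(json_path)) jsonlite::read_json(json_path) else NULL
  structure(
    tbl,
    estimator = meta$estimator %||% NA_character_,
    cutoffs = if (!is.null(meta)) lapply(meta$cutoffs, as.numeric) else NULL,
    n = meta$n %||% nrow(tbl),
    p = meta$p %||% NA_integer_,
    d = meta$d,
    d_rule = meta$d_rule,
    class = c("influence_tbl", class(tbl))
  )
}
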