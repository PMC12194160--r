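#' Read and write the pipeline's delimited input tables
#'
#' CSV readers/writers (UTF-8, header row required) for the three input
#' tables:
#' * monthly climate: columns `year`, `month`, `tm`, `tmin`, `tmax`,
#'   `precip`, `spei` (temperatures in degrees C, precipitation in mm,
#'   drought index unitless);
#' * monthly counts: columns `species`, `year`, `month`, `count`;
#' * nest counts: columns `species`, `year`, `n_nests`.
#'
#' Readers validate the table's invariants: unique contiguous months,
#' `tmin <= tm <= tmax`, non-negative precipitation and integer non-negative
#' counts.
#'
#' @param path File path.
#' @param x Table to write.
#' @return Readers return a tibble; writers return `path` invisibly.
#' @name climwindow_io
NULL

#' @rdname climwindow_io
#' @export
read_monthly_climate <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  validate_monthly_climate(x)
  x
}

#' @rdname climwindow_io
#' @export
write_monthly_climate <- function(x, path) {
  validate_monthly_climate(x)
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname climwindow_io
#' @export
read_monthly_counts <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  validate_monthly_counts(x)
  x
}

#' @rdname climwindow_io
#' @export
write_monthly_counts <- function(x, path) {
  validate_monthly_counts(x)
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname climwindow_io
#' @export
read_nest_counts <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("species", "year", "n_nests")
  if (!all(req %in% names(x))) {
    rlang::abort("nest table needs columns species, year, n_nests.",
                 class = "climwindow_invalid_argument")
  }
  if (any(x$n_nests < 0 | x$n_nests != round(x$n_nests))) {
    rlang::abort("`n_nests` must be non-negative integers.",
                 class = "climwindow_invalid_argument")
  }
  x
}

#' @rdname climwindow_io
#' @export
write_nest_counts <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

validate_monthly_climate <- function(x) {
  req <- c("year", "month", "tm", "tmin", "tmax", "precip", "spei")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("climate table is missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "climwindow_invalid_argument")
  }
  if (anyDuplicated(x[c("year", "month")]) > 0) {
    rlang::abort("duplicate year x month records in climate table.",
                 class = "climwindow_invalid_argument")
  }
  idx <- sort(month_index(x$year, x$month))
  if (length(idx) > 1 && any(diff(idx) != 1L)) {
    rlang::abort("climate series must be contiguous (no month gaps).",
                 class = "climwindow_invalid_argument")
  }
  bad <- stats::na.omit(x$tmin > x$tm | x$tm > x$tmax)
  if (any(bad)) {
    rlang::abort("temperature ordering violated: need tmin <= tm <= tmax.",
                 class = "climwindow_invalid_argument")
  }
  if (any(x$precip < 0, na.rm = TRUE)) {
    rlang::abort("`precip` must be >= 0.",
                 class = "climwindow_invalid_argument")
  }
  invisible(x)
}
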