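#' Assign calendar months to the wintering or breeding season
#'
#' The yearly cycle is split into two six-month seasons: wintering
#' (September--February) and breeding (March--August). This split drives
#' seasonal aggregation of counts and the anchoring of candidate climate
#' windows.
#'
#' @param month Integer vector of calendar months (1 = January ... 12 =
#'   December).
#'
#' @return A character vector the same length as `month`, each element
#'   `"wintering"` or `"breeding"`.
#'
#' @examples
#' assign_season(c(9, 3, 1))
#' table(assign_season(1:12))
#' @export
assign_season <- function(month) {
  if (!is.numeric(month) || any(is.na(month)) ||
      any(month != as.integer(month)) || any(month < 1L) || any(month > 12L)) {
    rlang::abort("`month` must be integers in 1..12.",
                 class = "climwindow_invalid_argument")
  }
  dplyr::if_else(month %in% 3:8, "breeding", "wintering")
}

#' Last calendar month of a season
#'
#' The reference month from which candidate window positions step back:
#' February for wintering (the season's final month, falling in the calendar
#' year after the season label), August for breeding.
#'
#' @param season `"wintering"` or `"breeding"`.
#' @return Integer month.
#' @keywords internal
season_reference_month <- function(season) {
  season <- match.arg(season, c("wintering", "breeding"))
  if (season == "wintering") 2L else 8L
}

#' Seasonal abundance from monthly counts
#'
#' Collapses monthly per-species counts into one value per species, season
#' and season-year: the arithmetic mean of the season's six monthly counts.
#' A wintering season spans two calendar years (September of year *t*
#' through February of year *t* + 1) and is labelled by the calendar year of
#' its September start. Season-years with fewer than six observed months are
#' flagged incomplete; season-years with no months at all are dropped with a
#' warning.
#'
#' @param counts A data frame of monthly counts with columns `species`,
#'   `year`, `month`, `count`.
#' @param season Optional filter: `"wintering"`, `"breeding"`, or `NULL`
#'   (default) for both.
#'
#' @return A tibble with columns `species`, `season`, `season_year`,
#'   `value` (mean of available monthly counts), `n_months`, and
#'   `incomplete` (`TRUE` when fewer than 6 months contributed).
#'
#' @examples
#' counts <- tibble::tibble(
#'   species = "sp1", year = 2005, month = 3:8,
#'   count = c(10, 10, 10, 10, 10, 10)
#' )
#' seasonal_abundance(counts)
#' @export
seasonal_abundance <- function(counts, season = NULL) {
  validate_monthly_counts(counts)
  out <- counts |>
    dplyr::mutate(
      season = assign_season(.data$month),
      season_year = dplyr::if_else(
        .data$season == "wintering" & .data$month %in% 1:2,
        .data$year - 1L, as.integer(.data$year)
      )
    ) |>
    dplyr::filter(!is.na(.data$count)) |>
    dplyr::group_by(.data$species, .data$season, .data$season_year) |>
    dplyr::summarise(
      value = mean(.data$count),
      n_months = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(incomplete = .data$n_months < 6L) |>
    dplyr::arrange(.data$species, .data$season, .data$season_year)
  n_empty <- sum(is.na(counts$count))
  if (n_empty > 0) {
    rlang::warn(sprintf("%d monthly count(s) missing; affected season-years flagged or omitted.",
                        n_empty))
  }
  if (!is.null(season)) {
    season <- match.arg(season, c("wintering", "breeding"))
    out <- dplyr::filter(out, .data$season == !!season)
  }
  out
}

validate_monthly_counts <- function(counts) {
  req <- c("species", "year", "month", "count")
  missing_cols <- setdiff(req, names(counts))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("`counts` is missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "climwindow_invalid_argument")
  }
  ok <- is.na(counts$count) |
    (counts$count >= 0 & counts$count == round(counts$count))
  if (!all(ok)) {
    rlang::abort("`count` must be non-negative integers.",
                 class = "climwindow_invalid_argument")
  }
  dup <- anyDuplicated(counts[c("species", "year", "month")])
  if (dup > 0) {
    rlang::abort("duplicate species x year x month records in `counts`.",
                 class = "climwindow_invalid_argument")
  }
  invisible(counts)
}
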