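#' @keywords internal
climate_variables <- function() c("tm", "tmin", "tmax", "precip", "spei")

#' Aggregation statistic for a climatic variable
#'
#' Temperatures and the drought index are averaged over a window;
#' precipitation is summed.
#'
#' @param variable One of `"tm"`, `"tmin"`, `"tmax"`, `"precip"`, `"spei"`.
#' @return `"mean"` or `"sum"`.
#' @export
window_agg <- function(variable) {
  variable <- match.arg(variable, climate_variables())
  if (variable == "precip") "sum" else "mean"
}

# absolute month index: consecutive integers over the calendar
month_index <- function(year, month) as.integer(year) * 12L + (as.integer(month) - 1L)

#' Enumerate candidate climate time-windows
#'
#' Builds the full candidate set scanned for each climatic variable: windows
#' of every duration 1--12 months at 12 end positions obtained by stepping
#' back one month at a time from the focal season's reference month (its
#' last month: February for wintering, August for breeding), giving
#' 12 x 12 = 144 candidates whose end months span both the focal and the
#' previous year.
#'
#' `year_offset` is relative to the calendar year in which the focal season
#' ends (for a wintering season labelled *t*, that is year *t* + 1): 0 means
#' the window ends in that year, -1 in the year before.
#'
#' The alternative reading that anchors all 12 calendar end-months in each
#' of the two years (288 candidates, including months after the season's
#' end in the focal year) is available as `variant = "per_year"`.
#'
#' @param variable One of `"tm"`, `"tmin"`, `"tmax"`, `"precip"`, `"spei"`.
#' @param season `"wintering"` or `"breeding"` (sets the reference month).
#' @param variant `"stepback"` (default, 144 windows) or `"per_year"`
#'   (288 windows).
#'
#' @return A tibble with columns `variable`, `duration`, `end_month`,
#'   `year_offset`, `agg`, and `months_back` (steps from the reference
#'   month to the window's end, used for tie-breaking).
#'
#' @examples
#' nrow(enumerate_windows("spei", "wintering"))
#' @export
enumerate_windows <- function(variable, season = c("breeding", "wintering"),
                              variant = c("stepback", "per_year")) {
  variable <- match.arg(variable, climate_variables())
  season <- match.arg(season)
  variant <- match.arg(variant)
  ref <- season_reference_month(season)
  if (variant == "stepback") {
    pos <- tibble::tibble(
      months_back = 0:11,
      end_month = ((ref - 0:11 - 1L) %% 12L) + 1L,
      year_offset = dplyr::if_else(ref - 0:11 >= 1L, 0L, -1L)
    )
  } else {
    pos <- tidyr::expand_grid(end_month = 1:12, year_offset = c(0L, -1L))
    # end-of-season calendar year is offset 0; months_back measured from ref
    pos$months_back <- ref - pos$end_month - 12L * pos$year_offset
  }
  out <- tidyr::expand_grid(duration = 1:12, pos)
  out$variable <- variable
  out$agg <- window_agg(variable)
  out[c("variable", "duration", "end_month", "year_offset", "agg", "months_back")]
}

# climate series -> function(absolute end index, duration) giving the
# windowed value, or NA where the span leaves the series
rolling_lookup <- function(climate, variable) {
  climate <- dplyr::arrange(climate, .data$year, .data$month)
  idx <- month_index(climate$year, climate$month)
  if (length(idx) > 1 && any(diff(idx) != 1L)) {
    rlang::abort("climate series has gaps or duplicate months.",
                 class = "climwindow_invalid_argument")
  }
  vals <- climate[[variable]]
  agg <- window_agg(variable)
  rolls <- lapply(1:12, function(d) rolling_aggregate(vals, d, agg))
  function(end_abs, duration) {
    pos <- match(end_abs, idx)
    out <- rep(NA_real_, length(end_abs))
    ok <- !is.na(pos) & pos >= duration
    out[ok] <- rolls[[duration]][pos[ok] - duration + 1L]
    out
  }
}

#' Value of a candidate window for given season-years
#'
#' Aggregates the window's climatic variable (mean, or sum for
#' precipitation) over the `duration` months ending at the window's end
#' month of the season-year's anchor calendar year plus `year_offset`.
#' Season-years whose span extends beyond the climate series yield `NA`.
#'
#' @param climate Monthly climate data frame (`year`, `month`, plus the
#'   variable column).
#' @param window One row of [enumerate_windows()] (data frame or list with
#'   `variable`, `duration`, `end_month`, `year_offset`).
#' @param season `"wintering"` or `"breeding"`; determines the anchor year
#'   (a wintering season labelled *t* ends in calendar year *t* + 1).
#' @param season_years Integer vector of season-year labels.
#'
#' @return Numeric vector, one value per element of `season_years`.
#'
#' @examples
#' clim <- tidyr::expand_grid(year = 2001:2005, month = 1:12)
#' clim$spei <- 0.5
#' w <- list(variable = "spei", duration = 3, end_month = 4, year_offset = 0L)
#' window_values(clim, w, "breeding", 2003:2005)
#' @export
window_values <- function(climate, window, season, season_years) {
  season <- match.arg(season, c("wintering", "breeding"))
  lookup <- rolling_lookup(climate, window$variable)
  anchor <- season_years + as.integer(season == "wintering") + window$year_offset
  lookup(month_index(anchor, window$end_month), window$duration)
}

#' Scan every candidate window of one climatic variable
#'
#' Computes the Spearman correlation between seasonal abundance and the
#' windowed climate value for each candidate window, with pairwise deletion
#' of season-years missing either quantity.
#'
#' @param abundance Seasonal abundance for one species and one season: a
#'   data frame with columns `season_year` and `value`
#'   (see [seasonal_abundance()]).
#' @param climate Monthly climate data frame.
#' @param variable Climatic variable to scan.
#' @param season `"wintering"` or `"breeding"`.
#' @param windows Optional candidate subset (rows shaped like
#'   [enumerate_windows()] output); defaults to the full 144-window set.
#' @param variant Enumeration variant, see [enumerate_windows()].
#'
#' @return A tibble with one row per candidate: the window fields plus
#'   `rho`, `p_value`, `n_years` (`NA` where the correlation is undefined).
#' @export
scan_windows <- function(abundance, climate, variable,
                         season = c("breeding", "wintering"),
                         windows = NULL, variant = "stepback") {
  season <- match.arg(season)
  variable <- match.arg(variable, climate_variables())
  if (is.null(windows)) {
    windows <- enumerate_windows(variable, season, variant)
  }
  abundance <- dplyr::filter(abundance, !is.na(.data$value))
  n_y <- nrow(abundance)
  if (n_y < 4) {
    rlang::abort("need at least 4 season-years of abundance.",
                 class = "climwindow_invalid_argument")
  }
  if (n_y < 8) {
    rlang::warn("fewer than 8 season-years: window scan will be unstable.")
  }
  lookup <- rolling_lookup(climate, variable)
  winter_shift <- as.integer(season == "wintering")
  res <- vapply(seq_len(nrow(windows)), function(i) {
    anchor <- abundance$season_year + winter_shift + windows$year_offset[i]
    w <- lookup(month_index(anchor, windows$end_month[i]),
                windows$duration[i])
    ok <- !is.na(w)
    n_ok <- sum(ok)
    if (n_ok < 4 ||
        stats::sd(w[ok]) == 0 || stats::sd(abundance$value[ok]) == 0) {
      return(c(NA_real_, NA_real_, n_ok))
    }
    # same computation as spearman_correlation(), inlined for the hot loop
    rho <- max(-1, min(1, stats::cor(rank(w[ok]), rank(abundance$value[ok]))))
    p <- if (abs(rho) == 1) 0 else {
      2 * stats::pt(-abs(rho * sqrt((n_ok - 2) / (1 - rho^2))), df = n_ok - 2)
    }
    c(rho, p, n_ok)
  }, numeric(3))
  dplyr::bind_cols(windows,
                   tibble::tibble(rho = res[1, ], p_value = res[2, ],
                                  n_years = as.integer(res[3, ])))
}

#' Best window of one climatic variable
#'
#' Exhaustively scans the candidate set and returns the window with the
#' highest absolute Spearman correlation. Ties are broken deterministically:
#' shorter duration first, then the end month closest to the season's
#' reference month, then the focal year before the previous year.
#'
#' @inheritParams scan_windows
#' @param species Optional species label carried into the result.
#'
#' @return A one-row tibble: `species`, `season`, `variable`, `duration`,
#'   `end_month`, `year_offset`, `rho`, `p_value`, `n_years`.
#' @export
scan_best_window <- function(abundance, climate, variable,
                             season = c("breeding", "wintering"),
                             species = NA_character_,
                             windows = NULL, variant = "stepback") {
  season <- match.arg(season)
  scanned <- scan_windows(abundance, climate, variable, season,
                          windows = windows, variant = variant)
  scanned <- dplyr::filter(scanned, !is.na(.data$rho))
  if (nrow(scanned) == 0) {
    rlang::abort("no candidate window had a defined correlation.",
                 class = "climwindow_no_result")
  }
  best <- scanned |>
    dplyr::arrange(dplyr::desc(abs(.data$rho)), .data$duration,
                   .data$months_back, dplyr::desc(.data$year_offset)) |>
    dplyr::slice(1)
  tibble::tibble(
    species = species, season = season,
    variable = best$variable, duration = best$duration,
    end_month = best$end_month, year_offset = best$year_offset,
    rho = best$rho, p_value = best$p_value, n_years = best$n_years
  )
}

#' Select the best-performing climatic variable
#'
#' Given the best window per climatic variable (rows from
#' [scan_best_window()]), returns the one with the highest absolute
#' correlation. Exact ties are resolved by a fixed priority order (spei,
#' tmax, tm, tmin, precip) with a warning.
#'
#' @param results Data frame of best-window rows, one per variable.
#' @return A one-row tibble, the winning row of `results`.
#' @export
select_best_variable <- function(results) {
  results <- dplyr::filter(results, !is.na(.data$rho))
  if (nrow(results) == 0) {
    rlang::abort("no scan result to select from.",
                 class = "climwindow_no_result")
  }
  priority <- c(spei = 1, tmax = 2, tm = 3, tmin = 4, precip = 5)
  ranked <- results |>
    dplyr::mutate(.prio = priority[.data$variable]) |>
    dplyr::arrange(dplyr::desc(abs(.data$rho)), .data$.prio)
  if (nrow(ranked) > 1 && abs(ranked$rho[1]) == abs(ranked$rho[2])) {
    rlang::warn(sprintf(
      "tied |rho| between variables %s and %s; '%s' chosen by priority order.",
      ranked$variable[1], ranked$variable[2], ranked$variable[1]))
  }
  dplyr::select(ranked[1, ], -".prio")
}

#' Do two candidate windows share any months?
#'
#' Two windows (for the same season) overlap when the month spans they
#' aggregate, anchored to the same season-year, intersect.
#'
#' @param w1,w2 Windows (lists or one-row data frames with `duration`,
#'   `end_month`, `year_offset`).
#' @param season `"wintering"` or `"breeding"`.
#' @return Logical scalar.
#' @export
window_overlaps <- function(w1, w2, season = c("breeding", "wintering")) {
  season <- match.arg(season)
  shift <- as.integer(season == "wintering")
  span <- function(w) {
    end <- month_index(shift + w$year_offset, w$end_month)
    seq(end - w$duration + 1L, end)
  }
  length(intersect(span(w1), span(w2))) > 0
}
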