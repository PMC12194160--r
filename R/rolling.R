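#' Rolling aggregation of a monthly series
#'
#' Right-aligned rolling mean or sum over a gapless ordered monthly sequence:
#' element *i* of the output aggregates input elements *i* .. *i* +
#' `duration` - 1. Temperature and drought-index series are aggregated with
#' the mean; precipitation with the sum. A missing value anywhere inside a
#' window makes that window's output `NA`.
#'
#' @param values Numeric vector, one element per consecutive month.
#' @param duration Window length in months (1--12 in the scan, but any
#'   `1 <= duration <= length(values)` is accepted).
#' @param agg `"mean"` or `"sum"`.
#'
#' @return Numeric vector of length `length(values) - duration + 1`.
#'
#' @examples
#' rolling_aggregate(c(1, 2, 3), 2, "mean")
#' rolling_aggregate(c(5, 5, 5, 5), 4, "sum")
#' @export
rolling_aggregate <- function(values, duration, agg = c("mean", "sum")) {
  agg <- match.arg(agg)
  if (!is.numeric(duration) || length(duration) != 1L || is.na(duration) ||
      duration < 1 || duration != round(duration)) {
    rlang::abort("`duration` must be a single positive integer.",
                 class = "climwindow_invalid_argument")
  }
  if (duration > length(values)) {
    rlang::abort("`duration` exceeds the length of `values`.",
                 class = "climwindow_invalid_argument")
  }
  fun <- if (agg == "mean") mean else sum
  as.numeric(zoo::rollapply(values, width = duration, FUN = fun,
                            align = "right", fill = NULL))
}
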