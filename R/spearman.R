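#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average-ranked data (ties receive mid-ranks), the
#' statistic used to rank candidate climate windows. Pairs with a missing
#' value in either vector are deleted pairwise before ranking. The p-value
#' uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom, two-sided.
#'
#' @param x,y Numeric vectors of equal length; at least 4 complete pairs.
#'
#' @return A one-row tibble with columns `rho`, `p_value`, `n`.
#'
#' @examples
#' spearman_correlation(1:4, c(10, 20, 30, 40))
#' spearman_correlation(1:4, 4:1)
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    rlang::abort("`x` and `y` must have equal length.",
                 class = "climwindow_invalid_argument")
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 4) {
    rlang::abort("need at least 4 complete pairs.",
                 class = "climwindow_invalid_argument")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("correlation undefined: an input has zero variance.",
                 class = "climwindow_undefined_correlation")
  }
  rho <- stats::cor(rank(x), rank(y))
  # guard against tiny numerical overshoot beyond +/-1
  rho <- max(-1, min(1, rho))
  if (abs(rho) == 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  tibble::tibble(rho = rho, p_value = p, n = n)
}
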