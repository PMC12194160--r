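#' Fit a quasi-Poisson GLM to count data
#'
#' Log-link quasi-Poisson regression: point estimates are the Poisson
#' maximum-likelihood estimates, standard errors are Poisson standard errors
#' inflated by `sqrt(phi)` where `phi` is the Pearson dispersion
#' `X^2 / (n - p)`, statistics are t on `n - p` degrees of freedom, and 95%
#' confidence intervals are Wald t intervals. IRLS runs to a relative
#' deviance change below 1e-8 (at most 100 iterations) from starting means
#' `y + 0.5`.
#'
#' @param formula Model formula; the response must be non-negative integer
#'   counts.
#' @param data Data frame containing the variables in `formula`.
#' @param conf_level Confidence level for the Wald intervals (default 0.95).
#'
#' @return An object of class `qp_fit` with [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods. `tidy()` gives one row per term
#'   (`term`, `estimate`, `std.error`, `statistic`, `p.value`, `conf.low`,
#'   `conf.high`); `glance()` gives `dispersion`, `deviance`, `logLik`
#'   (Poisson log-likelihood at dispersion 1), `df.residual`, `nobs`.
#'
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 6))
#' fit <- fit_quasipoisson(y ~ 1, d)
#' tidy(fit)
#' @export
fit_quasipoisson <- function(formula, data, conf_level = 0.95) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (any(y < 0) || any(y != round(y))) {
    rlang::abort("counts must be non-negative integers.",
                 class = "climwindow_invalid_argument")
  }
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) {
    rlang::abort("design matrix is rank-deficient (collinear predictors).",
                 class = "climwindow_singular_design")
  }
  if (nrow(X) <= ncol(X)) {
    rlang::abort("need more observations than parameters.",
                 class = "climwindow_invalid_argument")
  }
  # glm() evaluates `mustart` in the data/formula environment, so stage the
  # starting means (y + 0.5) there
  env <- new.env(parent = environment(formula) %||% parent.frame())
  env$.mu_start <- y + 0.5
  environment(formula) <- env
  fit <- stats::glm(formula, data = data, family = stats::quasipoisson(),
                    mustart = .mu_start,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) {
    rlang::abort("IRLS did not converge within 100 iterations.",
                 class = "climwindow_convergence_error")
  }
  mu <- stats::fitted(fit)
  df_res <- fit$df.residual
  phi <- sum((y - mu)^2 / mu) / df_res
  phi_floored <- FALSE
  if (phi <= 100 * .Machine$double.eps) {
    phi <- .Machine$double.eps
    phi_floored <- TRUE
    rlang::warn("zero-variance counts: dispersion floored at machine epsilon.")
  }
  est <- stats::coef(fit)
  # Poisson (dispersion = 1) covariance evaluated at the converged means
  # (glm's stored QR carries the previous iteration's working weights)
  cov_pois <- chol2inv(chol(crossprod(X * sqrt(mu))))
  se_pois <- sqrt(diag(cov_pois))
  se <- se_pois * sqrt(phi)
  tstat <- est / se
  p <- 2 * stats::pt(-abs(tstat), df = df_res)
  crit <- stats::qt(1 - (1 - conf_level) / 2, df = df_res)
  ll <- sum(stats::dpois(y, mu, log = TRUE))
  structure(
    list(
      coefficients = tibble::tibble(
        term = names(est), estimate = unname(est), std.error = unname(se),
        statistic = unname(tstat), p.value = unname(p),
        conf.low = unname(est - crit * se), conf.high = unname(est + crit * se)
      ),
      dispersion = phi, dispersion_floored = phi_floored,
      deviance = stats::deviance(fit), logLik = ll,
      n_obs = length(y), df_residual = df_res,
      family = "quasipoisson", conf_level = conf_level,
      formula = formula, glm = fit
    ),
    class = "qp_fit"
  )
}

#' @export
print.qp_fit <- function(x, ...) {
  cat("Quasi-Poisson GLM:", deparse(x$formula), "\n")
  cat(sprintf("n = %d, residual df = %d, Pearson dispersion = %.4g\n",
              x$n_obs, x$df_residual, x$dispersion))
  print(x$coefficients)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_quasipoisson
#' @param x A `qp_fit` object.
#' @param ... Unused.
#' @method tidy qp_fit
#' @export
tidy.qp_fit <- function(x, ...) x$coefficients

#' @rdname fit_quasipoisson
#' @method glance qp_fit
#' @export
glance.qp_fit <- function(x, ...) {
  tibble::tibble(
    dispersion = x$dispersion, deviance = x$deviance, logLik = x$logLik,
    df.residual = x$df_residual, nobs = x$n_obs, family = x$family
  )
}

#' Cameron-Trivedi overdispersion test for count data
#'
#' Tests equidispersion (variance equal to the mean) against the linear
#' alternative variance = (1 + alpha) * mean, via the auxiliary statistic
#' `s_i = ((y_i - mu_i)^2 - y_i) / mu_i` from a Poisson fit: the one-sided z
#' statistic is `sqrt(n) * mean(s) / sd(s)` and `alpha` is estimated by
#' `mean(s)`.
#'
#' @param y Non-negative integer counts, or a `qp_fit` object (its response
#'   and fitted means are reused).
#' @param data Data frame for `formula` when `y` is a vector response name;
#'   alternatively pass `y` as a numeric vector and `formula` as a one-sided
#'   RHS applied to `data`. Simplest usage: `overdispersion_test(y)` for an
#'   intercept-only mean.
#' @param formula Optional RHS formula (default intercept-only).
#'
#' @return A one-row tibble: `statistic` (z), `p_value` (one-sided, upper),
#'   `alpha` (estimated excess-variance coefficient).
#'
#' @examples
#' overdispersion_test(rpois(200, 5))
#' @export
overdispersion_test <- function(y, data = NULL, formula = ~1) {
  if (inherits(y, "qp_fit")) {
    mu <- stats::fitted(y$glm)
    yv <- y$glm$y
  } else {
    if (any(y < 0) || any(y != round(y))) {
      rlang::abort("counts must be non-negative integers.",
                   class = "climwindow_invalid_argument")
    }
    if (is.null(data)) data <- data.frame(row.names = seq_along(y))
    fml <- stats::update(formula, .y ~ .)
    data$.y <- y
    fit <- stats::glm(fml, data = data, family = stats::poisson())
    mu <- stats::fitted(fit)
    yv <- y
  }
  s <- ((yv - mu)^2 - yv) / mu
  z <- sqrt(length(s)) * mean(s) / stats::sd(s)
  tibble::tibble(statistic = z,
                 p_value = stats::pnorm(z, lower.tail = FALSE),
                 alpha = mean(s))
}

#' Likelihood-ratio test for a species effect on counts
#'
#' Compares a count model with species as a categorical predictor against
#' the intercept-only null. The chi-square statistic is twice the Poisson
#' log-likelihood difference (what a likelihood-ratio test applied to
#' quasi-Poisson fits computes numerically); because quasi-likelihoods admit
#' no true LR, a dispersion-scaled F variant is reported alongside:
#' `F = chi2 / (df * phi)` on (`df`, `n - k`) degrees of freedom, with `phi`
#' the Pearson dispersion of the species model.
#'
#' @param counts Data frame with columns `species` and `count`.
#'
#' @return A one-row tibble: `chi2`, `df`, `p_value`, `f_statistic`,
#'   `f_p_value`, `dispersion`.
#' @export
lr_species_test <- function(counts) {
  if (length(unique(counts$species)) < 2) {
    rlang::abort("need at least 2 species.",
                 class = "climwindow_invalid_argument")
  }
  fit1 <- fit_quasipoisson(count ~ species, counts)
  fit0 <- fit_quasipoisson(count ~ 1, counts)
  chi2 <- 2 * (fit1$logLik - fit0$logLik)
  df <- length(unique(counts$species)) - 1L
  fstat <- chi2 / (df * fit1$dispersion)
  tibble::tibble(
    chi2 = chi2, df = df,
    p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
    f_statistic = fstat,
    f_p_value = stats::pf(fstat, df, fit1$df_residual, lower.tail = FALSE),
    dispersion = fit1$dispersion
  )
}

#' Temporal trend of a yearly (or monthly) series
#'
#' Regression of a response on calendar year, centred at its mean before any
#' squaring: Gaussian ordinary least squares for climate and vegetation
#' responses, quasi-Poisson for counts. With `quadratic = TRUE` both the
#' linear and quadratic (centred) year terms are fitted.
#'
#' @param data Data frame containing the response and a year column.
#' @param response Name of the response column (string).
#' @param family `"gaussian"` or `"quasipoisson"`.
#' @param quadratic Include a centred-year-squared term?
#' @param year_col Name of the year column (default `"year"`).
#'
#' @return An object of class `trend_fit`; `tidy()` returns the term table
#'   (slope per year on the response's link scale), `glance()` the fit
#'   summary. The `slope`, `t_statistic` and `p_value` of the linear year
#'   term are stored as top-level fields.
#'
#' @examples
#' d <- data.frame(year = 2001:2010, v = 2 * (2001:2010 - 2000))
#' fit_trend(d, "v")$slope
#' @export
fit_trend <- function(data, response, family = c("gaussian", "quasipoisson"),
                      quadratic = FALSE, year_col = "year") {
  family <- match.arg(family)
  if (nrow(data) < 4) {
    rlang::abort("need at least 4 years.",
                 class = "climwindow_invalid_argument")
  }
  d <- data.frame(.y = data[[response]],
                  .yr = data[[year_col]] - mean(data[[year_col]]))
  if (nrow(d) < (2 + quadratic) + 1) {
    rlang::abort("fewer years than parameters + 1.",
                 class = "climwindow_invalid_argument")
  }
  fml <- if (quadratic) .y ~ .yr + I(.yr^2) else .y ~ .yr
  if (family == "gaussian") {
    fit <- stats::lm(fml, data = d)
    sm <- stats::summary.lm(fit)$coefficients
    if (stats::sd(d$.y) == 0) {
      # flat series: report zero slope/statistic rather than 0/0 noise
      sm[, 1] <- c(mean(d$.y), rep(0, nrow(sm) - 1))
      sm[, 2:4] <- 0
      sm[-1, 4] <- 1
    }
    ci <- stats::confint(fit)
    coefs <- tibble::tibble(
      term = rownames(sm), estimate = unname(sm[, 1]),
      std.error = unname(sm[, 2]), statistic = unname(sm[, 3]),
      p.value = unname(sm[, 4]),
      conf.low = unname(ci[, 1]), conf.high = unname(ci[, 2])
    )
    extra <- list(glm = fit, dispersion = stats::sigma(fit)^2)
  } else {
    qp <- fit_quasipoisson(fml, d)
    coefs <- qp$coefficients
    extra <- list(glm = qp$glm, dispersion = qp$dispersion)
  }
  coefs$term <- sub("^\\.yr$", "year", coefs$term)
  coefs$term <- sub("^I\\(\\.yr\\^2\\)$", "year^2", coefs$term)
  lin <- coefs[coefs$term == "year", ]
  structure(
    list(
      coefficients = coefs, slope = lin$estimate,
      t_statistic = lin$statistic, p_value = lin$p.value,
      quadratic = quadratic, year_center = mean(data[[year_col]]),
      family = family, response = response,
      dispersion = extra$dispersion, fit = extra$glm,
      data = d
    ),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("%s trend of '%s' (year centred at %.1f)\n",
              x$family, x$response, x$year_center))
  print(x$coefficients)
  invisible(x)
}

#' @rdname fit_trend
#' @param x A `trend_fit` object.
#' @param ... Unused.
#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, ...) x$coefficients

#' @rdname fit_trend
#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, t_statistic = x$t_statistic, p_value = x$p_value,
    quadratic = x$quadratic, year_center = x$year_center,
    family = x$family, response = x$response
  )
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing predictor
#' *j* on the remaining predictors (with intercept). Perfect collinearity
#' yields `Inf` with a warning. Values below 2 indicate low collinearity.
#'
#' @param X Data frame or matrix of at least two numeric predictor columns
#'   (no intercept column).
#'
#' @return Named numeric vector of per-predictor VIFs.
#'
#' @examples
#' vif(data.frame(a = rnorm(20), b = rnorm(20)))
#' @export
vif <- function(X) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) {
    rlang::abort("need at least 2 predictors.",
                 class = "climwindow_invalid_argument")
  }
  out <- vapply(seq_along(X), function(j) {
    r2 <- stats::summary.lm(
      stats::lm(X[[j]] ~ ., data = X[-j])
    )$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- names(X)
  if (any(is.infinite(out))) {
    rlang::warn("perfectly collinear predictors: infinite VIF.")
  }
  out
}

#' Additive climate + vegetation model of seasonal counts
#'
#' Quasi-Poisson regression of within-season monthly counts on the selected
#' climate window's value (constant within a season-year) and, optionally,
#' yearly vegetation cover. Variance inflation factors are computed first
#' when both predictors are present and attached to the fit.
#'
#' @param counts Data frame with columns `season_year` and `count`
#'   (monthly counts restricted to one species and one season).
#' @param climate_values Data frame with columns `season_year` and
#'   `climate` (the selected window's value per season-year).
#' @param vegetation Optional data frame with columns `year` and
#'   `percent_cover`; joined on `season_year == year`. `NULL` fits the
#'   climate-only model.
#'
#' @return A `qp_fit` (see [fit_quasipoisson()]) with a `vif` element when
#'   vegetation is included.
#' @export
fit_climate_vegetation_model <- function(counts, climate_values,
                                         vegetation = NULL) {
  d <- dplyr::inner_join(counts, climate_values, by = "season_year")
  if (!is.null(vegetation)) {
    d <- dplyr::inner_join(
      d,
      dplyr::select(vegetation, season_year = "year",
                    vegetation = "percent_cover"),
      by = "season_year"
    )
    fml <- count ~ climate + vegetation
  } else {
    fml <- count ~ climate
  }
  d <- dplyr::filter(d, !is.na(.data$count), !is.na(.data$climate))
  vifs <- NULL
  if (!is.null(vegetation)) {
    d <- dplyr::filter(d, !is.na(.data$vegetation))
    if (stats::sd(d$climate) > 0 && stats::sd(d$vegetation) > 0 &&
        abs(stats::cor(d$climate, d$vegetation)) >= 1 - 1e-12) {
      rlang::abort("climate and vegetation are perfectly collinear.",
                   class = "climwindow_singular_design")
    }
    vifs <- vif(d[c("climate", "vegetation")])
  }
  fit <- fit_quasipoisson(fml, d)
  fit$vif <- vifs
  fit
}
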