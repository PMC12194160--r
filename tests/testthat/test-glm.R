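test_that("intercept-only quasi-Poisson matches closed-form algebra", {
  d <- data.frame(y = c(1L, 2L, 3L, 6L))
  fit <- fit_quasipoisson(y ~ 1, d)
  expect_equal(tidy(fit)$estimate, log(3), tolerance = 1e-8)
  phi <- sum((d$y - 3)^2 / 3) / 3
  expect_equal(fit$dispersion, phi, tolerance = 1e-8)
  expect_equal(tidy(fit)$std.error, sqrt(phi / (4 * 3)), tolerance = 1e-8)
})

test_that("zero-variance counts floor the dispersion at machine positive", {
  d <- data.frame(y = c(2L, 2L, 2L, 2L))
  expect_warning(fit <- fit_quasipoisson(y ~ 1, d), "floored")
  expect_equal(tidy(fit)$estimate, log(2), tolerance = 1e-9)
  expect_gt(fit$dispersion, 0)
  expect_true(fit$dispersion_floored)
})

test_that("point estimates equal an independent Poisson-likelihood maximizer", {
  withr::with_seed(101, {
    for (i in 1:5) {
      n <- 40
      x1 <- rnorm(n)
      x2 <- runif(n)
      y <- rpois(n, exp(1 + 0.5 * x1 - 0.8 * x2))
      d <- data.frame(y = y, x1 = x1, x2 = x2)
      fit <- fit_quasipoisson(y ~ x1 + x2, d)
      oracle <- poisson_mle_oracle(y, cbind(1, x1, x2))
      expect_equal(tidy(fit)$estimate, unname(oracle), tolerance = 1e-6)
    }
  })
})

test_that("quasi-Poisson estimates equal the Poisson MLE; only SEs scale by sqrt(phi)", {
  withr::with_seed(7, {
    n <- 60
    x <- rnorm(n)
    y <- rnbinom(n, mu = exp(1 + 0.4 * x), size = 2)
  })
  d <- data.frame(y = y, x = x)
  fit <- fit_quasipoisson(y ~ x, d)
  pois <- stats::glm(y ~ x, data = d, family = poisson())
  expect_equal(tidy(fit)$estimate, unname(coef(pois)), tolerance = 1e-7)
  se_pois <- unname(sqrt(diag(vcov(pois))))
  expect_equal(tidy(fit)$std.error, se_pois * sqrt(fit$dispersion),
               tolerance = 1e-5)
  # t statistics on residual df, Wald t confidence intervals
  td <- tidy(fit)
  expect_equal(td$statistic, td$estimate / td$std.error)
  crit <- qt(0.975, fit$df_residual)
  expect_equal(td$conf.high - td$estimate, crit * td$std.error)
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
})

test_that("invalid count responses and singular designs are rejected", {
  d <- data.frame(y = c(1.5, 2, 3, 4), x = 1:4)
  expect_error(fit_quasipoisson(y ~ x, d), class = "climwindow_invalid_argument")
  d <- data.frame(y = c(-1L, 2L, 3L, 4L), x = 1:4)
  expect_error(fit_quasipoisson(y ~ x, d), class = "climwindow_invalid_argument")
  d <- data.frame(y = c(1L, 2L, 3L, 4L), x = 1:4)
  d$x2 <- d$x * 2
  expect_error(fit_quasipoisson(y ~ x + x2, d),
               class = "climwindow_singular_design")
})

test_that("counts exactly at their fitted means give a non-positive dispersion statistic", {
  y <- rep(c(2L, 4L), each = 10)
  # intercept-only fit: mu = 3 everywhere, but construct y == mu exactly
  y_eq <- rep(3L, 20)
  out <- suppressWarnings(overdispersion_test(y_eq + 0L * y))
  expect_true(is.na(out$statistic) || out$statistic <= 0)
  # y == mu with variation: two groups fitted with a factor mean
  d <- data.frame(g = rep(c("a", "b"), each = 10))
  out2 <- overdispersion_test(y, data = d, formula = ~g)
  expect_lte(out2$statistic, 0)
  expect_gte(out2$p_value, 0.5)
})

test_that("the overdispersion test rejects strongly overdispersed counts", {
  withr::with_seed(12, {
    y <- rnbinom(500, mu = 5, size = 5 * 5 / (15 - 5))  # variance 15
  })
  out <- overdispersion_test(y)
  expect_lt(out$p_value, 0.01)
  expect_gt(out$alpha, 0)
})

test_that("the species likelihood-ratio test behaves at its boundaries", {
  base <- rep(c(3L, 5L, 7L, 9L, 11L), 10)
  same <- tibble::tibble(species = rep(c("a", "b"), each = 50),
                         count = c(base, base))
  out <- lr_species_test(same)
  expect_equal(out$chi2, 0, tolerance = 1e-10)
  expect_equal(out$p_value, 1)

  withr::with_seed(4, {
    diffr <- tibble::tibble(
      species = rep(c("a", "b"), each = 50),
      count = c(rpois(50, 2), rpois(50, 200))
    )
  })
  out2 <- lr_species_test(diffr)
  expect_gt(out2$chi2, 1000)
  expect_lt(out2$p_value, 1e-10)
  expect_equal(out2$df, 1)
  expect_error(lr_species_test(tibble::tibble(species = "a", count = 1:5)),
               class = "climwindow_invalid_argument")
})

test_that("the species test matches an independent Poisson LR computation and is label-invariant", {
  withr::with_seed(15, {
    counts <- tibble::tibble(
      species = rep(c("a", "b", "c"), each = 30),
      count = rpois(90, rep(c(5, 9, 14), each = 30))
    )
  })
  out <- lr_species_test(counts)
  f1 <- stats::glm(count ~ species, data = counts, family = poisson())
  f0 <- stats::glm(count ~ 1, data = counts, family = poisson())
  expect_equal(out$chi2, as.numeric(2 * (logLik(f1) - logLik(f0))),
               tolerance = 1e-8)
  if (requireNamespace("lmtest", quietly = TRUE)) {
    lrt <- lmtest::lrtest(f0, f1)
    expect_equal(out$chi2, lrt$Chisq[2], tolerance = 1e-8)
    expect_equal(out$df, lrt$Df[2])
  }
  perm <- counts
  perm$species <- c(b = "c", c = "a", a = "b")[perm$species]
  expect_equal(lr_species_test(perm)$chi2, out$chi2, tolerance = 1e-10)
})

test_that("trend fits recover exact lines and match the closed-form OLS oracle", {
  d <- data.frame(year = 2001:2010, v = 2 * (2001:2010 - 2000))
  tr <- fit_trend(d, "v")
  expect_equal(tr$slope, 2, tolerance = 1e-10)
  expect_lt(tr$p_value, 1e-12)

  flat <- data.frame(year = 2001:2010, v = rep(4.2, 10))
  tr0 <- fit_trend(flat, "v")
  expect_equal(tr0$slope, 0, tolerance = 1e-12)
  expect_equal(tr0$t_statistic, 0, tolerance = 1e-6)

  withr::with_seed(22, {
    d <- data.frame(year = 2001:2010, v = rnorm(10, 3, 2))
  })
  tr <- fit_trend(d, "v")
  oracle <- ols_oracle(d$year - mean(d$year), d$v)
  expect_equal(tr$slope, unname(oracle["slope"]), tolerance = 1e-10)
  td <- tidy(tr)
  expect_equal(td$std.error[td$term == "year"], unname(oracle["se"]),
               tolerance = 1e-10)
})

test_that("quadratic trends use centred year and nest the linear fit", {
  withr::with_seed(30, {
    d <- data.frame(year = 2002:2019, v = rnorm(18, 10))
  })
  q <- fit_trend(d, "v", quadratic = TRUE)
  expect_setequal(tidy(q)$term, c("(Intercept)", "year", "year^2"))
  expect_equal(q$year_center, mean(2002:2019))
  # with the quadratic coefficient constrained to zero the linear fit returns
  lin <- fit_trend(d, "v")
  d2 <- d
  d2$v <- d$v  # same data: the linear term of the linear fit is the oracle
  expect_equal(lin$slope,
               ols_oracle(d$year - mean(d$year), d$v)[["slope"]])
  expect_error(fit_trend(d[1:3, ], "v"), class = "climwindow_invalid_argument")
})

test_that("quasi-Poisson trend fits work on count responses", {
  withr::with_seed(40, {
    yrs <- 2002:2019
    d <- data.frame(year = yrs, count = rpois(18, exp(2 + 0.08 * (yrs - 2010))))
  })
  tr <- fit_trend(d, "count", family = "quasipoisson")
  expect_gt(tr$slope, 0)
  expect_equal(glance(tr)$family, "quasipoisson")
})

test_that("VIF matches closed forms and flags collinearity", {
  withr::with_seed(50, {
    X <- data.frame(a = rnorm(200), b = rnorm(200))
  })
  v <- vif(X)
  expect_equal(unname(v), c(1, 1), tolerance = 0.05)

  # three predictors with exact pairwise correlation 0.5: VIF = 1.5 each
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  L <- chol(S)
  withr::with_seed(51, Z <- matrix(rnorm(900), 300, 3))
  Zo <- qr.Q(qr(scale(Z, scale = FALSE)))  # orthonormal columns
  Xc <- as.data.frame(Zo %*% L)
  v3 <- vif(Xc)
  expect_equal(unname(v3), rep(1.5, 3), tolerance = 1e-8)
  if (requireNamespace("car", quietly = TRUE)) {
    y <- rnorm(300)
    fit <- lm(y ~ ., data = Xc)
    expect_equal(unname(v3), unname(car::vif(fit)), tolerance = 1e-6)
  }

  near <- data.frame(a = rnorm(100))
  near$b <- near$a + rnorm(100, sd = 1e-4)
  expect_gt(max(vif(near)), 10)
  exact <- data.frame(a = 1:50, b = 2 * (1:50))
  expect_warning(v_inf <- vif(exact), "collinear")
  expect_true(any(is.infinite(v_inf)))
  expect_error(vif(data.frame(a = 1:5)), class = "climwindow_invalid_argument")
})

test_that("the additive climate + vegetation model fits and rejects duplicate predictors", {
  withr::with_seed(60, {
    sy <- 2002:2019
    clim_val <- rnorm(18)
    veg <- tibble::tibble(year = sy, percent_cover = 20 + 2.7 * (sy - 2002))
    counts <- tibble::tibble(
      season_year = rep(sy, each = 6),
      count = rpois(108, exp(3 + 0.4 * rep(clim_val, each = 6)))
    )
  })
  cv <- tibble::tibble(season_year = sy, climate = clim_val)
  fit <- fit_climate_vegetation_model(counts, cv, veg)
  expect_s3_class(fit, "qp_fit")
  expect_setequal(tidy(fit)$term, c("(Intercept)", "climate", "vegetation"))
  expect_length(fit$vif, 2)

  clim_only <- fit_climate_vegetation_model(counts, cv)
  expect_setequal(tidy(clim_only)$term, c("(Intercept)", "climate"))
  expect_null(clim_only$vif)

  dup_veg <- tibble::tibble(year = sy, percent_cover = clim_val)
  expect_error(fit_climate_vegetation_model(counts, cv, dup_veg),
               class = "climwindow_singular_design")
})
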