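test_that("the candidate set has 144 windows: 12 durations x 12 positions", {
  for (season in c("wintering", "breeding")) {
    for (v in c("tm", "tmin", "tmax", "precip", "spei")) {
      w <- enumerate_windows(v, season)
      expect_equal(nrow(w), 144)
      expect_setequal(unique(w$duration), 1:12)
      expect_equal(anyDuplicated(w[c("duration", "end_month", "year_offset")]), 0)
      expect_true(all(w$year_offset %in% c(0L, -1L)))
    }
  }
})

test_that("candidate end months reach the previous year; SPEI 12-month windows ending in April (wintering) and March (breeding) exist", {
  ww <- enumerate_windows("spei", "wintering")
  expect_true(any(ww$duration == 12 & ww$end_month == 4))
  wb <- enumerate_windows("spei", "breeding")
  expect_true(any(wb$duration == 12 & wb$end_month == 3))
  expect_true(any(ww$year_offset == -1) && any(ww$year_offset == 0))
})

test_that("precipitation windows sum while other variables average", {
  expect_equal(unique(enumerate_windows("precip", "breeding")$agg), "sum")
  expect_equal(unique(enumerate_windows("tmax", "breeding")$agg), "mean")
  expect_equal(window_agg("precip"), "sum")
  expect_equal(window_agg("spei"), "mean")
})

test_that("the per-year enumeration variant yields 288 candidates", {
  w <- enumerate_windows("spei", "breeding", variant = "per_year")
  expect_equal(nrow(w), 288)
  expect_equal(anyDuplicated(w[c("duration", "end_month", "year_offset")]), 0)
})

test_that("unknown variables are rejected", {
  expect_error(enumerate_windows("humidity", "breeding"))
})

test_that("window values reproduce hand-computed aggregates", {
  clim <- make_climate(2001:2006, spei = 0.5, precip = 10,
                       tm = function(m) as.numeric(m))
  # constant spei -> the window mean is the constant
  w <- list(variable = "spei", duration = 7, end_month = 11, year_offset = -1L)
  expect_equal(window_values(clim, w, "breeding", 2003:2005), rep(0.5, 3))
  # constant 10 mm precipitation, 3-month window -> 30
  w <- list(variable = "precip", duration = 3, end_month = 5, year_offset = 0L)
  expect_equal(window_values(clim, w, "breeding", 2004), 30)
  # tm equal to the month index: Nov-Dec mean = 11.5
  w <- list(variable = "tm", duration = 2, end_month = 12, year_offset = -1L)
  expect_equal(window_values(clim, w, "breeding", 2004), 11.5)
})

test_that("season-years whose window span leaves the series give NA", {
  clim <- make_climate(2001:2006, spei = 0.5)
  w <- list(variable = "spei", duration = 12, end_month = 3, year_offset = -1L)
  # season-years 2001 and 2002 need months from 1999-2000, before the series
  vals <- window_values(clim, w, "breeding", 2001:2004)
  expect_true(all(is.na(vals[1:2])))
  expect_equal(vals[3:4], c(0.5, 0.5))
})

test_that("wintering windows anchor on the season's ending calendar year", {
  clim <- make_climate(2001:2006)
  clim$spei <- ifelse(clim$year == 2005 & clim$month == 1, 3, 0)
  # wintering season 2004 ends in February 2005: a 1-month window ending
  # January (offset 0) must hit January 2005
  w <- list(variable = "spei", duration = 1, end_month = 1, year_offset = 0L)
  expect_equal(window_values(clim, w, "wintering", 2004), 3)
  expect_equal(window_values(clim, w, "wintering", 2003), 0)
})

test_that("a degenerate single-candidate scan equals the direct correlation", {
  withr::with_seed(21, {
    clim <- make_climate(2001:2019)
    clim$spei <- rnorm(nrow(clim))
    ab <- tibble::tibble(season_year = 2002:2019,
                         value = rgamma(18, 10))
  })
  single <- enumerate_windows("spei", "breeding")[1, ]
  best <- scan_best_window(ab, clim, "spei", "breeding", windows = single)
  w <- window_values(clim, as.list(single), "breeding", ab$season_year)
  direct <- spearman_correlation(w, ab$value)
  expect_equal(best$rho, direct$rho)
  expect_equal(best$p_value, direct$p_value)
  expect_equal(best$duration, single$duration)
})

test_that("the scan is exhaustive: no candidate beats the returned |rho|", {
  withr::with_seed(33, {
    clim <- make_climate(2000:2019)
    for (v in c("tm", "tmin", "tmax", "precip", "spei")) {
      clim[[v]] <- clim[[v]] + rnorm(nrow(clim))
    }
    ab <- tibble::tibble(season_year = 2002:2019, value = rgamma(18, 5))
  })
  for (season in c("breeding", "wintering")) {
    best <- scan_best_window(ab, clim, "spei", season)
    all_rho <- scan_windows(ab, clim, "spei", season)$rho
    expect_true(all(abs(all_rho) <= abs(best$rho) + 1e-12, na.rm = TRUE))
    # brute-force re-scan of every candidate straight from window_values
    brute <- vapply(seq_len(144), function(i) {
      w <- as.list(enumerate_windows("spei", season)[i, ])
      vals <- window_values(clim, w, season, ab$season_year)
      ok <- !is.na(vals)
      if (sum(ok) < 4) return(NA_real_)
      cor(rank(vals[ok]), rank(ab$value[ok]))
    }, numeric(1))
    expect_equal(max(abs(brute), na.rm = TRUE), abs(best$rho))
  }
})

test_that("reversing the abundance ordering flips rho but not the selected window", {
  withr::with_seed(14, {
    clim <- make_climate(2000:2016)
    clim$spei <- rnorm(nrow(clim))
    ab <- tibble::tibble(season_year = 2002:2016, value = rgamma(15, 5))
  })
  best <- scan_best_window(ab, clim, "spei", "breeding")
  flipped <- ab
  flipped$value <- max(ab$value) + min(ab$value) - ab$value
  best_f <- scan_best_window(flipped, clim, "spei", "breeding")
  expect_equal(best_f$rho, -best$rho)
  expect_equal(best_f[c("duration", "end_month", "year_offset")],
               best[c("duration", "end_month", "year_offset")])
})

test_that("the best variable is the one with maximal |rho|; ties fall to the priority order", {
  res <- tibble::tibble(
    species = "s", season = "breeding",
    variable = c("tm", "tmax", "precip"),
    duration = 1L, end_month = 3L, year_offset = 0L,
    rho = c(0.2, 0.7, -0.5), p_value = 0.05, n_years = 18L
  )
  expect_equal(select_best_variable(res)$variable, "tmax")
  expect_equal(select_best_variable(res[1, ])$variable, "tm")
  tie <- res
  tie$variable <- c("spei", "tmax", "precip")
  tie$rho <- c(0.7, 0.7, 0.1)
  expect_warning(pick <- select_best_variable(tie), "tie")
  expect_equal(pick$variable, "spei")
  expect_error(select_best_variable(res[0, ]), class = "climwindow_no_result")
})

test_that("window overlap detection respects durations, end months and year offsets", {
  w1 <- list(duration = 12L, end_month = 3L, year_offset = 0L)
  w2 <- list(duration = 1L, end_month = 6L, year_offset = -1L)   # inside w1
  w3 <- list(duration = 2L, end_month = 3L, year_offset = -1L)   # one year earlier
  expect_true(window_overlaps(w1, w2, "breeding"))
  expect_false(window_overlaps(w1, w3, "breeding"))
  expect_true(window_overlaps(w1, w1, "breeding"))
})
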