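# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Poisson maximum likelihood via a generic numerical optimizer
poisson_mle_oracle <- function(y, X) {
  negll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(y * eta - exp(eta))
  }
  start <- c(log(mean(y) + 0.5), rep(0, ncol(X) - 1))
  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  opt$par
}

# Exact rank formula for tie-free data: 1 - 6 * sum(d^2) / (n (n^2 - 1))
spearman_exact_formula <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Brute-force average ranks (mid-ranks for ties), without rank()
average_ranks <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}

# Pearson correlation of brute-force average ranks
spearman_brute_force <- function(x, y) {
  rx <- average_ranks(x)
  ry <- average_ranks(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Closed-form OLS slope and its standard error
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  se <- sqrt(sum(resid^2) / (length(x) - 2) / sxx)
  c(slope = slope, se = se)
}

# A small balanced monthly count table
make_counts <- function(species = "sp1", years = 2002:2019,
                        count_fun = function(year, month) 10L) {
  grid <- expand.grid(year = years, month = 1:12)
  tibble::tibble(
    species = species, year = grid$year, month = grid$month,
    count = as.integer(mapply(count_fun, grid$year, grid$month))
  )
}

# A constant-valued climate grid covering `years`
make_climate <- function(years, spei = 0, precip = 10, tm = NULL) {
  grid <- expand.grid(year = years, month = 1:12)
  grid <- grid[order(grid$year, grid$month), ]
  tm_val <- if (is.null(tm)) rep(15, nrow(grid)) else tm(grid$month)
  tibble::tibble(
    year = grid$year, month = grid$month,
    tm = tm_val, tmin = tm_val - 5, tmax = tm_val + 5,
    precip = precip, spei = spei
  )
}

# Configuration used by the parameter-recovery experiments: one species,
# counts driven by a 12-month SPEI window ending in March of the breeding
# season's focal year, effect size beta on the log scale
recovery_config <- function(seed, beta = 0.446) {
  true_window <- list(variable = "spei", duration = 12L, end_month = 3L,
                      year_offset = 0L)
  effects <- if (beta != 0) {
    list(list(species = "species_B", season = "breeding", beta = beta,
              window = true_window))
  } else {
    list()
  }
  list(
    config = simulation_config(
      seed = seed,
      species_params = default_species_params()[2, ],
      effects = effects
    ),
    window = true_window,
    beta = beta
  )
}

# One recovery replicate: simulate, fit the quasi-Poisson model of monthly
# breeding counts on the true window's values, return the fit and inputs
recovery_fit <- function(seed, beta = 0.446) {
  rc <- recovery_config(seed, beta)
  study <- simulate_study(rc$config)
  monthly <- dplyr::mutate(
    study$counts,
    season = assign_season(month),
    season_year = dplyr::if_else(season == "wintering" & month %in% 1:2,
                                 year - 1L, as.integer(year))
  )
  d <- dplyr::filter(monthly, season == "breeding")
  sy <- sort(unique(d$season_year))
  cv <- tibble::tibble(
    season_year = sy,
    climate = window_values(study$climate, rc$window, "breeding", sy)
  )
  list(fit = fit_climate_vegetation_model(d, cv), study = study, rc = rc)
}
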