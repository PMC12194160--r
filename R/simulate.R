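#' Configuration for the synthetic study generator
#'
#' Bundles every parameter of the synthetic data: study span, species-level
#' count distributions, climate-effect injections, monthly climate
#' seasonality, and the vegetation trend. Defaults emulate the design the
#' package targets: an 18-year (2002--2019) monthly survey of four waterbird
#' species at a Mediterranean marsh (wet October--February, mean annual
#' temperature about 18.7 degrees C) with a linearly increasing vegetation
#' cover (+2.7 percentage points per year) and moderately overdispersed
#' counts (variance 3 times the mean).
#'
#' @param n_years Number of study years (default 18).
#' @param start_year First study year (default 2002). One extra leading
#'   climate year is always generated so previous-year windows are defined
#'   for the first study year.
#' @param species_params Tibble with one row per species: `species` label,
#'   `winter_mean` and `breed_mean` (expected monthly counts by season),
#'   `phi` (count variance/mean ratio, >= 1), `month_amplitude` (within-
#'   season log-scale cosine amplitude), `nest_mean` and `nest_trend`
#'   (yearly nest counts: mean level and log-linear trend per year).
#' @param effects List of climate/vegetation effect injections; each element
#'   a list with `species`, `season`, `beta` (log-scale effect of the true
#'   window's centred value), `window` (list with `variable`, `duration`,
#'   `end_month`, `year_offset`), and optional `veg_beta` (log-scale effect
#'   per centred percent cover).
#' @param climate List of climate-process parameters: `tm_mean`,
#'   `tm_amplitude` (annual cosine peaking in August), `tm_sd` (monthly
#'   noise), `temp_spread` and `spread_sd` (mean and noise of the tm-to-
#'   tmin/tmax half-range), `precip_monthly_mean` (12 monthly mm means,
#'   wet October--February), `precip_shape` (gamma shape), `spei_ar`
#'   (AR(1) coefficient of the standardized drought index).
#' @param vegetation List: `intercept` (% cover in `start_year`), `slope`
#'   (percentage points per year), `sd` (yearly noise).
#' @param seed Integer seed; all generators derive their streams from it.
#'
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_years = 18,
                              start_year = 2002,
                              species_params = default_species_params(),
                              effects = list(),
                              climate = list(),
                              vegetation = list(),
                              seed = 1L) {
  if (n_years < 2) {
    rlang::abort("`n_years` must be >= 2.", class = "climwindow_invalid_argument")
  }
  if (anyDuplicated(species_params$species) > 0) {
    rlang::abort("species labels must be unique.",
                 class = "climwindow_invalid_argument")
  }
  if (any(species_params$phi < 1)) {
    rlang::abort("per-species `phi` must be >= 1.",
                 class = "climwindow_invalid_argument")
  }
  climate_defaults <- list(
    tm_mean = 18.7, tm_amplitude = 7, tm_sd = 1,
    temp_spread = 5, spread_sd = 0.8,
    precip_monthly_mean = c(95, 85, 60, 45, 30, 10, 3, 8, 35, 80, 105, 115),
    precip_shape = 2, spei_ar = 0.5
  )
  vegetation_defaults <- list(intercept = 25, slope = 2.7, sd = 3)
  structure(
    list(
      n_years = as.integer(n_years), start_year = as.integer(start_year),
      species_params = species_params, effects = effects,
      climate = utils::modifyList(climate_defaults, climate),
      vegetation = utils::modifyList(vegetation_defaults, vegetation),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Default per-species simulation parameters
#'
#' Four synthetic species whose wintering/breeding monthly count levels and
#' nest counts mirror the magnitudes typical of a four-species waterbird
#' assemblage: one abundant diving duck (hundreds wintering), one
#' mid-abundance duck, and two scarce species (tens or fewer).
#'
#' @return A tibble, one row per species.
#' @export
default_species_params <- function() {
  tibble::tibble(
    species = c("species_A", "species_B", "species_C", "species_D"),
    winter_mean = c(700, 108, 13, 12),
    breed_mean = c(84, 28, 3, 6.5),
    phi = c(3, 3, 3, 3),
    month_amplitude = c(0.15, 0.15, 0.15, 0.15),
    nest_mean = c(26, 10, 9, 0.6),
    nest_trend = c(0.03, 0, 0.04, 0.05)
  )
}

sim_years <- function(config) {
  seq(config$start_year, length.out = config$n_years)
}

#' Generate a synthetic monthly climate series
#'
#' Produces `n_years + 1` years of monthly records (one leading burn-in year
#' so previous-year windows exist for the first study year): sinusoidal
#' temperatures with `tmin <= tm <= tmax` by construction, gamma-distributed
#' precipitation following a wet-winter monthly profile, and an AR(1)
#' drought index with marginal mean 0 and standard deviation 1.
#'
#' @param config A [simulation_config()].
#' @return A tibble with columns `year`, `month`, `tm`, `tmin`, `tmax`,
#'   `precip`, `spei`.
#' @export
generate_climate <- function(config) {
  cl <- config$climate
  years <- c(config$start_year - 1L, sim_years(config))
  grid <- tidyr::expand_grid(year = years, month = 1:12)
  n <- nrow(grid)
  withr::with_seed(config$seed, {
    tm <- cl$tm_mean + cl$tm_amplitude * cos(2 * pi * (grid$month - 8) / 12) +
      stats::rnorm(n, sd = cl$tm_sd)
    spread_lo <- cl$temp_spread + abs(stats::rnorm(n, sd = cl$spread_sd))
    spread_hi <- cl$temp_spread + abs(stats::rnorm(n, sd = cl$spread_sd))
    precip_mean <- cl$precip_monthly_mean[grid$month]
    precip <- stats::rgamma(n, shape = cl$precip_shape,
                            scale = precip_mean / cl$precip_shape)
    eps <- stats::rnorm(n, sd = sqrt(1 - cl$spei_ar^2))
    spei <- as.numeric(stats::filter(eps, cl$spei_ar, method = "recursive",
                                     init = stats::rnorm(1)))
  })
  tibble::tibble(
    year = grid$year, month = grid$month,
    tm = tm, tmin = tm - spread_lo, tmax = tm + spread_hi,
    precip = precip, spei = spei
  )
}

#' Generate synthetic monthly bird counts
#'
#' Overdispersed counts (negative binomial parameterized so the variance is
#' `phi` times the mean; Poisson when `phi` = 1) whose log-mean combines the
#' species' seasonal level, a zero-mean within-season cosine cycle, any
#' injected climate-window effect `beta * (window value, centred)`, and any
#' vegetation effect. One record per species, study year and month.
#'
#' @param config A [simulation_config()].
#' @param climate Monthly climate from [generate_climate()] (must include
#'   the leading year).
#' @param vegetation Optional yearly cover tibble from
#'   [generate_vegetation()]; required when any effect has a `veg_beta`.
#'
#' @return A tibble with columns `species`, `year`, `month`, `count`.
#' @export
generate_counts <- function(config, climate, vegetation = NULL) {
  sp <- config$species_params
  years <- sim_years(config)
  grid <- tidyr::expand_grid(species = sp$species, year = years, month = 1:12)
  grid$season <- assign_season(grid$month)
  grid$season_year <- dplyr::if_else(
    grid$season == "wintering" & grid$month %in% 1:2,
    grid$year - 1L, grid$year
  )
  # position of the month within its season (0..5), zero-mean cosine cycle
  month_pos <- c(4, 5, 0, 1, 2, 3, 4, 5, 0, 1, 2, 3)
  grid$pos <- month_pos[grid$month]
  grid <- dplyr::left_join(grid, sp, by = "species")
  log_mu <- log(ifelse(grid$season == "wintering",
                       grid$winter_mean, grid$breed_mean)) +
    grid$month_amplitude * cos(2 * pi * grid$pos / 6)

  for (eff in config$effects) {
    sel <- grid$species == eff$species & grid$season == eff$season
    if (!any(sel)) next
    sy <- sort(unique(grid$season_year[sel]))
    w <- window_values(climate, eff$window, eff$season, sy)
    wc <- w - mean(w, na.rm = TRUE)
    wc[is.na(wc)] <- 0
    log_mu[sel] <- log_mu[sel] + eff$beta * wc[match(grid$season_year[sel], sy)]
    veg_beta <- eff$veg_beta %||% 0
    if (veg_beta != 0) {
      if (is.null(vegetation)) {
        rlang::abort("`vegetation` is required when an effect has `veg_beta`.",
                     class = "climwindow_invalid_argument")
      }
      v <- vegetation$percent_cover[match(grid$season_year[sel],
                                          vegetation$year)]
      vc <- v - mean(vegetation$percent_cover)
      vc[is.na(vc)] <- 0
      log_mu[sel] <- log_mu[sel] + veg_beta * vc
    }
  }
  mu <- exp(log_mu)
  counts <- withr::with_seed(config$seed + 1L, {
    out <- integer(length(mu))
    pois <- grid$phi <= 1
    out[pois] <- stats::rpois(sum(pois), mu[pois])
    if (any(!pois)) {
      out[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois],
                                   size = mu[!pois] / (grid$phi[!pois] - 1))
    }
    out
  })
  tibble::tibble(species = grid$species, year = grid$year,
                 month = grid$month, count = counts) |>
    dplyr::arrange(.data$species, .data$year, .data$month)
}

#' Generate synthetic yearly nest counts
#'
#' Poisson draws around species-specific log-linear year trends centred on
#' the study midpoint; one record per species and year.
#'
#' @param config A [simulation_config()].
#' @return A tibble with columns `species`, `year`, `n_nests`.
#' @export
generate_nests <- function(config) {
  sp <- config$species_params
  years <- sim_years(config)
  grid <- tidyr::expand_grid(species = sp$species, year = years)
  grid <- dplyr::left_join(grid, sp[c("species", "nest_mean", "nest_trend")],
                           by = "species")
  lambda <- grid$nest_mean * exp(grid$nest_trend * (grid$year - mean(years)))
  n_nests <- withr::with_seed(config$seed + 2L,
                              stats::rpois(length(lambda), lambda))
  tibble::tibble(species = grid$species, year = grid$year, n_nests = n_nests)
}

#' Generate a synthetic yearly vegetation-cover series
#'
#' Linear trend in percent cover plus Gaussian noise, clipped to [0, 100].
#'
#' @param config A [simulation_config()].
#' @return A tibble with columns `year`, `percent_cover`.
#' @export
generate_vegetation <- function(config) {
  vg <- config$vegetation
  years <- sim_years(config)
  cover <- withr::with_seed(config$seed + 3L, {
    vg$intercept + vg$slope * (years - config$start_year) +
      stats::rnorm(length(years), sd = vg$sd)
  })
  tibble::tibble(year = years, percent_cover = pmin(100, pmax(0, cover)))
}

#' Generate a synthetic reflectance raster with planted vegetation fraction
#'
#' Builds NIR/RED bands whose NDVI is above 0.3 for an exactly planted
#' fraction of interior (masked) pixels and below 0.1 for the rest, so
#' threshold classification at 0.2 recovers the fraction exactly.
#'
#' @param year Year label.
#' @param true_fraction Planted vegetated fraction of masked pixels, in
#'   [0, 1].
#' @param shape Raster dimensions (rows, cols), default 32 x 32.
#' @param seed Integer seed.
#'
#' @return A list with elements `nir`, `red` (matrices), `mask` (logical
#'   matrix marking interior pixels), `year`, `true_fraction`.
#' @export
generate_raster <- function(year, true_fraction, shape = c(32, 32),
                            seed = 1L) {
  if (true_fraction < 0 || true_fraction > 1) {
    rlang::abort("`true_fraction` must be in [0, 1].",
                 class = "climwindow_invalid_argument")
  }
  nr <- shape[1]; nc <- shape[2]
  mask <- matrix(FALSE, nr, nc)
  mask[2:(nr - 1), 2:(nc - 1)] <- TRUE
  n_in <- sum(mask)
  n_veg <- round(true_fraction * n_in)
  withr::with_seed(seed, {
    veg_idx <- sample(which(mask), n_veg)
    target <- matrix(stats::runif(nr * nc, -0.25, 0.08), nr, nc)
    target[veg_idx] <- stats::runif(n_veg, 0.35, 0.85)
    total <- matrix(stats::runif(nr * nc, 0.4, 0.9), nr, nc)
  })
  nir <- total * (1 + target) / 2
  red <- total - nir
  list(nir = nir, red = red, mask = mask, year = as.integer(year),
       true_fraction = n_veg / n_in)
}

#' Generate the full synthetic study
#'
#' One call producing every input the analysis pipeline consumes: climate,
#' vegetation, monthly counts, nest counts, and a manifest of the true
#' generating parameters (so recovery can be scored without re-deriving
#' them).
#'
#' @param config A [simulation_config()].
#' @return A list with elements `climate`, `vegetation`, `counts`, `nests`,
#'   `manifest`.
#' @export
simulate_study <- function(config = simulation_config()) {
  climate <- generate_climate(config)
  vegetation <- generate_vegetation(config)
  counts <- generate_counts(config, climate, vegetation)
  nests <- generate_nests(config)
  manifest <- list(
    seed = config$seed, n_years = config$n_years,
    start_year = config$start_year,
    species_params = lapply(split(config$species_params,
                                  seq_len(nrow(config$species_params))),
                            as.list),
    effects = config$effects,
    climate = config$climate, vegetation = config$vegetation
  )
  list(climate = climate, vegetation = vegetation, counts = counts,
       nests = nests, manifest = manifest)
}

#' Write a simulation manifest as YAML
#'
#' @param manifest Manifest list from [simulate_study()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}
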