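# climwindow

Climate-window selection and overdispersed count models for waterbird
population dynamics.

## What it does, and for whom

Ecologists monitoring wetland birds often hold monthly counts spanning one
or two decades and ask which part of the year's climate best explains
year-to-year changes in abundance: does a species track a drought index
integrated over the whole preceding year, or maximum temperature in a
two-month late-summer window? `climwindow` answers this with an exhaustive
*time-window scan*: for each climatic variable *x* ∈ {T̄, Tmin, Tmax, P,
SPEI}, all windows of duration 1–12 months at 12 one-month-shifted end
positions (144 candidates, reaching into the previous calendar year) are
aggregated — mean for temperatures and the drought index, sum for
precipitation — and the window maximizing the absolute Spearman correlation
|ρ| with seasonal abundance is selected, per species and season (wintering
= September–February, breeding = March–August). The best variable feeds a
quasi-Poisson GLM of monthly counts

log E[N] = β₀ + β₁·climate(window) + β₂·vegetation,  Var[N] = φ·E[N]

with Pearson-dispersion standard errors, t statistics on residual df, Wald
95% intervals, a Cameron–Trivedi overdispersion test and a VIF collinearity
screen. A vegetation stage derives yearly percent cover from NIR/RED
reflectance (NDVI = (NIR − RED)/(NIR + RED), vegetated if NDVI > 0.2), and
a seeded synthetic-data generator reproduces the whole study design (18
years × 12 months × 4 species, 864 counts, 72 nest records) with known
ground truth so every stage is testable without external data.

## Worked example

Simulate a study in which one species' breeding counts are driven (β =
0.446 on the log scale) by the 12-month SPEI window ending in March, then
run the full pipeline:

```r
library(climwindow)

cfg <- simulation_config(seed = 42, effects = list(list(
  species = "species_B", season = "breeding", beta = 0.446,
  window = list(variable = "spei", duration = 12L, end_month = 3L,
                year_offset = 0L))))
report <- run_full_analysis(config = cfg)
dplyr::filter(report$best_windows, species == "species_B")
#> # A tibble: 2 × 9
#>   species   season    variable duration end_month year_offset   rho   p_value n_years
#> 1 species_B breeding  spei            9        12          -1 0.803 0.0000595      18
#> 2 species_B wintering precip          2         4          -1 0.623 0.00761       17
```

The scan correctly picks SPEI for the breeding season, with a 9-month
window overlapping the injected 12-month one (overlapping windows of the
same variable are strongly correlated, so near-misses of this kind are
expected); |ρ| = 0.80 over the 18 breeding season-years. The wintering row
is a null scan — its |ρ| = 0.62 is the maximum of 720 correlated null
candidates, which is why scan p-values must be read as ranking scores, not
nominal tests. The additive GLM then recovers the effect:

```r
dplyr::filter(report$glm_table, species == "species_B", season == "breeding")
#>   term        estimate conf.low conf.high std.error statistic  p.value
#> 1 (Intercept)  3.57     3.36      3.79      0.109       32.8  4.83e-57
#> 2 climate      0.421    0.291     0.551     0.0653       6.44 3.62e- 9
#> 3 vegetation  -0.00324 -0.00759   0.00110   0.00219     -1.48 1.41e- 1
```

β̂ = 0.42 (95% CI 0.29–0.55) covers the true 0.446; the vegetation term,
truly zero here, is not significant. The simulated vegetation trend is
likewise recovered (`report$vegetation_trend`: slope 2.85 %/yr, t = 26.0,
built around a true slope of 2.7). `write_report(report, "out/")` writes
every table as CSV plus a run log; `plot_window_scan()`,
`plot_seasonal_abundance()` and `autoplot()` on trend fits give the usual
ggplot2 views.

All user-facing functions also work standalone on your own CSV tables
(`read_monthly_counts()`, `read_monthly_climate()`, `read_nest_counts()`;
see `?climwindow_io` for the column contracts).

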