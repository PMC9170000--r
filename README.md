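# subwaypm

Bayesian spline analysis of real-time personal particulate-matter (PM)
exposure time-series from underground transport workplaces.

Occupational-hygiene campaigns in subway systems record, for each monitored
work shift, a real-time concentration series in the worker's personal
breathing zone — an optical particle counter logging PM10 / PM2.5 / PM1 /
PM0.3 mass every 5 minutes and a diffusion-charger counter logging 10–700 nm
number concentration every 6 seconds — together with an activity logbook
giving the worker's station on the line (`Tunnel` when travelling between
two adjacent stations), their environment (sampling room, ticket counter,
platform, train cabin, ...) and any short events (door openings, heater use,
passing trains). `subwaypm` turns those raw ingredients into posterior
exposure estimates with full MCMC validation.

## The model

Log10 concentrations are modelled with a hierarchical Bayesian spline
regression. For record *r* of monitored day *i*:

```
Y_ir ~ N( mu_i + X_station' alpha + X_env' beta + X_event' gamma
          + zeta_i' b(t_ir),  sigma2_i )
```

with day intercepts `mu_i ~ N(m_job, tau2_job)` absorbing a job random
effect, day-specific residual variances, reference-coded categorical
effects (`N(0, 5^2)` priors; the reference station and environment are
fixed at fold change 1), and a day-specific cubic B-spline trend on
within-shift time. All full conditionals are conjugate, so the model is
fitted by a blocked Gibbs sampler — deterministic given a seed, no tuning.
Effects are reported as fold changes `10^coefficient` with 95% credible
intervals; a category is *elevated* when its interval lies above 1.

The package covers the complete pipeline:

* `simulate_study()` — synthetic campaigns with known ground truth
  (24 day-series across 3 occupations, 45 stations / 8 environments /
  10 events by default, paired number-concentration series, gravimetric
  shift values, station metadata);
* `annotate()`, `build_design()` — logbook joining and design
  construction;
* `fit_calibration()`, `select_family()`, `apply_calibration()` —
  gravimetric calibration of PM2.5/PM10 (power / linear / exponential
  families, compared by original-scale R²; PM1 and PM0.3 are refused —
  no measurement standard exists);
* `build_model()`, `fit_spline_model()`, `predict()` — the model above;
* `gelman_rubin()`, `mcmc_acf()`, `prior_sensitivity()`,
  `posterior_predictive_check()`, `diagnose_fit()` — WAMBS-style
  validation;
* `fold_change_summary()`, `flag_elevated()`, `gm_gsd()`,
  `station_correlations()` — reported summaries;
* `integrate_band()`, `align_series()`, `compare_devices()` — optical
  counter vs wide-range counter comparison.

## A worked example

```r
library(subwaypm)
library(dplyr)

cfg <- sim_config(n_stations = 6, n_environments = 4, n_events = 2,
                  days_per_job = 2, seed = 42)
study <- simulate_study(cfg)

ann   <- annotate(filter(study$mass, fraction == "PM10"), study$logbook,
                  event_levels = cfg$event_levels)
des   <- build_design(ann, cfg$reference_station, cfg$reference_environment)
model <- build_model(des, pm_model_spec(iterations = 1000, burnin = 300,
                                        chains = 2))
draws <- fit_spline_model(model, seed = 1)

gelman_rubin(draws) |> summarise(max_rhat = max(rhat, na.rm = TRUE))
#>   max_rhat
#> 1     1.04

fold_change_summary(draws, "environment")
#> # A tibble: 4 × 6
#>   category             fraction fold_change_median ci_low ci_high elevated
#> 1 sampling_room        <NA>                  1      1       1     FALSE
#> 2 cloakroom            <NA>                  0.669  0.479   0.937 FALSE
#> 3 ticket_counter       <NA>                  1.84   1.15    2.95  TRUE
#> 4 underground_corridor <NA>                  1.58   1.19    2.15  TRUE

posterior_predictive_check(model, draws)
#> <pm_ppc> 97.7% of 432 observed records inside the 95% predictive interval
```

Chains converge (max R̂ 1.04 on this short run), and the fold changes
recover the generating truth: the simulation used environment effects of
0.89 (cloakroom), 2.50 (ticket counter) and 2.10 (corridor) relative to
the sampling room, each inside its credible interval. The ticket counter
and corridor are correctly flagged as elevated; the reference row is
exactly (1, 1, 1) by construction. Geometric-mean tables show the expected
order-of-magnitude separation between PM0.3 and PM10:

```r
gm_gsd(filter(study$mass, fraction %in% c("PM0.3", "PM10")), "job")
#> # A tibble: 6 × 5
#>   job                 fraction     n    gm   gsd
#> 1 locomotive_operator PM0.3      144 0.345  1.92
#> 2 locomotive_operator PM10       144 4.06   1.92
#> 3 security_guard      PM0.3      144 0.402  2.19
#> 4 security_guard      PM10       144 4.96   2.19
#> 5 station_agent       PM0.3      144 0.715  2.04
#> 6 station_agent       PM10       144 9.17   1.90
```

The methods vignette (`vignettes/subwaypm-methods.Rmd`) documents the
model, priors, sampler blocks, the synthetic-data generator's defaults and
their rationale, and the validation protocol.

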