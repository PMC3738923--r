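# thermapop

Microclimate-driven population and metapopulation dynamics at a thermal
range margin.

## What this package is for

Thermally limited species at their cool range margin — the motivating system
is the silver-spotted skipper butterfly on British chalk grassland — depend
on hot near-ground microclimates.  Whether a habitat patch supports breeding
in a given summer depends on how many August hours its turf spends above an
activity threshold (25 °C), which in turn depends on slope, aspect,
topographic shading, wind shelter and that year's weather.  `thermapop`
implements the full modelling chain needed to ask whether such *dynamic
thermal habitat quality* drives population growth and range expansion
through a fragmented patch network:

1. **Weather downscaling** — rescale an hourly station series (temperature,
   wind, sunshine fraction) so daily temperature extremes and monthly
   wind/sunshine means match gridded climate targets
   (`downscale_weather()`; sunshine uses capped "water-filling" so hourly
   fractions never exceed 1 while monthly means match exactly).
2. **Topographic microclimate** — hourly 10-cm air temperature per 5-m
   terrain cell, from clear-sky direct/diffuse shortwave adjusted for
   sunshine, slope, aspect and horizon shading, wind attenuated by an
   upwind shelter index, and a two-parameter radiation/wind warming form
   (`run_microclimate()`); August hours > 25 °C are averaged over each
   patch's cells into annual thermal habitat quality and *effective areas*
   `A'_i(t) = area_i · q_i(t)/q̄` (`effective_areas()`).
3. **Population dynamics** — a seven-model ladder of discrete logistic
   models of transect density change,
   `ΔD = (β₀T + β₂)D ± (β₁T + β₃)D²`, with the thermal covariate entering
   growth rate and carrying capacity linearly; AIC comparison
   (`model_ladder()`) and a permutation test of the covariate's explanatory
   power (`randomisation_test()`).
4. **Metapopulation dynamics** — a stochastic incidence function model with
   connectivity `S_i = Σ_j (d_ij + 0.05)^−α A_j^b`, colonisation
   `C = S²/(y + S²)` and extinction `E = (1 − C)·min(1, μA^−x)`, fitted to
   a pair of occupancy snapshots by maximum likelihood (`fit_ifm()`),
   with likelihood-proportional parameter sampling inside the joint 95%
   confidence region (`sample_parameter_sets()`), stochastic ensembles
   (`simulate_ensemble()`), per-patch and 5-km-grouped AIC evaluation
   (`evaluate_occupancy()`), and colonisation/extinction time series
   (`colonisation_extinction_series()`).

Synthetic generators (`generate_terrain()`, `generate_weather()`,
`generate_patch_network()`, `generate_density_series()`,
`generate_occupancy_history()`) provide inputs with known ground truth, so
every stage is testable without field data.  `run_pipeline()` orchestrates
all stages from one declarative configuration with per-stage seeds and a
checksummed manifest.

## A worked example

Fit the incidence function model to a synthetic snapshot pair and check the
fitted parameters against the generating truth:

```r
library(thermapop)

nw    <- generate_patch_network(synth_network_config(
           n_patches = 300, extent_km = 60, clustering = 1, seed = 5))
truth <- ifm_params(alpha = 1.5, y = 20, mu = 1, x = 0.5, b = 0.5)
start <- as.integer(seq_len(300) %% 2 == 0)

s0 <- generate_occupancy_history(nw, truth, nw$area_ha, start, 30,
                                 seed = 6)[[31]]
s1 <- generate_occupancy_history(nw, truth, nw$area_ha, s0, 9,
                                 seed = 101)[[10]]

fit <- fit_ifm(s0, s1, nw$area_ha, nw$dist_km, n_steps = 9, seed = 1)
fit
#> ifm_fit: logLik -158.89; alpha=1.3 y=37.6 mu=1.14 x=0.556 b=0.38
```

The dispersal exponent and the extinction parameters land near the truth
while the colonisation half-saturation trades off against them (the likelihood
surface is genuinely wide — which is why downstream simulation samples
whole parameter *sets* in proportion to likelihood rather than using the
MLE alone):

```r
sets <- sample_parameter_sets(fit, 100, seed = 2)
ens  <- simulate_ensemble(s0, nw$area_ha, sets, n_runs = 500, n_years = 9,
                          nw$dist_km, seed = 3)
ev   <- evaluate_occupancy(ens, s1, group_size_km = 5,
                           coords_km = nw$centroid_km)
round(c(AIC = ev$AIC, grouped_AIC = ev$group_AIC), 1)
#>         AIC grouped_AIC
#>       328.3       328.8
```

Lower AIC means the ensemble reproduces the observed 0/1 occupancy pattern
more reliably; comparing these numbers between a microclimate-weighted run
and a plain habitat-area run measures what the dynamic thermal surface adds.

## Package layout

- `R/terrain.R`, `R/weather.R`, `R/network.R` — synthetic-data generators
- `R/downscale.R` — station-to-grid rescaling
- `R/solar.R`, `R/microclimate.R` — solar geometry, irradiance, shelter,
  threshold-hours, thermal quality, effective areas
- `R/popdyn.R` — logistic model ladder and randomisation test
- `R/ifm.R`, `R/ifm-fit.R` — incidence function model, exact oracle,
  fitting, sampling, ensembles, evaluation
- `R/io.R` — CSV / ESRI ASCII grid / GeoJSON interchange
- `R/pipeline.R` — end-to-end orchestration
- `vignettes/microclimate-metapopulation.Rmd` — model assumptions, design
  decisions and limitations
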