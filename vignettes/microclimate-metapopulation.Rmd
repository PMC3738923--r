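---
title: "Modelling range expansion with dynamic microclimates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling range expansion with dynamic microclimates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermapop)
```

## The scientific problem

Ectotherms at their cool range margin often depend on hot microclimates:
short-turf grassland on a south-facing slope can run 5–15 °C warmer near the
ground than the ambient air, and whether a habitat patch supports breeding in
a given summer depends on how many hours its surface spends above an
activity threshold (25 °C for the silver-spotted skipper system this package
is built around).  Because topography varies at metres and weather varies
between years, the *effective* amount of habitat in a fragmented landscape
fluctuates in space and time.  `thermapop` implements the full chain from
hourly station weather to range-expansion predictions:

1. **Downscaling** — rescale an hourly station series so daily temperature
   extremes and monthly wind/sunshine means match gridded climate targets.
2. **Microclimate** — hourly 10-cm air temperature per 5-m terrain cell from
   slope, aspect, horizon shading and wind shelter; August hours > 25 °C
   summarised to per-patch annual *thermal habitat quality* `q`.
3. **Population dynamics** — a ladder of discrete logistic models of annual
   transect density change, with growth rate and carrying capacity linear in
   a thermal covariate, compared by AIC and probed with a randomisation
   test.
4. **Metapopulation dynamics** — a stochastic incidence function model (IFM)
   whose per-patch areas are weighted by normalised thermal quality, fitted
   to a pair of occupancy snapshots, and simulated as ensembles.

Synthetic-data generators with known ground truth stand in for field data;
every stage is therefore testable end to end.

## Microclimate model

The near-surface temperature model is deliberately compact.  For each cell
and hour:

* **Solar geometry.**  A standard low-precision ephemeris (declination +
  equation of time + hour angle) gives altitude and azimuth to ~0.5°,
  ample at hourly, 5-m resolution.
* **Clear-sky shortwave.**  Direct-normal irradiance is
  `S0 * tau^(1/sin alt)` with solar constant `S0 = 1361` W m⁻² and
  broadband transmittance `tau = 0.75`; diffuse is a fixed fraction
  (`0.2`) of clear-sky global, times a sky-view factor computed from the
  horizon-angle profile.  Both are configuration-exposed in
  `microclim_coeffs()`.
* **Terrain adjustment.**  The direct beam is multiplied by the hourly
  sunshine fraction and the cosine of the incidence angle on the tilted
  surface, and zeroed when the sun sits below the cell's horizon angle in
  the solar azimuth sector (16 sectors by default).
* **Wind shelter.**  A shelter index `s = tan(horizon angle upwind)`
  attenuates ambient wind as `u / (1 + c s)`; a 90° horizon is treated as
  full shelter with a small floor wind speed (0.1 m s⁻¹).
* **Warming.**  The 10-cm excess over ambient is `k1 Q / (1 + k2 u)` with
  `Q` net shortwave, `k1 = 0.015` °C/(W m⁻²) and `k2 = 0.5` s m⁻¹.

The two-parameter warming form is this package's own parameterisation of a
radiation/wind energy balance: the interior constants of calibrated
chalk-grassland energy-balance models are not published in a reusable form,
so we chose the simplest form with the right monotonicities — increasing in
radiation, decreasing in wind, equal to ambient at zero radiation — with
defaults set so that sunlit, sheltered slopes exceed ambient by roughly
5–15 °C, the observed magnitude in short turf.  All coefficients can be
re-calibrated against loggers via `microclim_coeffs()`.

Longwave radiation, soil heat flux and night-time temperature inversions are
out of scope: they matter mainly at night and in winter, while the quantity
of interest is daytime August heat.  The threshold count uses a strict
inequality (`> 25` °C), applied uniformly.

Per-patch quality is the **mean** over member cells of August threshold
hours.  A sum over cells would re-count patch area, which already enters the
metapopulation model separately; the mean keeps quality an intensive
quantity.  (`patch_thermal_quality()`; switchable by summing yourself from
the per-cell raster.)

Hourly wind *direction* is not part of the weather inputs; the driver uses a
fixed prevailing direction (default 225°, south-westerly, typical of
southern Britain).  Shelter therefore varies between cells but not between
hours.

## Downscaling

Daily temperature uses the affine map sending the day's observed extremes
exactly onto the target `tmax`/`tmin` (rank-preserving; exact by
construction).  Days run midnight-to-midnight in the series clock.  A
constant input day with `tmax > tmin` admits no affine map; callers choose
between an error and midpoint filling.

Monthly wind is scaled multiplicatively.  Monthly sunshine fraction cannot
be, because hourly sunshine is capped at 1: plain scaling either breaks the
cap or misses the mean.  We use iterative proportional scaling with capping
("water-filling"): scale the uncapped hours, clamp any that exceed 1,
redistribute the remaining deficit, and repeat; the mean is matched to
1e-9 when feasible.  Hours at zero (night) stay zero, so the achievable
maximum is the nonzero-hour fraction and an unreachable target raises an
error naming it.

## Population dynamics ladder

Annual density change is `ΔD = r D (1 − D/K)` with `r = β0 T + β2` and the
quadratic coefficient linear in `T` as well; fitting is linear regression of
`ΔD` on `{D, D², T·D, T·D²}` with no intercept.  Seven structures are
compared (`model_ladder()`): pooled with no covariate (i), per-transect
random curvature (ii), regional August temperature (iii), regional plus
random intercept-level (iv) or slope-and-intercept (v) transect deviations,
patch thermal quality (vi), and lagged quality (vii).

Design choices worth noting:

* **Sign of the D² term.**  The source literature for this model family
  describes the quadratic coefficient as the linear form of `−r/K` while
  reporting all-positive coefficients, which under that reading admits no
  positive carrying capacity.  Rather than silently "fixing" this, both
  conventions are implemented (`sign_convention = "paper"` keeps the fitted
  coefficient as-is; `"logistic"` negates it so `K = r/(β1 T + β3) > 0`).
  The regression itself is identical either way; only reporting and
  simulation differ.  The synthetic generator uses `"logistic"`.
* **Mixed models** are fitted by maximum likelihood (`lme4::lmer`,
  `REML = FALSE`) so AIC is comparable across fixed-effect structures; the
  AIC parameter count is fixed effects + variance components + residual
  variance (the `logLik` df).  Conventions that count per-transect effect
  levels as parameters give much larger counts for models ii/iv/v; we use
  the likelihood df.
* **R²** is the squared Pearson correlation of fitted vs observed `ΔD`
  (switchable to `1 − SSE/SST`).
* **Pairs** are consecutive years only; gaps break pairs rather than being
  interpolated.
* The synthetic density generator adds Gaussian noise to `ΔD`, truncated so
  density stays non-negative, and treats `D = 0` as absorbing (an extinct
  transect population does not spontaneously regenerate from noise).

The randomisation test permutes the thermal covariate jointly across all
transect-year cells, refits, and compares the observed R² with the null
distribution; `p = (1 + #{null ≥ observed}) / (n_reps + 1)`.

## Incidence function model

Connectivity `S_i = Σ_{j≠i occupied} (d_ij + 0.05)^−α A_j^b` (km; the offset
is 50 m), colonisation `C = S²/(y + S²)`, extinction
`E = (1 − C) · min(1, μ A^−x)` — the `(1 − C)` factor is the rescue effect
and the raw term is capped at 1 (standard IFM practice; the bare formula
exceeds 1 for small patches).  The kernel is a power law, which fits
mark-recapture dispersal for this species better than a negative
exponential.  Updates are synchronous: `C` and `E` are computed on the
pre-step state.  In microclimate mode the areas are *effective areas*
`A'_i(t) = area_i × q_i(t)/q̄`, with `q̄` the mean quality over all patches
and all calibration years (so the calibration-window mean weight is exactly
1); habitat-area mode uses plain areas and is algebraically the constant-`q`
special case.

**Fitting** maximises the Bernoulli likelihood of the second snapshot given
the first over `(α, y, μ, x, b)` (L-BFGS-B on log parameters, multiple
starts).  The interval is propagated as nine annual transitions for a
9-year survey gap (the model's natural timestep), with the count
configurable.  The per-patch end-interval probabilities come from a
deterministic **mean-field** propagation — per-patch occupancy
probabilities with connectivity built from expected source contributions —
which is smooth in the parameters and fast, at the price of ignoring
correlations between patches.  The package carries an exact joint-chain
oracle (`exact_marginals()`, feasible to ~12 patches) against which both
the simulator and the mean-field surrogate are tested; mean-field error is
small under weak-to-moderate coupling but the composite (independence)
likelihood is genuinely approximate for strongly clustered networks, and
the joint 95% confidence region
`{θ : 2[lnL(θ̂) − lnL(θ)] ≤ χ²₀.₉₅,₅ = 11.07}` inherits that
approximation.

**Parameter-set sampling** draws sets in proportion to their likelihood
within the joint region, by rejection: uniform proposals (in log space) in
a box bracketing the region (per-axis profile bounds, expanded 1.5×),
accepted with probability `L(θ)/L(θ̂)` and only if inside the region.
**Ensembles** then draw one set per run (cycling), and evaluation scores
each observation by the proportion of runs reproducing it, with a
`(matches + 0.5)/(n_runs + 1)` pseudocount so never-matched observations
get a finite penalty; AIC uses `k = 5`.  Grouped evaluation forms squares
of a given side (anchored at the coordinate origin) and scores the joint
event that every patch in the square is predicted correctly — a
conservative guard against spatial autocorrelation.  Unsurveyed patches are
excluded from likelihood sums but still simulated.

## Synthetic data: what it emulates, and what it does not

* **Terrain** is a sinusoidal ridge–valley surface plus seeded smooth
  random-phase waves — chosen over fractal noise because slopes, aspects
  and horizons are analytically checkable.  Real escarpments have sharper
  breaks of slope and more aspect asymmetry than sinusoids.
* **Weather** is seasonal + diurnal sinusoids + AR(1) synoptic noise with
  per-year offsets for runs of hot and cool summers, wind as truncated
  AR(1), and beta-distributed hourly sunshine zeroed at night.  It has no
  weather fronts, no diurnal asymmetry, and no temperature–sunshine
  coupling; passing tests show the machinery is correct, not that the
  generator is a climate model.
* **Patch networks** draw areas from a log-normal truncated to
  [39 m², 71 ha] with the truncated mean solved to 3.61 ha — the size
  structure of the chalk-grassland network the models target — and place
  centroids uniformly or in Thomas-process-like clusters.  The clustering
  strength is a free knob; no observed landscape statistics constrain it.
* **Density series and occupancy histories** iterate the fitted models
  themselves, so recovery tests are exact-oracle tests.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale problem sizes
chosen as the package's own study design: oracle comparisons on 3–10-patch
networks with 10,000-run ensembles; parameter recovery on a 300-patch
clustered network over a 9-year snapshot gap with 20 replicate fits; the
model ladder at 10 transects × 20 years × 200 replicates; randomisation
calibration at 1,000 trials × 500 permutations; microclimate invariants on
a 200 × 200 grid-month.  Horizon searches stop at 500 m by default (at 5-m
resolution, relief beyond that subtends < ~6° for typical chalk downland
relief).  Optimiser bounds, the χ² cut-off, pseudocounts and tie-break
conventions are given above; random number use is always seeded through
function arguments, and identical seeds give bit-identical outputs.

## Known limitations

* The mean-field fitting likelihood is a composite likelihood; its joint
  confidence region is approximate under strong spatial clustering (see
  above), and the package documents rather than corrects this.
* The microclimate warming form is monotone-correct but not a calibrated
  energy balance; `k1`, `k2`, transmittance and diffuse fraction should be
  re-fitted against loggers before quantitative use on real terrain.
* Sunshine is treated as an hourly fraction; sub-hourly cloud structure is
  invisible.
* The IFM tracks occupancy only — no within-patch abundance, and no
  environmental correlation between patches beyond what the shared
  effective-area series induces.
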