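---
title: "Methods: soil microclimate reconstruction in glacier forelands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil microclimate reconstruction in glacier forelands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forelandclim)
```

## The problem

Near-subsurface soil temperature is the climate that soil fauna, microbial
communities and establishing plants actually experience in recently
deglaciated terrain. It is decoupled from the regional ("macro") climate by
elevation, topographic radiation loading, snowpack insulation, katabatic
drainage off the ice, burial depth and canopy shading. `forelandclim`
reconstructs monthly soil temperature during the snow-free season from
these drivers, validates the reconstruction's spatial transferability, and
quantifies both the temporal change between two periods and the capacity of
fine-scale spatial heterogeneity to buffer it.

## The model

Monthly mean soil temperature is modelled as a linear mixed model:

$$\mathrm{soilT} \sim mT + rad + sfd + dg + tc + pf + d
  + sfd{:}mT + sfd{:}rad + sfd{:}dg + sfd{:}d + tc{:}rad + (1\,|\,gl)$$

* `mT` — macroclimate at the station, downscaled by a fixed environmental
  lapse rate (default −0.0065 °C/m; −0.005 and −0.008 are provided as
  sensitivity alternates, and on synthetic alpine terrain the surfaces they
  produce correlate above r = 0.98, so the choice is not critical).
* `rad` — monthly-averaged daily cumulative absorbed shortwave radiation
  (MJ m⁻² d⁻¹), from the hourly topographic chain described below.
* `sfd` — monthly frequency of snow-free days (%); it interacts with
  `mT`, `rad`, `dg` and `d` because snow gates every surface coupling.
* `dg` — distance to the glacier forefront (m), square-root transformed to
  linearize the decaying katabatic cooling.
* `tc`, `pf` — binary tree-cover (> 0 % canopy) and permafrost
  (probability ≥ 0.9) occurrence.
* `d` — burial depth, 5/10/15 cm, treated as a continuous standardized
  predictor. The alternative categorical treatment is supported
  (`depth_continuous = FALSE` in `build_design()`); continuous is the
  default because the depth–sfd interaction is most parsimonious on a
  single slope and validation depths are snapped to the nearest class
  anyway.
* `(1 | gl)` — a per-glacier random intercept absorbing unmeasured
  geography.

Continuous predictors are standardized to zero mean and unit variance on
the *training* table after transformation; the standardization is frozen
and reapplied unchanged to validation and projection inputs. Anything else
would make averaged leave-one-out coefficients meaningless across folds.
Estimation is by REML (lme4). Fit quality is summarized by the
variance-partitioning R²: with $\sigma^2_f$ the variance of the fixed
linear predictor, $R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_{gl} +
\sigma^2_e)$ and $R^2_c$ adds $\sigma^2_{gl}$ to the numerator.

### Snow decoupling cutoff

Under snow, soil temperature hovers near 0 °C regardless of atmosphere and
sun, so snow-rich months would distort the regression.
`sfd_cutoff_diagnostics()` refits the model at increasing sfd cutoffs and
tracks residual-vs-fitted structure (a decile-bin curvature index and a
heteroscedasticity index). On worlds with built-in decoupling the
distortion shrinks from cutoff 0 % to 20 % and is flat beyond, which is why
the pipeline discards months with `sfd ≤ 20 %` (strict inequality:
20.0 % is excluded).

### Variance attribution

Two complementary views are implemented by hand (they are part of the
method, not off-the-shelf steps):

* **Semi-partial R²** — each fixed term's contribution is removed from the
  full fit's linear predictor (coefficients not re-estimated) and the drop
  in explained variance is taken relative to the full model's total
  variance. For orthogonal designs the semi-partials sum exactly to R²m;
  intervals come from a glacier-block bootstrap (glaciers resampled with
  replacement, model refit), because glaciers — not rows — are the
  exchangeable unit under the random-effect structure. The default is 1000
  replicates; the tests and the acceptance script use far fewer, which is a
  problem-size choice of this package, not a statistical necessity.
* **Permutation importance** — each raw predictor is permuted (default
  1000 times) with the design matrix rebuilt from the permuted column, so a
  predictor's additive and interactive contributions are broken jointly;
  importance is the mean of 1 − r between original and permuted
  predictions. A predictor whose additive and interactive coefficients are
  all zero scores exactly 0.

### Transferability and validation

`loo_by_glacier()` refits the model once per held-out glacier and stores
each fold's fixed coefficients; their unweighted arithmetic mean (on the
standardized scale) is the transferable coefficient set, applied to new
data with the random effect omitted. Agreement is measured with
**weighted** statistics: observations are hierarchically downweighted so
that each region sums to 1, each glacier within a region to 1/G, and each
non-empty sfd decile class within a glacier to 1/(G·M). The wording of the
third level is ambiguous in isolation ("observations within each glacier ×
region sum up to 1/M"); the package uses the only reading consistent with
region totals of 1, namely an equal 1/(G·M) share per non-empty class, with
empty classes receiving no mass. wR² is the coefficient of determination
of the weighted regression of observed on predicted (slope and intercept
free), wMAE and wRMSE the weighted error moments. For external-style data
without a glacier level, stations are grouped by single-linkage clustering
at 1000 m (`cluster_stations()`).

## The radiation chain

For the 15th day of each month, 24 hourly estimates are computed and
summed (`daily_cumulative()`; exactly 24 values are required):

1. `solar_position()` — a low-precision NOAA/Meeus ephemeris (declination,
   equation of time, hour angle), accurate to ~0.01° against an
   independent Astronomical Almanac implementation. Hours are the 24 local
   solar hours of the 15th day, converted to UTC through the 15°/h
   longitude offset.
2. `clearness_index()` — Kt = downward / extraterrestrial, clipped to
   [0, 1]. At night (sun below the horizon) Kt is defined as 0 and Kd as 1,
   which avoids 0/0.
3. `diffuse_fraction()` — the piecewise clearness-index separation of
   Orgill–Hollands form: `1 − 0.249 Kt` below 0.35, `1.557 − 1.84 Kt` to
   0.75, then the clear-sky floor 0.177. It has the overcast limit
   Kd(0) = 1, is monotone non-increasing within each piece, and is clipped
   to [0, 1].
4. `partition_net()` — diffuse = net · Kd, direct = net · (1 − Kd); the sum
   is conserved exactly. Net radiation is used as delivered ("albedo-free");
   the target surface's own albedo is *not* applied again — the forecast
   albedo enters only as the adjacent-terrain reflectance below.
5. `horizon_svf()` — per-sector horizon angles by ray-marching (default 24
   sectors, step = one cell, search radius 5 km — an accuracy/cost balance
   at 30–90 m cells), and the sky view factor
   `svf = cos²(slope/2) · mean(cos²(horizon))`.
6. `absorbed_hourly()` — the direct beam through the incidence angle on
   the tilted surface divided by `max(ε, sin(altitude))` with ε = 10⁻³
   capping low-sun amplification; diffuse split into an isotropic part
   (svf-weighted), a circumsolar part weighted by a Hay-type anisotropy
   index `direct/extraterrestrial` and routed like the beam, and a
   terrain-reflected part `albedo · (1 − svf) · global`. Cells behind the
   local horizon, or with the sun down, receive no beam. Negative results
   are clamped to zero with a warning.

## Snow detection and calibration

A logger under snow shows a strongly damped diurnal cycle. `daily_range()`
computes per-day max − min (at least 4 records per day, guarding against
spuriously small ranges at the devices' 6–480 records/day); a day is
snow-free when its range reaches the threshold. The satellite route
converts daily fractional snow cover to occurrence at the conservative
40 % threshold (snow iff cover ≥ 40 %). `calibrate_snow()` sweeps
thresholds {0.5…3 °C} × minimum-image filters {1…20}, scores each
combination with the weighted agreement statistics, and selects the
maximum wR² (ties broken by smaller wRMSE — the selection rule itself is a
package choice, since "most robust" admits several formalizations). The
sfd denominator is the month's *observed* valid days by default; calendar
days are available behind a switch (`denominator = "calendar"`), as either
reading is defensible.

## Projection, change and buffering

`project_soil_temperature()` applies a coefficient vector to raw
covariates at 5 cm depth, masking snow-decoupled cells (`sfd ≤ 20 %`) and
cells with fewer than 15 supporting images. `stratified_sample()` draws
two points per distance class (0–100, 400–600, 900–1100, 1900–2100,
2900–3100 m) per 50 km equal-area cell, dropping cells that cannot supply
all ten points. `delta_t()` differences the two periods' month means with
pairwise masking (a month masked in either period is dropped from both);
multiple years within a period collapse to per-month period means first,
and seasonal subsets use the standard climatological quarters with
unweighted month means. `t_var()` is the q90 − q10 range within a 250 m
buffer by cell-center inclusion (at least 5 cells), and
`t_bp = t_var / ΔT` keeps the sign of the change; `|ΔT| < 10⁻⁶ °C` maps to
a signed-infinity sentinel in the top class, since spatial variability
trivially exceeds no change. Type-7 (linear-interpolation) quantiles are
used everywhere — extremes, buffers, summaries — so all quantile-based
results share one rule. `extrapolation_audit()` reports the percentage of
projection values strictly outside each predictor's training range.

## The synthetic world

`simulate_world()` builds the study conditions end to end: 20 glacier
forelands (6 stations × 24 months by default) spread from 55° S to 70° N —
guaranteeing polar, mid-latitude and equatorial weighting regions —
with station elevations, distances (20–3000 m), depths cycling 5/10/15 cm,
and binary covariates; monthly macroclimate with latitude-dependent
seasonality, lapse-rate elevation dependence and a warming trend
(default 0.5 °C/decade); insolation from solar geometry plus noise; daily
snow calendars (snow when the station's monthly macroclimate plus 2 °C
per-day jitter is below freezing, which creates the sfd–elevation–season
covariance the model exploits); and soil temperatures generated from the
exact standardized design the model fits, with glacier intercepts
(sd 1.5 °C) and monthly residuals (sd 1.5 °C) — magnitudes chosen to give
realistic fit quality (weighted RMSE near 2 °C). Months at or below 20 %
snow-free days are generated snow-decoupled near 0 °C. The generating
coefficients (`default_true_coefficients()`) carry the field-expected
signs: soil warms with macroclimate, radiation, snow-free days and
distance from the ice; cools with depth and canopy; permafrost has a small
negative effect; couplings steepen as the snow-free season lengthens and
deep soil lags it.

Hourly logger traces are the station-month mean plus a diurnal sinusoid
(amplitude 5 °C snow-free, 0.2 °C under snow — the gap that makes snow
detectable) plus AR(1) noise (lag-1 correlation 0.6) whose scale is
proportional to the residual sd, so zero-noise worlds are exactly
deterministic. Satellite snow cover is ≥ 40 % on calendar snow days,
< 40 % otherwise, with i.i.d. cloud gaps. Every draw flows from named
substreams of one master seed: identical configs reproduce the world bit
for bit.

What the generator does *not* emulate: soil moisture and thermal inertia,
longwave radiation, vegetation height, real glacier dynamics, spatially
correlated cloud fields, and measurement error in the covariates. Passing
tests on this world therefore demonstrate the correctness and internal
consistency of the pipeline — filters, transforms, estimation, weighting,
projection algebra — not the realism of any coefficient for a particular
mountain range.

## Numerical choices and degenerate inputs

* Rasters are north-up, cell-center registered, row 1 at the northern
  edge; plain-text ASCII-grid and GeoJSON I/O keep every artifact
  inspectable.
* Flat DEM cells take slope 0 and sentinel aspect 180 (any aspect is
  equivalent at zero slope). DEM borders use one-sided differences via
  linear edge extrapolation, so planar ramps are exact everywhere.
* The coarse reference elevation for lapse-rate downscaling is the mean
  fine elevation per coarse cell (`aggregate_elevation()`), the only
  choice that makes downscaling mean-preserving; coarse products rarely
  state their reference surface.
* Distance to the glacier is the 8-connected chamfer path distance
  (cardinal step = cell, diagonal = √2·cell), matching grid-distance
  semantics rather than Euclidean distance; it equals Dijkstra on the
  lattice.
* A singular mixed-model fit (glacier variance collapsing to zero) is an
  error by default with advice attached; `singular = "allow"` accepts it,
  which is correct for worlds generated without between-glacier variance.
* Monthly aggregation requires a declared nominal recording frequency and
  drops months below 90 % completeness (the 89.9 % month is out); monthly
  extremes are the 5 %/95 % type-7 quantiles over at least 20 records.
* Monthly means are computed from raw records directly (not via daily
  means); both conventions appear in field practice and the difference
  vanishes for regular sampling.

## Problem sizes

Defaults in tests and the acceptance script are sized for a single CPU:
20 recovery worlds of 20 × 6 × 24 station-months, a 10-glacier projection
world, a 3-glacier noise-free snow world, 100 ephemeris comparison points,
and reduced bootstrap/permutation counts. All are package choices that can
be scaled up through the corresponding arguments.

## Known limitations

* The projection surface operates on covariate tables; planetary-scale
  raster stacks are out of scope, as are satellite retrievals — inputs are
  expected as local files or in-memory tables.
* The diffuse-fraction separation uses a single clearness-index predictor;
  separation models with additional predictors (solar elevation,
  persistence) exist and could sharpen hourly partitions in high-albedo
  terrain.
* The weighting scheme assumes every observation carries region, group and
  sfd labels; there is no partial-label fallback.
* Depth enters linearly by default; with only three depths the data cannot
  distinguish linear from categorical treatment, and both are offered.
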