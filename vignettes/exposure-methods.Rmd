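---
title: "Time-weighted-average personal PM2.5 exposure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-weighted-average personal PM2.5 exposure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmexposure)
```

## The problem

Epidemiological exposure assessment has traditionally assigned each person
the PM2.5 concentration of the nearest fixed outdoor monitor. People,
however, spend most of the day indoors and move through microenvironments
whose concentrations differ from ambient air, so fixed-site assignments
misclassify exposure. `pmexposure` implements and compares three
time-weighted-average (TWA) reconstructions of daily personal PM2.5
exposure against personal-monitor ground truth:

* **S1 — fixed-site**: measured home indoor concentration and the kriged
  outdoor concentration of the home's grid cell, combined with fixed
  population-average occupancy times (15.86 h at home, 3.34 h outdoors,
  national exposure-factor handbook values).
* **S2 — location-aware, single indoor measurement**: the same measured
  home concentration, but diary-based personal occupancy times and
  GPS-matched outdoor concentrations along the individual's trajectory.
* **S3 — microenvironment models**: GPS-matched outdoor concentrations
  plus hourly model predictions of indoor PM2.5 for each of five indoor
  microenvironments (house, office, educational facility, transportation,
  other indoor), weighted by diary hours.

All three are instances of the TWA identity
$C_{TWA} = \sum_i C_i T_i \,/\, \sum_i T_i$, applied once per
participant-day over 30-minute diary slots.

## Pipeline components

### Ordinary kriging of the sensor network

Sensor readings are averaged to hourly station means (the indoor models run
hourly; minute-level kriging would add cost without information the rest of
the pipeline can use). Each hour, a spherical semivariogram
$\gamma(h) = n + p\,(1.5h/r - 0.5(h/r)^3)$ is fitted to the Matheron
empirical variogram by weighted least squares: the model is linear in
nugget $n$ and partial sill $p$ given the range $r$, so the fit profiles a
log-spaced range grid and polishes the best range with a one-dimensional
optimizer, clamping $n, p \ge 0$. Ordinary kriging then predicts every
500 m cell center with weights constrained to sum to one (Lagrange
multiplier). Implementation conventions:

* $\gamma(0) = 0$ even with a positive nugget, so the predictor is an exact
  interpolator at station locations;
* duplicate station coordinates are averaged (the system is singular
  otherwise) with a logged count;
* negative predictions are clipped to zero and counted — concentrations are
  physical quantities;
* with more than `max_neighbors` (default 64) stations, each prediction
  uses its nearest stations; with fewer, one factorization per hour serves
  all cells;
* a snapshot with fewer than 10 finite stations refuses to fit and asks the
  caller for a wider time window;
* an all-constant snapshot yields a zero-sill model, and kriging then falls
  back to the plain mean, which reproduces the constant everywhere.

Grid cells are half-open squares, lower-left inclusive: a point exactly on
`x0 + cell_size` belongs to column 2. GPS fixes are matched per minute to
the temporally nearest hourly field (ties to the earlier hour), and the
home-cell series uses the identical per-minute convention so that a
permanently-home track and the home-cell extraction agree exactly.

### Trajectory and diary fusion

The diary is the authoritative occupancy record: a GPS fix inside the home
cell during a slot labeled "office" counts as office time. Participant-days
are completed to 48 slots; missing slots become explicit gaps. Days with
more than `gap_limit_h` (default 4 h) of gaps are excluded from TWA
computation; smaller gaps inherit the previous slot's label. The 4 h limit
is this package's rule — the source methodology excluded participants with
missing time-activity data but stated no day-level rule.

### Hourly indoor microenvironment models

Each indoor label gets a tree-ensemble regressor of hourly indoor PM2.5 on
six inputs: outdoor PM2.5, the outdoor PM2.5/PM10 ratio, temperature, wind
speed, relative humidity, and precipitation. The house model is an
extremely randomized forest (`ranger`, `splitrule = "extratrees"`, 300
trees); other labels use gradient boosting (`xgboost`, 200 rounds,
`eta = 0.1`, depth 6). These fixed backends replace an upstream AutoML
model search: the pipeline contract only needs an hourly predictor with
the six stated inputs, and fixed seeds make results reproducible. A seeded
20% holdout records honest R², RMSE and MAE. Predictions are clipped at
zero and apply to both 30-minute slots of their hour. Labels with fewer
than 100 training rows can share one pooled non-house model
(`pool_sparse_labels`).

### Scenario details

* S2 is computed exactly as a two-term formula: hours in non-house indoor
  microenvironments are dropped from numerator and denominator. A config
  variant (`s2_fold_other_into_house`) folds them into the house term for
  sensitivity analysis.
* S2/S3 denominators are the day's accounted (diary-labeled) hours, which
  may be under 24; no renormalization to 24 h is applied.
* Whether "transportation" is an indoor microenvironment or outdoor
  exposure is genuinely ambiguous — it is listed among the indoor labels
  but is a moving space. The default uses the transportation indoor model;
  `transport_outdoor = TRUE` routes it to the GPS-matched outdoor
  concentration.
* S1 uses per-day home means (each day's S1 varies with that day's
  measured home concentration), matching the daily-average reading of the
  scenario definition.
* The measured truth is the equal-cadence daily mean of the personal
  monitor, kept only when at least `min_personal_coverage_h` (default
  18 h) of valid samples exist.

### Contribution rates and CTE/RME

The printed contribution formula divides by $C_{TWA} \times 24$; whenever a
day's accounted time is under 24 h those shares cannot sum to 100%. The
package therefore computes both conventions — `literal24` as printed and
`normalized` (divide by the accounted hours), whose indoor and outdoor
shares sum to exactly 100 — and reports `normalized` as the headline
number, since published contribution rates behave as shares of total
exposure. CTE and RME profiles are the contribution splits of the days at
the 50th and 95th percentile (nearest-rank, ties to the earliest date) of
the pooled participant-day TWA distribution, pooled across participants
because the reference summaries are single percentages, not per-person
ones.

## The synthetic study generator

The panel data motivating this pipeline are not public, so the package
ships a generator whose defaults encode the qualitative structure such
urban panel data show:

* **Outdoor field**: mean 15 µg/m³; a stationary Gaussian random field
  with spherical covariance (range 3000 m, sill 9, nugget 0.5) realized on
  a 500 m knot lattice and bilinearly interpolated; a ±4 µg/m³ diurnal
  sinusoid; an iid N(0, 4²) between-day regional shift; and a +7 µg/m³
  **commute corridor** band through the domain center. Homes sit off the
  corridor, workplaces inside it, so GPS-matched outdoor exposure exceeds
  home-cell outdoor exposure — the location-based-vs-fixed-grid contrast.
* **Diaries**: weekday/weekend templates giving ≈12.6 h/day at home and
  ≈1.4 h/day outdoors — close to reported activity budgets (≈11.9 h home,
  ≈1.5 h outdoor) — with roughly 19 h/day indoors overall.
* **Home monitors**: infiltration baseline (slope 0.65, intercept
  8 µg/m³ for houses) plus short indoor **peak events** — 2.5 events/day
  Poisson, exponentially distributed initial magnitudes (mean 140 µg/m³)
  decaying at 1.5 h⁻¹, placed at minutes when someone is home. These stand
  in for cooking/smoking-type episodes.
* **Personal truth** is the occupied microenvironment's concentration at
  every time point (no personal-cloud term). For the house, the
  microenvironment (room-average/breathing-zone) concentration carries
  only `room_fraction` (default 0.05) of the monitor-local peak signal:
  stationary monitors sit near sources and mix poorly, so they read
  systematically above personal exposure at home, as panel comparisons of
  home monitors and personal monitors show. This number is a design
  choice, not an estimate from any home; it is the lever that makes the
  observed pattern — scenarios built on the home monitor overestimate
  while correlating weakly — reproducible at desk scale. With larger
  fractions the day-to-day peak mass couples truth to S1/S2 so strongly
  that the characteristic S3 correlation advantage disappears.
* **Indoor model training data** are source-free hourly reference series
  (infiltration relation plus noise) per label. Training on such series —
  rather than on the peak-contaminated monitors themselves — mirrors how
  hourly indoor models adopted from aggregate frameworks capture
  infiltration-driven variation but miss minute-scale episodes; an hourly
  conditional-mean regressor trained on the contaminated series itself
  would simply reproduce the average peak mass and the designed
  under-prediction would vanish.

What the generator does **not** emulate: real meteorology (its met series
is decorative noise with plausible ranges), mass-balance indoor dynamics
(a static infiltration line suffices for the biases of interest),
anisotropic or space-time pollution structure, GPS measurement error
beyond small jitter, and diary misreporting. Passing tests therefore
demonstrate that the estimators recover a *designed* structure, not that
they would perform identically on field data.

Presets: `small` (5 participants × 7 days, 50 sensors) is the test and
acceptance default; `study` (93 × 60, 200 sensors) mirrors the motivating
study's scale; `tiny` (2 × 2, 30 sensors) is for smoke tests. The
simulation replicate counts used in the test suite (20 seeds of the small
preset) were chosen so the full suite runs comfortably on a laptop-class
single core.

## Numerical conventions and degenerate inputs

* Timestamps are timezone-naive local time (stored as UTC internally); a
  participant-day is [00:00, 24:00) local midnight-to-midnight, a
  convention this package fixes because daily aggregation requires one.
* Coordinates are planar metric; `project_lonlat()` is the documented
  equirectangular entry point for geographic inputs (adequate below ~0.1%
  distortion at city scale).
* A TWA over zero total hours is an error (undefined day), not a zero.
* A zero scenario TWA makes contribution rates undefined (error).
* Pearson r is reported as `NA` when either series has zero variance;
  paired t-tests on identically zero differences are reported as
  no-difference with p = 1.
* CV is computed as 100·sd/mean of the pooled participant-day series per
  scenario; published per-scenario CVs are not always consistent with
  their own printed mean/sd pairs, so the package fixes and documents this
  one convention.

## Known limitations

* The kriging is isotropic, per-hour, and purely spatial; no universal
  kriging drift terms, no space-time covariance.
* The indoor models see only six hourly inputs; occupant behavior
  (cooking, window opening) is unobservable to them by construction, which
  is precisely the mechanism being studied, but also a real limitation for
  absolute accuracy.
* Contribution CTE/RME profiles describe single selected days; they carry
  no uncertainty statement.
* The generator's parameters are free design knobs, not estimates of any
  particular housing stock; quantitative agreement with any specific
  published table is out of scope for the synthetic pipeline.
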