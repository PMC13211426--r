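# pmexposure

Daily personal PM2.5 exposure assessment from a dense low-cost sensor
network, GPS trajectories, 30-minute time–activity diaries, home indoor
monitors and hourly microenvironment concentration models — for exposure
scientists and environmental epidemiologists who need to know how much a
fixed-site exposure assignment misrepresents what people actually breathe.

## What it computes

Everything rests on the time-weighted average (TWA)

```
C_TWA = Σᵢ Cᵢ·Tᵢ / Σᵢ Tᵢ
```

where `Cᵢ` is the PM2.5 concentration of microenvironment *i* and `Tᵢ` the
time spent there. Three reconstructions of a person's daily exposure are
computed and compared against personal-monitor ground truth:

| Scenario | Indoor concentration | Outdoor concentration | Occupancy times |
|---|---|---|---|
| S1 | measured at home | kriged grid cell of the home | fixed handbook values (15.86 h / 3.34 h) |
| S2 | measured at home | kriged cells along the GPS track | personal diary hours |
| S3 | hourly model per microenvironment | kriged cells along the GPS track | personal diary hours |

Around that core the package provides:

* **Ordinary kriging** of hourly sensor-network snapshots onto a 500 m
  grid (Matheron empirical variogram, weighted-least-squares spherical
  fit, sum-to-one kriging weights, negative predictions clipped);
* **trajectory–grid fusion**: per-minute GPS fixes matched to half-open
  grid cells at the temporally nearest hourly field, aggregated to the
  30-minute diary lattice, with the diary as the authoritative occupancy
  record;
* **indoor models**: per-microenvironment tree ensembles (extremely
  randomized forest for houses, gradient boosting elsewhere) predicting
  hourly indoor PM2.5 from outdoor PM2.5, the PM2.5/PM10 ratio and four
  meteorological variables;
* **contribution rates**: indoor/outdoor shares of each day's exposure,
  summarized at the 50th-percentile (CTE) and 95th-percentile (RME) days;
* **evaluation**: RMSE, MAE, Pearson r, CV and mean-ratio summaries plus
  paired t-tests and one-way ANOVA;
* a **synthetic panel-study generator** reproducing the qualitative
  structure of urban exposure data — commute-corridor pollution excess,
  short indoor peak events that hourly models cannot capture, ~19 h/day
  spent indoors — so the whole pipeline is testable without restricted
  panel data.

## Worked example

Simulate a small synthetic panel (5 participants × 7 days, 50 sensors) and
run the full pipeline:

```r
library(pmexposure)

scn <- sim_scenario("small", rng_seed = 1)
data_dir <- file.path(tempdir(), "demo")
simulate_study(scn, data_dir)

res <- run_exposure_pipeline(data_dir, study_config(rng_seed = 1))
res$evaluation
#> # A tibble: 4 × 11
#>   series n_days  mean    sd cv_pct    mae  rmse pearson_r mean_ratio_to_measured
#> 1 measu…     35  17.9  3.39   18.9 NA     NA       NA                        1
#> 2 S1         35  25.1  7.28   29.0  7.22   9.22     0.621                    1.4
#> 3 S2         35  31.1 11.5    37.1 13.2   17.1      0.278                    1.7
#> 4 S3         35  17.0  3.12   18.4  0.987  1.12     0.984                    0.9
```

The designed structure of urban panel data appears directly in the
numbers: S2 (GPS outdoor + single home monitor) overestimates the most —
its outdoor term samples the polluted commute corridor and its indoor term
carries the home monitor's peak events; S1 overestimates through the same
home monitor; S3, built from hourly microenvironment models that smooth
out short peak episodes, slightly underestimates but tracks the day-to-day
variation far better (here r ≈ 0.98 vs 0.62/0.28, and the smallest RMSE
and MAE).

```r
subset(res$contribution, convention == "normalized" & level == "CTE")
#>   scenario level convention indoor_pct outdoor_pct participant_id date
#> 1 S1       CTE   normalized       91.0        9.03 P02        2023-01-13
#> 3 S2       CTE   normalized       95.3        4.66 P01        2023-01-10
#> 5 S3       CTE   normalized       94.2        5.76 P02        2023-01-11
```

Indoor environments dominate exposure (> 90% at the central-tendency day in
all scenarios) because most of the day is spent indoors — the reason
fixed-site outdoor assignments misclassify personal exposure.

A thin command-line front end over the same functions lives in
`inst/cli/exposure.R`:

```sh
Rscript inst/cli/exposure.R simulate --preset small --seed 7 --out study/
Rscript inst/cli/exposure.R estimate --data study/ --out results/
```

## Package layout

```
R/                  io/validation, synthetic generator, kriging, trajectory
                    fusion, indoor models, TWA scenarios, contributions,
                    evaluation, pipeline orchestration
inst/cli/           command-line front end
inst/extdata/       published reference summary (CSV)
scripts/            acceptance script
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (models, conventions, design choices)
```
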