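#' Run the full exposure-assessment pipeline on a study directory
#'
#' Reads the study CSVs (sensor network, diaries, GPS, home and personal
#' monitors, meteorology, home locations, indoor reference series), kriges
#' the sensor network to the grid hour by hour (PM2.5 and PM10), fuses GPS
#' tracks and diaries into occupancy series, trains the microenvironment
#' indoor models, computes S1/S2/S3 and measured daily exposures, and
#' produces the evaluation and contribution summaries.
#'
#' @param data_dir Directory with `sensors.csv`, `diary.csv`, `gps.csv`,
#'   `home_monitor.csv`, `personal.csv`, `met.csv`, `homes.csv`,
#'   `indoor_reference.csv` (the layout written by [simulate_study()]).
#' @param cfg A `study_config`.
#' @param out_dir Optional output directory; when given, `daily.csv`,
#'   `evaluation.csv` and `contribution.csv` are written there
#'   (deterministically for fixed inputs and seed).
#' @return List with `daily` (the `daily_exposure` table), `evaluation`
#'   (per-scenario metrics), `comparisons` (paired tests + ANOVA),
#'   `contribution` (CTE/RME summary), `models`, and `geom`.
#' @export
run_exposure_pipeline <- function(data_dir, cfg = study_config(),
                                  out_dir = NULL) {
  sensors <- read_sensor_table(file.path(data_dir, "sensors.csv"))
  diary <- read_diary(file.path(data_dir, "diary.csv"))
  track <- read_track(file.path(data_dir, "gps.csv"))
  home_monitor <- read_monitor_series(file.path(data_dir, "home_monitor.csv"))
  personal <- read_monitor_series(file.path(data_dir, "personal.csv"))
  met <- read_met(file.path(data_dir, "met.csv"))
  homes <- read_homes(file.path(data_dir, "homes.csv"))
  reference <- readr::read_csv(file.path(data_dir, "indoor_reference.csv"),
                               show_col_types = FALSE, progress = FALSE)
  reference$timestamp <- parse_timestamp(reference$timestamp)

  s <- cfg$grid_cell_size_m
  xr <- range(c(sensors$x_m, track$x_m, homes$x_m))
  yr <- range(c(sensors$y_m, track$y_m, homes$y_m))
  geom <- grid_geometry(
    x0 = floor(xr[1] / s) * s, y0 = floor(yr[1] / s) * s,
    cell_size_m = s,
    n_cols = ceiling((xr[2] - floor(xr[1] / s) * s) / s) + 1,
    n_rows = ceiling((yr[2] - floor(yr[1] / s) * s) / s) + 1
  )
  stack25 <- krige_sensor_hours(sensors, geom, "pm25",
                                max_neighbors = cfg$max_neighbors)
  stack10 <- krige_sensor_hours(sensors, geom, "pm10",
                                max_neighbors = cfg$max_neighbors)

  gps25 <- slot_average(suppressMessages(match_track_to_grid(track, stack25)))
  gps10 <- slot_average(suppressMessages(match_track_to_grid(track, stack10)))
  gps_slots <- dplyr::left_join(
    gps25, dplyr::rename(gps10, value_pm10 = "value"),
    by = c("participant_id", "slot_start"))

  home_slots <- dplyr::bind_rows(lapply(seq_len(nrow(homes)), function(i) {
    hs <- home_cell_series(c(homes$x_m[i], homes$y_m[i]), stack25)
    hs$participant_id <- homes$participant_id[i]
    hs
  }))

  occ <- build_occupancy(diary, gps_slots, home_slots, cfg)
  models <- train_microenv_models(reference, stack25, stack10, met, cfg)
  occ <- add_indoor_predictions(occ, models, met)

  daily <- compute_daily_exposure(occ, home_monitor, personal, cfg)
  evaluation <- summarize_scenarios(daily)
  comparisons <- paired_comparisons(daily)
  contribution <- contribution_summary(occ, home_monitor, daily, cfg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    daily_out <- daily
    num <- vapply(daily_out, is.numeric, logical(1))
    daily_out[num] <- lapply(daily_out[num], round, 4)
    write_table_csv(daily_out, file.path(out_dir, "daily.csv"))
    ev <- evaluation
    num <- vapply(ev, is.numeric, logical(1))
    ev[num] <- lapply(ev[num], round, 4)
    write_table_csv(ev, file.path(out_dir, "evaluation.csv"))
    co <- contribution
    co$indoor_pct <- round(co$indoor_pct, 4)
    co$outdoor_pct <- round(co$outdoor_pct, 4)
    write_table_csv(co, file.path(out_dir, "contribution.csv"))
  }
  list(daily = daily, evaluation = evaluation, comparisons = comparisons,
       contribution = contribution, models = models, geom = geom)
}

#' Ratio of two mean concentrations, as reported
#'
#' Convenience for the "x times higher" comparisons used in exposure
#' reports: the ratio of two means rounded to a stated precision.
#'
#' @param numerator_mean,denominator_mean Mean concentrations (ug/m3).
#' @param digits Decimal places of the reported ratio.
#' @return The rounded ratio.
#' @export
concentration_ratio <- function(numerator_mean, denominator_mean, digits = 1) {
  stopifnot(denominator_mean > 0)
  round(numerator_mean / denominator_mean, digits)
}

#' Published summary statistics of the motivating panel study
#'
#' Daily-exposure summary statistics reported for a 93-adult panel in the
#' Seoul metropolitan area (measured personal exposure and the three TWA
#' scenarios), plus the highest and lowest participant mean exposures.
#' Shipped so that the package's ratio-style summaries can be reproduced
#' from the published numbers without access to the restricted panel data.
#'
#' @return Tibble `quantity, series, value` (concentrations in ug/m3).
#' @export
reference_panel_summary <- function() {
  path <- system.file("extdata", "panel_reference_summary.csv",
                      package = "pmexposure", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
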