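#' Time-weighted average concentration
#'
#' \eqn{C_{TWA} = \sum_i C_i T_i / \sum_i T_i}: the daily exposure
#' concentration as the occupancy-time-weighted mean of microenvironment
#' concentrations.
#'
#' @param conc Concentrations \eqn{C_i} (ug/m3), non-negative.
#' @param hours Occupancy times \eqn{T_i} (hours), non-negative.
#' @return The TWA concentration (ug/m3).
#' @export
twa <- function(conc, hours) {
  stopifnot(length(conc) == length(hours))
  keep <- !is.na(conc) & !is.na(hours)
  conc <- conc[keep]; hours <- hours[keep]
  if (any(conc < 0) || any(hours < 0)) {
    stop("twa: concentrations and hours must be non-negative", call. = FALSE)
  }
  if (sum(hours) <= 0) {
    stop("twa: total occupancy time is zero; day undefined", call. = FALSE)
  }
  sum(conc * hours) / sum(hours)
}

#' Scenario S1: fixed-site estimate with handbook occupancy times
#'
#' Combines the measured daily home indoor concentration and the kriged
#' outdoor concentration at the home cell using fixed population-average
#' occupancy times (defaults 15.86 h at home, 3.34 h outdoors).
#'
#' @param c_house Daily mean measured home indoor PM2.5 (ug/m3; vectorized
#'   over days).
#' @param c_outdoor Daily mean kriged outdoor PM2.5 at the home cell.
#' @param cfg A `study_config`.
#' @return Daily S1 TWA concentrations; `NA` where either input is missing
#'   (day excluded).
#' @export
scenario_s1 <- function(c_house, c_outdoor, cfg = study_config()) {
  th <- cfg$s1_time_house_h; to <- cfg$s1_time_outdoor_h
  out <- (c_house * th + c_outdoor * to) / (th + to)
  out[is.na(c_house) | is.na(c_outdoor)] <- NA_real_
  out
}

slot_series <- function(monitor) {
  monitor |>
    dplyr::mutate(slot_start = slot_floor(.data$timestamp)) |>
    dplyr::group_by(.data$participant_id, .data$slot_start) |>
    dplyr::summarise(value = mean(.data$pm25, na.rm = TRUE), .groups = "drop")
}

#' Scenario S2: measured home concentration with diary occupancy times
#'
#' Two-term TWA per participant-day: the measured home concentration
#' weighted by diary home hours plus the GPS-matched outdoor concentration
#' weighted by diary outdoor hours. Hours spent in other indoor
#' microenvironments are excluded from numerator and denominator (the
#' formula has exactly two terms); `cfg$s2_fold_other_into_house` folds them
#' into the house term instead, as a sensitivity variant. Computed at slot
#' level, then aggregated.
#'
#' @param occ An `occupancy` tibble.
#' @param home_monitor A `monitor_series` of home indoor measurements.
#' @param cfg A `study_config`.
#' @return Tibble `participant_id, date, s2` (`NA` where the combined
#'   house + outdoor time is zero or the day is excluded).
#' @export
scenario_s2 <- function(occ, home_monitor, cfg = study_config()) {
  hm <- slot_series(home_monitor)
  house_like <- if (cfg$s2_fold_other_into_house) indoor_levels() else "house"
  occ |>
    dplyr::left_join(dplyr::rename(hm, c_house_slot = "value"),
                     by = c("participant_id", "slot_start")) |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(
      s2 = {
        is_house <- .data$microenv %in% house_like & !is.na(.data$c_house_slot)
        is_out <- .data$microenv %in% "outdoor" & !is.na(.data$c_outdoor_gps)
        num <- sum(.data$c_house_slot[is_house]) * 0.5 +
          sum(.data$c_outdoor_gps[is_out]) * 0.5
        den <- (sum(is_house) + sum(is_out)) * 0.5
        if (den > 0 && !any(.data$day_excluded)) num / den else NA_real_
      },
      .groups = "drop"
    )
}

#' Scenario S3: microenvironment model predictions with diary occupancy
#'
#' TWA over the five indoor microenvironments (hourly model predictions)
#' plus GPS-matched outdoor concentration, weighted by diary hours; the
#' denominator is the day's accounted (labeled) time. Transportation uses
#' its indoor model unless `cfg$transport_outdoor` routes it to the
#' GPS-matched outdoor concentration. A day whose occupied indoor label
#' lacks a prediction is excluded (`NA`).
#'
#' @param occ An `occupancy` tibble carrying a `c_indoor_pred` column (see
#'   [add_indoor_predictions()]).
#' @param cfg A `study_config`.
#' @return Tibble `participant_id, date, s3`.
#' @export
scenario_s3 <- function(occ, cfg = study_config()) {
  if (!"c_indoor_pred" %in% names(occ)) {
    stop("scenario_s3: occupancy lacks 'c_indoor_pred'; ",
         "run add_indoor_predictions() first", call. = FALSE)
  }
  out_like <- if (cfg$transport_outdoor) c("outdoor", "transportation")
              else "outdoor"
  occ |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(
      s3 = {
        lab <- .data$microenv
        is_out <- lab %in% out_like
        is_in <- !is.na(lab) & !is_out
        cvals <- ifelse(is_out, .data$c_outdoor_gps, .data$c_indoor_pred)
        ok <- (is_in | is_out)
        if (any(ok & is.na(cvals)) || !any(ok) || any(.data$day_excluded)) {
          NA_real_
        } else {
          sum(cvals[ok]) * 0.5 / (sum(ok) * 0.5)
        }
      },
      .groups = "drop"
    )
}

#' Attach per-slot indoor model predictions to an occupancy series
#'
#' Builds the six-feature row for every slot from the GPS-matched outdoor
#' PM2.5/PM10 and hourly meteorology, and predicts with the occupied
#' label's model. Hourly model output applies to both slots of the hour.
#'
#' @param occ An `occupancy` tibble with `c_outdoor_gps` and
#'   `c_outdoor_gps_pm10`.
#' @param models Named list from [train_microenv_models()].
#' @param met A validated `met_table`.
#' @return `occ` with a `c_indoor_pred` column (NA for outdoor/gap slots or
#'   labels without a model).
#' @export
add_indoor_predictions <- function(occ, models, met) {
  hrs <- hour_floor(occ$slot_start)
  mi <- nearest_time_index(met$timestamp, hrs)
  feats <- tibble::tibble(
    outdoor_pm25 = occ$c_outdoor_gps,
    ratio_pm25_pm10 = pmin(pmax(
      occ$c_outdoor_gps / pmax(occ$c_outdoor_gps_pm10, 1e-9), 1e-6), 1),
    temp_c = met$temp_c[mi], wind_ms = met$wind_ms[mi],
    rh_pct = met$rh_pct[mi], precip_mm = met$precip_mm[mi]
  )
  pred <- rep(NA_real_, nrow(occ))
  for (l in intersect(indoor_levels(), unique(occ$microenv))) {
    if (is.null(models[[l]])) next
    sel <- which(occ$microenv == l & !is.na(feats$outdoor_pm25))
    if (length(sel) == 0) next
    pred[sel] <- predict_indoor(models[[l]], feats[sel, ])
  }
  occ$c_indoor_pred <- pred
  occ
}

#' Measured daily personal exposure
#'
#' Equal-cadence time-weighted daily mean of the personal monitor; days
#' with less than `min_coverage_h` of valid samples are excluded.
#'
#' @param personal A `monitor_series` of personal measurements.
#' @param min_coverage_h Minimum valid coverage (hours) to retain a day.
#' @return Tibble `participant_id, date, measured, coverage_h`.
#' @export
measured_daily <- function(personal, min_coverage_h = 18) {
  cad <- personal |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      cadence_min = if (dplyr::n() > 1)
        stats::median(diff(as.numeric(.data$timestamp))) / 60 else 60,
      .groups = "drop"
    )
  personal |>
    dplyr::mutate(date = day_of(.data$timestamp)) |>
    dplyr::left_join(cad, by = "participant_id") |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(
      coverage_h = sum(!is.na(.data$pm25)) * .data$cadence_min[1] / 60,
      measured = mean(.data$pm25, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(measured = ifelse(.data$coverage_h >= min_coverage_h,
                                    .data$measured, NA_real_))
}

#' Daily exposure table: all scenarios plus measured truth
#'
#' Computes S1, S2, S3 and the measured daily mean for every
#' participant-day, together with the diary hours by microenvironment.
#'
#' @param occ An `occupancy` tibble with `c_indoor_pred` attached.
#' @param home_monitor Home indoor `monitor_series`.
#' @param personal Personal `monitor_series` (ground truth).
#' @param cfg A `study_config`.
#' @return A `daily_exposure` tibble: `participant_id, date, s1, s2, s3,
#'   measured`, `h_<label>` hours columns and `gap_h`.
#' @export
compute_daily_exposure <- function(occ, home_monitor, personal,
                                   cfg = study_config()) {
  hm_slots <- slot_series(home_monitor)
  daily_house <- hm_slots |>
    dplyr::mutate(date = day_of(.data$slot_start)) |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(c_house_daily = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
  daily_out <- occ |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(c_outdoor_daily = mean(.data$c_outdoor_home, na.rm = TRUE),
                     .groups = "drop")
  s1 <- daily_house |>
    dplyr::full_join(daily_out, by = c("participant_id", "date")) |>
    dplyr::mutate(s1 = scenario_s1(.data$c_house_daily, .data$c_outdoor_daily,
                                   cfg)) |>
    dplyr::select("participant_id", "date", "s1")
  s2 <- scenario_s2(occ, home_monitor, cfg)
  s3 <- scenario_s3(occ, cfg)
  meas <- measured_daily(personal, cfg$min_personal_coverage_h)
  hrs <- occupancy_hours(occ)
  out <- hrs |>
    dplyr::left_join(s1, by = c("participant_id", "date")) |>
    dplyr::left_join(s2, by = c("participant_id", "date")) |>
    dplyr::left_join(s3, by = c("participant_id", "date")) |>
    dplyr::left_join(dplyr::select(meas, "participant_id", "date", "measured"),
                     by = c("participant_id", "date")) |>
    dplyr::relocate("participant_id", "date", "s1", "s2", "s3", "measured")
  class(out) <- c("daily_exposure", class(out))
  out
}
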