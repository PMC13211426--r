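#' Match a GPS track to kriged grid concentrations
#'
#' Maps every GPS fix to its half-open grid cell at the temporally nearest
#' kriged field (ties resolve to the earlier field). Fixes outside the grid
#' extent are assigned the nearest boundary cell and counted in the
#' `n_clamped` attribute.
#'
#' @param track A validated `track` (per-minute fixes).
#' @param stack A `grid_stack` covering the track's time span.
#' @return Tibble `participant_id, timestamp, value` with the matched cell
#'   concentration per fix.
#' @export
match_track_to_grid <- function(track, stack) {
  cell <- lookup_cell(stack$geom, track$x_m, track$y_m, clamp = TRUE)
  n_out <- attr(cell, "n_clamped")
  if (n_out > 0) message(sprintf(
    "match_track_to_grid: %d fix(es) outside extent mapped to boundary cells",
    n_out))
  ti <- nearest_time_index(stack$times, track$timestamp)
  out <- tibble::tibble(
    participant_id = track$participant_id,
    timestamp = track$timestamp,
    value = stack$values[cbind(cell$row, cell$col, ti)]
  )
  attr(out, "n_clamped") <- n_out
  out
}

#' Average a matched per-minute series up to 30-minute slots
#'
#' @param matched Output of [match_track_to_grid()].
#' @return Tibble `participant_id, slot_start, value` (slot mean).
#' @export
slot_average <- function(matched) {
  matched |>
    dplyr::mutate(slot_start = slot_floor(.data$timestamp)) |>
    dplyr::group_by(.data$participant_id, .data$slot_start) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
}

#' Fixed home-cell concentration series
#'
#' Extracts the kriged concentration of the cell containing the home
#' location for each 30-minute slot, using the same per-minute
#' nearest-field averaging as [match_track_to_grid()], so that a
#' permanently-home track and the home-cell series agree exactly.
#'
#' @param home_xy Numeric `c(x_m, y_m)` of the residence.
#' @param stack A `grid_stack`.
#' @param slots Optional POSIXct slot starts; defaults to the full 30-minute
#'   lattice spanning the stack's hours.
#' @return Tibble `slot_start, value`.
#' @export
home_cell_series <- function(home_xy, stack, slots = NULL) {
  if (is.null(slots)) {
    d0 <- slot_floor(min(stack$times))
    d1 <- hour_floor(max(stack$times))
    slots <- seq(d0, d1 + 3599, by = 1800)
  }
  minutes <- rep(slots, each = 30) + 60 * rep(0:29, times = length(slots))
  vals <- stack_lookup(stack, home_xy[1], home_xy[2], minutes)
  tibble::tibble(
    slot_start = slots,
    value = colMeans(matrix(vals, nrow = 30))
  )
}

#' Build per-slot occupancy series
#'
#' Joins the diary with GPS-matched and home-cell outdoor concentrations on
#' the 30-minute slot lattice. Each participant-day is completed to 48
#' slots; missing diary slots become explicit gaps. When a day's gap time
#' exceeds `cfg$gap_limit_h` the day is flagged excluded; smaller gaps
#' inherit the previous slot's label (carried forward within participant)
#' and are marked `imputed`. The diary label is authoritative: GPS never
#' overrides it.
#'
#' @param diary A validated `diary`.
#' @param gps_slots Tibble `participant_id, slot_start, value` of
#'   GPS-matched outdoor PM2.5 (see [slot_average()]); may also carry a
#'   `value_pm10` column for the PM2.5/PM10 feature.
#' @param home_slots Tibble `participant_id, slot_start, value` of home-cell
#'   outdoor PM2.5.
#' @param cfg A `study_config`.
#' @return An `occupancy` tibble: `participant_id, slot_start, date,
#'   microenv, imputed, gap, c_outdoor_gps, c_outdoor_gps_pm10,
#'   c_outdoor_home, day_excluded`.
#' @export
build_occupancy <- function(diary, gps_slots, home_slots, cfg = study_config()) {
  lattice <- diary |>
    dplyr::distinct(.data$participant_id, date = day_of(.data$slot_start)) |>
    dplyr::rowwise() |>
    dplyr::mutate(slot_start = list(
      as.POSIXct(paste(.data$date, "00:00:00"), tz = "UTC") + 1800 * (0:47))) |>
    dplyr::ungroup() |>
    tidyr::unnest("slot_start")
  occ <- lattice |>
    dplyr::left_join(
      dplyr::select(diary, "participant_id", "slot_start", "microenv"),
      by = c("participant_id", "slot_start")
    ) |>
    dplyr::arrange(.data$participant_id, .data$slot_start) |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::mutate(gap_h = sum(is.na(.data$microenv)) * 0.5) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      imputed = is.na(.data$microenv) & .data$gap_h <= cfg$gap_limit_h,
      microenv = ifelse(
        .data$gap_h <= cfg$gap_limit_h,
        vctrs_fill_down(.data$microenv), .data$microenv
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      gap = is.na(.data$microenv),
      imputed = .data$imputed & !.data$gap,
      day_excluded = .data$gap_h > cfg$gap_limit_h
    ) |>
    dplyr::select(-"gap_h")
  gps_slots <- dplyr::rename(gps_slots, c_outdoor_gps = "value")
  if (!"value_pm10" %in% names(gps_slots)) gps_slots$value_pm10 <- NA_real_
  gps_slots <- dplyr::rename(gps_slots, c_outdoor_gps_pm10 = "value_pm10")
  home_slots <- dplyr::rename(home_slots, c_outdoor_home = "value")
  occ <- occ |>
    dplyr::left_join(gps_slots, by = c("participant_id", "slot_start")) |>
    dplyr::left_join(home_slots, by = intersect(
      c("participant_id", "slot_start"), names(home_slots)))
  class(occ) <- c("occupancy", class(occ))
  occ
}

# last-observation-carried-forward for a character vector (base, no deps)
vctrs_fill_down <- function(x) {
  idx <- cumsum(!is.na(x))
  filled <- x[!is.na(x)][pmax(idx, 1)]
  filled[idx == 0] <- NA
  filled
}

#' Per-day hours spent in each microenvironment
#'
#' @param occ An `occupancy` tibble.
#' @return Tibble with one row per participant-day and one hours column per
#'   label plus `gap_h`; labeled plus gap hours always total 24.
#' @export
occupancy_hours <- function(occ) {
  base <- occ |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(
      day_excluded = any(.data$day_excluded),
      gap_h = sum(is.na(.data$microenv)) * 0.5,
      .groups = "drop"
    )
  counts <- occ |>
    dplyr::filter(!is.na(.data$microenv)) |>
    dplyr::count(.data$participant_id, .data$date, .data$microenv)
  out <- base
  for (l in microenv_levels()) {
    cl <- counts[counts$microenv == l, c("participant_id", "date", "n")]
    names(cl)[3] <- "n_l"
    out <- dplyr::left_join(out, cl, by = c("participant_id", "date"))
    out[[paste0("h_", l)]] <- ifelse(is.na(out$n_l), 0, out$n_l) * 0.5
    out$n_l <- NULL
  }
  out
}
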