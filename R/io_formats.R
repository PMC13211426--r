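#' Microenvironment labels
#'
#' The closed set of microenvironment labels used throughout the package:
#' five indoor categories plus outdoor. Time-activity diaries must use
#' exactly these labels.
#'
#' @return Character vector of the six labels.
#' @export
microenv_levels <- function() {
  c("house", "office", "educational_facility", "transportation",
    "other_indoor", "outdoor")
}

#' Indoor microenvironment labels
#'
#' @return The five indoor labels (everything except `"outdoor"`).
#' @export
indoor_levels <- function() {
  setdiff(microenv_levels(), "outdoor")
}

#' Study configuration
#'
#' Bundles the fixed analysis parameters of the exposure pipeline. Defaults
#' follow the study conventions: a 500 m kriging grid, handbook occupancy
#' times of 15.86 h indoors at home and 3.34 h outdoors for scenario S1, and
#' the 50th/95th percentile days for the central-tendency (CTE) and
#' reasonable-maximum (RME) contribution summaries.
#'
#' @param grid_cell_size_m Kriging grid cell size in meters (default 500).
#' @param s1_time_house_h Fixed home occupancy time (hours) used by S1.
#' @param s1_time_outdoor_h Fixed outdoor occupancy time (hours) used by S1.
#' @param cte_percentile Fraction defining the CTE day (default 0.50).
#' @param rme_percentile Fraction defining the RME day (default 0.95).
#' @param gap_limit_h Diary gap tolerance per participant-day (hours): days
#'   with more than this much unlabeled time are excluded from TWA
#'   computation; smaller gaps inherit the previous slot's label.
#' @param min_personal_coverage_h Minimum valid personal-monitor coverage
#'   (hours) for a measured daily mean to be retained.
#' @param transport_outdoor If `TRUE`, scenario S3 treats transportation
#'   slots as outdoor (GPS-matched grid concentration); if `FALSE` (default)
#'   transportation uses its indoor prediction model, consistent with its
#'   classification among the indoor microenvironments.
#' @param s2_fold_other_into_house If `TRUE`, scenario S2 folds hours spent
#'   in non-house indoor microenvironments into the house term (sensitivity
#'   variant); by default those hours are excluded from both numerator and
#'   denominator, as the two-term S2 formula is written.
#' @param contribution_convention `"normalized"` (denominator is the day's
#'   accounted hours, shares sum to 100) or `"literal24"` (denominator fixed
#'   at 24 h). Both are always computed; this selects the headline one.
#' @param pool_sparse_labels If `TRUE`, office/educational/transportation/
#'   other-indoor share one pooled indoor model when any label has fewer
#'   than 100 training rows.
#' @param max_neighbors Maximum number of nearest stations used per kriging
#'   solve.
#' @param rng_seed Integer seed used wherever the pipeline needs randomness
#'   (model training splits).
#'
#' @return An object of class `study_config`.
#' @export
study_config <- function(grid_cell_size_m = 500,
                         s1_time_house_h = 15.86,
                         s1_time_outdoor_h = 3.34,
                         cte_percentile = 0.50,
                         rme_percentile = 0.95,
                         gap_limit_h = 4,
                         min_personal_coverage_h = 18,
                         transport_outdoor = FALSE,
                         s2_fold_other_into_house = FALSE,
                         contribution_convention = c("normalized", "literal24"),
                         pool_sparse_labels = FALSE,
                         max_neighbors = 64,
                         rng_seed = 1L) {
  contribution_convention <- match.arg(contribution_convention)
  cfg <- structure(
    list(
      grid_cell_size_m = as.numeric(grid_cell_size_m),
      s1_time_house_h = as.numeric(s1_time_house_h),
      s1_time_outdoor_h = as.numeric(s1_time_outdoor_h),
      cte_percentile = as.numeric(cte_percentile),
      rme_percentile = as.numeric(rme_percentile),
      gap_limit_h = as.numeric(gap_limit_h),
      min_personal_coverage_h = as.numeric(min_personal_coverage_h),
      transport_outdoor = isTRUE(transport_outdoor),
      s2_fold_other_into_house = isTRUE(s2_fold_other_into_house),
      contribution_convention = contribution_convention,
      pool_sparse_labels = isTRUE(pool_sparse_labels),
      max_neighbors = as.integer(max_neighbors),
      rng_seed = as.integer(rng_seed)
    ),
    class = "study_config"
  )
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  stopifnot(
    cfg$grid_cell_size_m > 0,
    cfg$s1_time_house_h >= 0, cfg$s1_time_outdoor_h >= 0,
    cfg$s1_time_house_h + cfg$s1_time_outdoor_h > 0,
    cfg$cte_percentile > 0, cfg$rme_percentile < 1,
    cfg$cte_percentile < cfg$rme_percentile,
    cfg$gap_limit_h >= 0, cfg$min_personal_coverage_h >= 0,
    cfg$max_neighbors >= 1
  )
  invisible(cfg)
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat(sprintf("  grid cell: %g m | S1 times: house %g h, outdoor %g h\n",
              x$grid_cell_size_m, x$s1_time_house_h, x$s1_time_outdoor_h))
  cat(sprintf("  CTE/RME percentiles: %g / %g | contribution: %s\n",
              x$cte_percentile, x$rme_percentile, x$contribution_convention))
  cat(sprintf("  diary gap limit: %g h | personal coverage: >= %g h | seed: %d\n",
              x$gap_limit_h, x$min_personal_coverage_h, x$rng_seed))
  invisible(x)
}

# ---- timestamp handling ----------------------------------------------------

# All timestamps are timezone-naive local time; internally stored as POSIXct
# in UTC so arithmetic never crosses DST. A participant-day is [00:00, 24:00).
parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(format(x, "%Y-%m-%d %H:%M:%S"),
                                                tz = "UTC"))
  out <- as.POSIXct(as.character(x), tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d"))
  out
}

format_timestamp <- function(x) format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC")

slot_floor <- function(t) {
  secs <- as.numeric(t)
  as.POSIXct(floor(secs / 1800) * 1800, origin = "1970-01-01", tz = "UTC")
}

hour_floor <- function(t) {
  secs <- as.numeric(t)
  as.POSIXct(floor(secs / 3600) * 3600, origin = "1970-01-01", tz = "UTC")
}

day_of <- function(t) as.Date(t, tz = "UTC")

# ---- generic validated reading --------------------------------------------

read_raw_csv <- function(path, required_cols, kind) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s schema error in '%s': missing column(s) %s",
                 kind, path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

# Apply named row-level checks; rows failing any check are dropped and logged
# once each (first failing reason wins), in a `rejections` attribute.
apply_row_checks <- function(df, checks, kind) {
  reason <- rep(NA_character_, nrow(df))
  for (nm in names(checks)) {
    ok <- checks[[nm]]
    ok[is.na(ok)] <- FALSE
    reason[is.na(reason) & !ok] <- nm
  }
  rejected <- which(!is.na(reason))
  rej <- tibble::tibble(row = rejected, reason = reason[rejected])
  if (nrow(rej) > 0) {
    message(sprintf("%s: rejected %d row(s) [%s]", kind, nrow(rej),
                    paste(sprintf("%s: %d", names(table(rej$reason)),
                                  as.integer(table(rej$reason))),
                          collapse = "; ")))
    df <- df[-rejected, , drop = FALSE]
  }
  attr(df, "rejections") <- rej
  df
}

#' Rejected-row log of a validated table
#'
#' @param x A table returned by one of the `read_*` functions.
#' @return A tibble with columns `row` (1-based row index in the source
#'   file's data section) and `reason`.
#' @export
rejections <- function(x) {
  r <- attr(x, "rejections")
  if (is.null(r)) tibble::tibble(row = integer(), reason = character()) else r
}

#' Read and validate a sensor-network table
#'
#' Expects columns `station_id, x_m, y_m, timestamp, pm25, pm10` with planar
#' metric coordinates. Rows with negative concentrations, `pm25 > pm10`,
#' non-finite coordinates, unparseable timestamps, or non-increasing
#' timestamps within a station are rejected and logged (see [rejections()]).
#'
#' @param path CSV file path.
#' @return A validated tibble of class `sensor_table`.
#' @export
read_sensor_table <- function(path) {
  df <- read_raw_csv(path, c("station_id", "x_m", "y_m", "timestamp",
                             "pm25", "pm10"), "sensor")
  ts <- parse_timestamp(df$timestamp)
  df$timestamp <- ts
  ord <- order(df$station_id, df$timestamp)
  df <- df[ord, , drop = FALSE]
  inc <- rep(TRUE, nrow(df))
  if (nrow(df) > 1) {
    same <- df$station_id[-1] == df$station_id[-nrow(df)]
    nondec <- diff(as.numeric(df$timestamp)) <= 0
    inc[-1] <- !(same & nondec)
  }
  df <- apply_row_checks(df, list(
    bad_timestamp = !is.na(df$timestamp),
    nonfinite_coord = is.finite(df$x_m) & is.finite(df$y_m),
    negative_pm25 = !is.na(df$pm25) & df$pm25 >= 0,
    negative_pm10 = !is.na(df$pm10) & df$pm10 >= 0,
    pm25_exceeds_pm10 = is.na(df$pm25) | is.na(df$pm10) | df$pm25 <= df$pm10,
    nonincreasing_time = inc
  ), "sensor")
  class(df) <- c("sensor_table", class(df))
  df
}

#' Read and validate a time-activity diary
#'
#' Expects columns `participant_id, slot_start, microenv`. Slot starts must
#' lie on the 30-minute lattice; labels must come from [microenv_levels()]
#' (an unknown label is an error naming the value); duplicate
#' (participant, slot) entries with conflicting labels are an error, exact
#' duplicates are dropped and logged.
#'
#' @param path CSV file path.
#' @return A validated tibble of class `diary`.
#' @export
read_diary <- function(path) {
  df <- read_raw_csv(path, c("participant_id", "slot_start", "microenv"),
                     "diary")
  df$slot_start <- parse_timestamp(df$slot_start)
  bad_label <- setdiff(unique(df$microenv), microenv_levels())
  if (length(bad_label) > 0) {
    stop("diary: unknown microenvironment label(s): ",
         paste(sprintf("'%s'", bad_label), collapse = ", "), call. = FALSE)
  }
  key <- paste(df$participant_id, format_timestamp(df$slot_start))
  if (anyDuplicated(key)) {
    lab_per_key <- tapply(df$microenv, key, function(v) length(unique(v)))
    if (any(lab_per_key > 1)) {
      stop("diary: duplicate (participant, slot) with conflicting labels: ",
           names(lab_per_key)[which(lab_per_key > 1)[1]], call. = FALSE)
    }
  }
  on_lattice <- !is.na(df$slot_start) &
    (as.numeric(df$slot_start) %% 1800 == 0)
  df <- apply_row_checks(df, list(
    bad_timestamp = !is.na(df$slot_start),
    off_lattice = on_lattice,
    duplicate_slot = !duplicated(key)
  ), "diary")
  df <- df[order(df$participant_id, df$slot_start), , drop = FALSE]
  class(df) <- c("diary", class(df))
  df
}

#' Read and validate a GPS track
#'
#' Expects columns `participant_id, timestamp, x_m, y_m` at (nominally)
#' 1-minute cadence. Cadence gaps are flagged in a `gaps` attribute, never
#' silently filled.
#'
#' @param path CSV file path.
#' @return A validated tibble of class `track`; `attr(x, "gaps")` lists
#'   participant gaps longer than one minute.
#' @export
read_track <- function(path) {
  df <- read_raw_csv(path, c("participant_id", "timestamp", "x_m", "y_m"),
                     "track")
  df$timestamp <- parse_timestamp(df$timestamp)
  df <- apply_row_checks(df, list(
    bad_timestamp = !is.na(df$timestamp),
    nonfinite_coord = is.finite(df$x_m) & is.finite(df$y_m)
  ), "track")
  df <- df[order(df$participant_id, df$timestamp), , drop = FALSE]
  gaps <- df |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      gap_after = list(.data$timestamp[which(diff(as.numeric(.data$timestamp)) > 60)]),
      .groups = "drop"
    ) |>
    tidyr::unnest("gap_after")
  attr(df, "gaps") <- gaps
  class(df) <- c("track", class(df))
  df
}

#' Read and validate a meteorology series
#'
#' Expects columns `timestamp, temp_c, wind_ms, rh_pct, precip_mm` (hourly).
#'
#' @param path CSV file path.
#' @return A validated tibble of class `met_table`.
#' @export
read_met <- function(path) {
  df <- read_raw_csv(path, c("timestamp", "temp_c", "wind_ms", "rh_pct",
                             "precip_mm"), "met")
  df$timestamp <- parse_timestamp(df$timestamp)
  df <- apply_row_checks(df, list(
    bad_timestamp = !is.na(df$timestamp),
    negative_wind = is.na(df$wind_ms) | df$wind_ms >= 0,
    rh_out_of_range = is.na(df$rh_pct) | (df$rh_pct >= 0 & df$rh_pct <= 100),
    negative_precip = is.na(df$precip_mm) | df$precip_mm >= 0
  ), "met")
  df <- df[order(df$timestamp), , drop = FALSE]
  class(df) <- c("met_table", class(df))
  df
}

#' Read a participant-indexed monitor series
#'
#' Shared reader for home indoor monitor and personal monitor series:
#' columns `participant_id, timestamp, pm25`. Negative concentrations and
#' unparseable timestamps are rejected and logged.
#'
#' @param path CSV file path.
#' @return A validated tibble of class `monitor_series`.
#' @export
read_monitor_series <- function(path) {
  df <- read_raw_csv(path, c("participant_id", "timestamp", "pm25"),
                     "monitor")
  df$timestamp <- parse_timestamp(df$timestamp)
  df <- apply_row_checks(df, list(
    bad_timestamp = !is.na(df$timestamp),
    negative_pm25 = !is.na(df$pm25) & df$pm25 >= 0
  ), "monitor")
  df <- df[order(df$participant_id, df$timestamp), , drop = FALSE]
  class(df) <- c("monitor_series", class(df))
  df
}

#' Read participant home locations
#'
#' Columns `participant_id, x_m, y_m` (planar metric coordinates of the
#' residence).
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_homes <- function(path) {
  df <- read_raw_csv(path, c("participant_id", "x_m", "y_m"), "homes")
  apply_row_checks(df, list(
    nonfinite_coord = is.finite(df$x_m) & is.finite(df$y_m)
  ), "homes")
}

#' Write a validated table back to CSV
#'
#' Timestamp columns are serialized as `YYYY-mm-dd HH:MM:SS` so that a
#' write-then-read round trip is value-identical.
#'
#' @param x A tibble (possibly one of the validated classes).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  out <- as.data.frame(x)
  for (nm in names(out)) {
    if (inherits(out[[nm]], "POSIXct")) out[[nm]] <- format_timestamp(out[[nm]])
  }
  readr::write_csv(tibble::as_tibble(out), path, progress = FALSE)
  invisible(path)
}

#' Project longitude/latitude to local planar meters
#'
#' Equirectangular projection about a stated origin: adequate at city scale
#' (< 0.1% distortion over tens of km), which is all the 500 m grid needs.
#' All package internals require planar metric coordinates; this is the
#' documented entry point for geographic inputs.
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @param origin_lon,origin_lat Projection origin in decimal degrees.
#' @return A tibble with columns `x_m`, `y_m`.
#' @export
project_lonlat <- function(lon, lat, origin_lon, origin_lat) {
  r_earth <- 6371008.8
  x <- (lon - origin_lon) * pi / 180 * r_earth * cos(origin_lat * pi / 180)
  y <- (lat - origin_lat) * pi / 180 * r_earth
  tibble::tibble(x_m = x, y_m = y)
}
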