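# shared fixture builders: everything is generated in code at test time

write_fixture_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

ts0 <- function(h = 0, m = 0, day = "2023-01-09") {
  as.POSIXct(sprintf("%s %02d:%02d:00", day, h, m), tz = "UTC")
}

# a constant-valued hourly grid stack over `n_hours`
constant_stack <- function(value = 12, n_hours = 24, n_cols = 4, n_rows = 4,
                           cell = 500, day = "2023-01-09") {
  geom <- grid_geometry(0, 0, cell, n_cols, n_rows)
  times <- ts0(day = day) + 3600 * (seq_len(n_hours) - 1)
  vals <- array(value, dim = c(n_rows, n_cols, n_hours))
  structure(list(geom = geom, times = times, values = vals,
                 value_col = "pm25"), class = "grid_stack")
}

# stack whose cell values are a supplied function of (col, row, hour index)
patterned_stack <- function(f, n_hours = 24, n_cols = 4, n_rows = 4,
                            cell = 500, day = "2023-01-09") {
  geom <- grid_geometry(0, 0, cell, n_cols, n_rows)
  times <- ts0(day = day) + 3600 * (seq_len(n_hours) - 1)
  vals <- array(NA_real_, dim = c(n_rows, n_cols, n_hours))
  for (k in seq_len(n_hours))
    for (j in seq_len(n_cols))
      for (i in seq_len(n_rows)) vals[i, j, k] <- f(j, i, k)
  structure(list(geom = geom, times = times, values = vals,
                 value_col = "pm25"), class = "grid_stack")
}

# single-participant diary for one day from a label vector of length 48
diary_from_labels <- function(labels, id = "P01", day = "2023-01-09") {
  stopifnot(length(labels) == 48)
  tibble::tibble(participant_id = id,
                 slot_start = ts0(day = day) + 1800 * (0:47),
                 microenv = labels)
}

# monitor series at a fixed cadence from a value vector
monitor_from_values <- function(values, cadence_min = 10, id = "P01",
                                day = "2023-01-09") {
  tibble::tibble(
    participant_id = id,
    timestamp = ts0(day = day) + 60 * cadence_min * (seq_along(values) - 1),
    pm25 = values
  )
}

# random occupancy fixture with gps/home concentrations, for property tests
random_occupancy <- function(seed, id = "P01", day = "2023-01-09") {
  set.seed(seed)
  labels <- sample(microenv_levels(), 48, replace = TRUE,
                   prob = c(0.5, 0.2, 0.05, 0.05, 0.1, 0.1))
  occ <- diary_from_labels(labels, id = id, day = day)
  occ$date <- as.Date(day)
  occ$imputed <- FALSE
  occ$gap <- FALSE
  occ$day_excluded <- FALSE
  occ$c_outdoor_gps <- runif(48, 5, 40)
  occ$c_outdoor_gps_pm10 <- occ$c_outdoor_gps / runif(48, 0.4, 0.7)
  occ$c_outdoor_home <- runif(48, 5, 30)
  occ
}

# brute-force slot-level weighted mean: independent oracle for the TWA engine
slot_brute_force <- function(conc, keep) {
  sum(conc[keep] * 0.5) / (sum(keep) * 0.5)
}
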