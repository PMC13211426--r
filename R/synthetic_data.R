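# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so generator calls never perturb user code.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic study scenario
#'
#' Defines a complete synthetic panel study: an urban domain with a
#' high-pollution commute corridor, a spatially correlated outdoor PM2.5
#' field with a diurnal cycle, participants who move between off-corridor
#' homes and corridor workplaces, home monitors subject to short indoor
#' peak events (cooking-type sources), and the meteorology and sensor
#' network needed by the downstream pipeline.
#'
#' Defaults encode the qualitative structure of urban panel data: GPS-matched
#' outdoor concentrations exceed home-cell concentrations (activity happens
#' in the corridor), stationary home monitors read above source-free indoor
#' predictions (peak events), and participants spend roughly 19 h/day
#' indoors with about 12 h at home and 1.5 h outdoors.
#'
#' @param preset `"small"` (5 participants, 7 days, 50 sensors — the test
#'   default), `"study"` (93 participants, 60 days, 200 sensors — mirrors
#'   the motivating study's scale), or `"tiny"` (2 participants, 2 days,
#'   30 sensors — smoke-test scale).
#' @param n_participants,n_days,n_sensors Study size overrides.
#' @param domain_extent_m Width/height of the square domain (meters).
#' @param outdoor Outdoor-field parameters: `mean_level` (ug/m3),
#'   `spatial_range_m`, `sill`, `nugget` ((ug/m3)^2, spherical covariance),
#'   `diurnal_amp` (ug/m3), `day_sd` (between-day regional sd, ug/m3).
#' @param urban_excess Additional concentration (ug/m3) inside the commute
#'   corridor band.
#' @param corridor_halfwidth_m Half-width of the corridor band.
#' @param infiltration Named list (one entry per indoor label) of
#'   `c(slope, intercept)`: indoor baseline = slope * outdoor + intercept.
#' @param peak_process Home peak-event process: `rate_per_day` (Poisson),
#'   `magnitude_ugm3` (exponential mean of the initial peak height),
#'   `decay_per_h` (exponential decay), `room_fraction` (share of the
#'   monitor-local peak signal present in the room-average/breathing zone;
#'   the stationary monitor sits near sources and reads the full peak).
#' @param sensor_noise_sd,monitor_noise_sd,indoor_noise_sd Measurement noise
#'   standard deviations (ug/m3).
#' @param start_date First study day (a participant-day is local
#'   `[00:00, 24:00)`).
#' @param rng_seed Integer seed; every generated artifact is a deterministic
#'   function of the scenario including this seed.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(preset = c("small", "study", "tiny"),
                         n_participants = NULL, n_days = NULL,
                         n_sensors = NULL,
                         domain_extent_m = c(10000, 10000),
                         outdoor = list(mean_level = 15, spatial_range_m = 3000,
                                        sill = 9, nugget = 0.5,
                                        diurnal_amp = 4, day_sd = 4),
                         urban_excess = 7,
                         corridor_halfwidth_m = 750,
                         infiltration = list(
                           house = c(0.65, 8.0),
                           office = c(0.45, 6.0),
                           educational_facility = c(0.45, 6.0),
                           transportation = c(0.60, 3.0),
                           other_indoor = c(0.50, 5.5)
                         ),
                         peak_process = list(rate_per_day = 2.5,
                                             magnitude_ugm3 = 140,
                                             decay_per_h = 1.5,
                                             room_fraction = 0.05),
                         sensor_noise_sd = 2,
                         monitor_noise_sd = 1.5,
                         indoor_noise_sd = 1.0,
                         start_date = as.Date("2023-01-09"),
                         rng_seed = 1L) {
  preset <- match.arg(preset)
  sizes <- switch(preset,
    small = c(5L, 7L, 50L),
    study = c(93L, 60L, 200L),
    tiny  = c(2L, 2L, 30L)
  )
  scn <- structure(list(
    preset = preset,
    n_participants = as.integer(n_participants %||% sizes[1]),
    n_days = as.integer(n_days %||% sizes[2]),
    n_sensors = as.integer(n_sensors %||% sizes[3]),
    domain_extent_m = as.numeric(domain_extent_m),
    outdoor = outdoor,
    urban_excess = as.numeric(urban_excess),
    corridor_halfwidth_m = as.numeric(corridor_halfwidth_m),
    infiltration = infiltration,
    peak_process = peak_process,
    sensor_noise_sd = as.numeric(sensor_noise_sd),
    monitor_noise_sd = as.numeric(monitor_noise_sd),
    indoor_noise_sd = as.numeric(indoor_noise_sd),
    start_date = as.Date(start_date),
    knot_spacing_m = 500,
    rng_seed = as.integer(rng_seed)
  ), class = "sim_scenario")
  validate_sim_scenario(scn)
  scn
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_sim_scenario <- function(scn) {
  stopifnot(
    scn$n_participants >= 1, scn$n_days >= 1, scn$n_sensors >= 1,
    all(scn$domain_extent_m > 0),
    scn$outdoor$sill >= scn$outdoor$nugget, scn$outdoor$nugget >= 0,
    scn$outdoor$spatial_range_m > 0,
    scn$peak_process$magnitude_ugm3 >= 0, scn$peak_process$rate_per_day >= 0,
    scn$peak_process$decay_per_h > 0,
    scn$peak_process$room_fraction >= 0, scn$peak_process$room_fraction <= 1,
    all(names(infiltration_labels()) %in% names(scn$infiltration)) ||
      all(infiltration_labels() %in% names(scn$infiltration))
  )
  invisible(scn)
}

infiltration_labels <- function() indoor_levels()

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("<sim_scenario> preset '%s': %d participants x %d days, %d sensors\n",
              x$preset, x$n_participants, x$n_days, x$n_sensors))
  cat(sprintf("  outdoor mean %g ug/m3, range %g m, urban excess +%g; seed %d\n",
              x$outdoor$mean_level, x$outdoor$spatial_range_m,
              x$urban_excess, x$rng_seed))
  invisible(x)
}

scenario_origin <- function(scn) {
  as.POSIXct(paste(scn$start_date, "00:00:00"), tz = "UTC")
}

in_corridor <- function(scn, y) {
  yc <- scn$domain_extent_m[2] / 2
  abs(y - yc) <= scn$corridor_halfwidth_m
}

#' Simulate the continuous outdoor PM2.5 field
#'
#' The field is the sum of a stationary spatial Gaussian random field
#' (spherical covariance, realized on a 500 m knot lattice and bilinearly
#' interpolated), a shared sinusoidal diurnal cycle, an iid Gaussian
#' between-day regional shift, and a constant urban excess inside the
#' commute corridor band; values are clipped at 0. The realization is a
#' deterministic function of the scenario seed, so repeated evaluation at
#' the same point and time returns identical values.
#'
#' @param scn A `sim_scenario`.
#' @return An object of class `outdoor_field`; evaluate with
#'   [field_value()].
#' @export
simulate_outdoor_field <- function(scn) {
  sp <- scn$knot_spacing_m
  xs <- seq(0, scn$domain_extent_m[1], by = sp)
  ys <- seq(0, scn$domain_extent_m[2], by = sp)
  kn <- expand.grid(x = xs, y = ys)
  psill <- scn$outdoor$sill - scn$outdoor$nugget
  knot_z <- with_seed(scn$rng_seed, {
    z <- numeric(nrow(kn))
    if (psill > 0) {
      D <- as.matrix(stats::dist(kn))
      u <- pmin(D / scn$outdoor$spatial_range_m, 1)
      Sigma <- psill * (1 - (1.5 * u - 0.5 * u^3))
      diag(Sigma) <- psill + scn$outdoor$nugget + 1e-8
      L <- chol(Sigma)
      z <- as.numeric(crossprod(L, stats::rnorm(nrow(kn))))
    } else if (scn$outdoor$nugget > 0) {
      z <- stats::rnorm(nrow(kn), sd = sqrt(scn$outdoor$nugget))
    }
    z
  })
  day_effects <- with_seed(scn$rng_seed + 1000L,
                           stats::rnorm(scn$n_days, 0, scn$outdoor$day_sd))
  structure(list(
    scn = scn, xs = xs, ys = ys,
    knot = matrix(knot_z, nrow = length(xs), ncol = length(ys)),
    day_effects = day_effects
  ), class = "outdoor_field")
}

#' Evaluate the simulated outdoor field
#'
#' @param field An `outdoor_field`.
#' @param x,y Coordinates in meters (vectorized).
#' @param t POSIXct times (recycled against coordinates).
#' @return PM2.5 concentrations (ug/m3), clipped at 0.
#' @export
field_value <- function(field, x, y, t) {
  scn <- field$scn
  n <- max(length(x), length(t))
  x <- rep_len(x, n); y <- rep_len(y, n); t <- rep_len(t, n)
  sp <- scn$knot_spacing_m
  xi <- pmin(pmax(x, 0), scn$domain_extent_m[1]) / sp
  yi <- pmin(pmax(y, 0), scn$domain_extent_m[2]) / sp
  i0 <- pmin(floor(xi), length(field$xs) - 2) + 1
  j0 <- pmin(floor(yi), length(field$ys) - 2) + 1
  fx <- xi - (i0 - 1); fy <- yi - (j0 - 1)
  k <- field$knot
  z <- (1 - fx) * (1 - fy) * k[cbind(i0, j0)] +
    fx * (1 - fy) * k[cbind(i0 + 1, j0)] +
    (1 - fx) * fy * k[cbind(i0, j0 + 1)] +
    fx * fy * k[cbind(i0 + 1, j0 + 1)]
  hours <- (as.numeric(t) %% 86400) / 3600
  diurnal <- scn$outdoor$diurnal_amp * sin(2 * pi * (hours - 8) / 24)
  day_idx <- floor(as.numeric(t - scenario_origin(scn), units = "days")) + 1
  day_idx <- pmin(pmax(day_idx, 1), length(field$day_effects))
  val <- scn$outdoor$mean_level + z + diurnal + field$day_effects[day_idx] +
    scn$urban_excess * in_corridor(scn, y)
  pmax(val, 0)
}

# ---- diary template --------------------------------------------------------

weekday_template <- function() {
  rep(c("house", "transportation", "office", "other_indoor", "office",
        "educational_facility", "outdoor", "other_indoor", "transportation",
        "house"),
      times = c(14, 1, 9, 1, 5, 2, 2, 4, 1, 9))
}

weekend_template <- function() {
  rep(c("house", "transportation", "outdoor", "other_indoor", "outdoor",
        "transportation", "other_indoor", "house"),
      times = c(17, 1, 3, 7, 2, 1, 3, 14))
}

diary_day_labels <- function(date) {
  wd <- as.POSIXlt(as.POSIXct(paste(date, "00:00:00"), tz = "UTC"))$wday
  if (wd %in% c(0, 6)) weekend_template() else weekday_template()
}

# cumulative peak signal (ug/m3) at times `t` from events at `t_ev` with
# initial magnitudes `mag` and exponential decay (per hour)
peak_signal <- function(t, t_ev, mag, decay_per_h) {
  if (length(t_ev) == 0) return(numeric(length(t)))
  dt_h <- outer(as.numeric(t), as.numeric(t_ev), "-") / 3600
  contrib <- exp(-decay_per_h * pmax(dt_h, 0)) * (dt_h >= 0)
  as.numeric(contrib %*% mag)
}

#' Simulate participants: diaries, GPS tracks, monitors, personal truth
#'
#' Each participant has a home in a residential (off-corridor) zone and a
#' workplace in the corridor. Diaries follow weekday/weekend templates
#' (about 12 h/day at home, 1.5 h/day outdoors); GPS tracks move between
#' home, workplace and a nearby outdoor area at 1-minute cadence. The home
#' monitor reads the infiltration baseline plus the full local peak signal
#' (it sits near indoor sources); the house microenvironment concentration
#' — and hence personal truth while at home — carries only `room_fraction`
#' of that peak signal. Personal truth at any time is the occupied
#' microenvironment's concentration.
#'
#' @param scn A `sim_scenario`.
#' @param field The matching `outdoor_field`.
#' @return List with tibbles `diary`, `track`, `home_monitor`, `personal`
#'   (truth), `homes`, and `home_baseline` (the source-free infiltration
#'   series underlying the home monitor, retained for diagnostics).
#' @export
simulate_participants <- function(scn, field) {
  origin <- scenario_origin(scn)
  yc <- scn$domain_extent_m[2] / 2
  W <- scn$domain_extent_m[1]
  ids <- sprintf("P%02d", seq_len(scn$n_participants))
  homes <- with_seed(scn$rng_seed + 2000L, {
    side <- rep_len(c(1, -1), scn$n_participants)
    tibble::tibble(
      participant_id = ids,
      x_m = stats::runif(scn$n_participants, 0.1 * W, 0.9 * W),
      y_m = yc + side * stats::runif(scn$n_participants,
                                     scn$corridor_halfwidth_m + 1000,
                                     scn$domain_extent_m[2] / 2 - 500)
    )
  })
  works <- with_seed(scn$rng_seed + 2001L, tibble::tibble(
    participant_id = ids,
    x_m = pmin(pmax(homes$x_m + stats::runif(scn$n_participants, -2000, 2000),
                    200), W - 200),
    y_m = yc + stats::runif(scn$n_participants,
                            -0.6 * scn$corridor_halfwidth_m,
                            0.6 * scn$corridor_halfwidth_m)
  ))
  parks <- tibble::tibble(
    participant_id = ids,
    x_m = pmin(pmax(works$x_m + 300, 200), W - 200),
    y_m = yc
  )

  dates <- scn$start_date + seq_len(scn$n_days) - 1
  slot_starts_day <- function(date) {
    as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + 1800 * (0:47)
  }

  diary <- dplyr::bind_rows(lapply(seq_along(ids), function(p) {
    dplyr::bind_rows(lapply(seq_along(dates), function(d) {
      tibble::tibble(participant_id = ids[p],
                     slot_start = slot_starts_day(dates[d]),
                     microenv = diary_day_labels(dates[d]))
    }))
  }))

  # per-minute positions driven by the diary labels
  track <- with_seed(scn$rng_seed + 3000L, {
    dplyr::bind_rows(lapply(seq_along(ids), function(p) {
      hx <- homes$x_m[p]; hy <- homes$y_m[p]
      wx <- works$x_m[p]; wy <- works$y_m[p]
      px <- parks$x_m[p]; py <- parks$y_m[p]
      dlab <- diary$microenv[diary$participant_id == ids[p]]
      slot_of_min <- rep(seq_along(dlab), each = 30)
      minutes <- origin + 60 * (seq_len(scn$n_days * 1440) - 1)
      lab <- dlab[slot_of_min]
      x <- numeric(length(lab)); y <- numeric(length(lab))
      at_home <- lab == "house"
      at_work <- lab %in% c("office", "educational_facility", "other_indoor")
      at_park <- lab == "outdoor"
      x[at_home] <- hx; y[at_home] <- hy
      x[at_work] <- wx; y[at_work] <- wy
      x[at_park] <- px; y[at_park] <- py
      moving <- which(lab == "transportation")
      if (length(moving) > 0) {
        prev_lab <- dlab[pmax(slot_of_min[moving] - 1, 1)]
        frac <- ((seq_along(lab) - 1) %% 30 + 0.5)[moving] / 30
        to_work <- prev_lab == "house"
        x[moving] <- ifelse(to_work, hx + frac * (wx - hx),
                            wx + frac * (hx - wx))
        y[moving] <- ifelse(to_work, hy + frac * (wy - hy),
                            wy + frac * (hy - wy))
      }
      jit <- ifelse(at_home, 10, ifelse(at_park, 50, 20))
      tibble::tibble(
        participant_id = ids[p], timestamp = minutes,
        x_m = pmin(pmax(x + stats::rnorm(length(x), 0, jit), 0), W),
        y_m = pmin(pmax(y + stats::rnorm(length(y), 0, jit), 0),
                   scn$domain_extent_m[2])
      )
    }))
  })

  # home monitor, room concentration and personal truth at 10-min cadence
  mon_times <- origin + 600 * (seq_len(scn$n_days * 144) - 1)
  pk <- scn$peak_process
  infl <- scn$infiltration

  per_participant <- with_seed(scn$rng_seed + 4000L, {
    lapply(seq_along(ids), function(p) {
      hx <- homes$x_m[p]; hy <- homes$y_m[p]
      dlab <- diary$microenv[diary$participant_id == ids[p]]
      slot_idx <- floor(as.numeric(mon_times - origin, units = "mins") / 30) + 1
      lab <- dlab[slot_idx]
      out_home <- field_value(field, hx, hy, mon_times)
      base_home <- infl$house[1] * out_home + infl$house[2]

      # peak events occur while someone is home
      home_min <- which(rep(dlab, each = 30) == "house")
      n_ev <- stats::rpois(scn$n_days, pk$rate_per_day)
      ev_idx <- if (sum(n_ev) > 0 && length(home_min) > 0) {
        unlist(lapply(seq_len(scn$n_days), function(d) {
          cand <- home_min[home_min > (d - 1) * 1440 & home_min <= d * 1440]
          if (length(cand) == 0 || n_ev[d] == 0) return(integer(0))
          sample(cand, n_ev[d], replace = TRUE)
        }))
      } else integer(0)
      t_ev <- origin + 60 * (ev_idx - 1)
      mag <- stats::rexp(length(t_ev), rate = 1 / pk$magnitude_ugm3)
      pk_sig <- peak_signal(mon_times, t_ev, mag, pk$decay_per_h)

      monitor <- pmax(base_home + pk_sig +
                        stats::rnorm(length(mon_times), 0,
                                     scn$monitor_noise_sd), 0)
      room <- pmax(base_home + pk$room_fraction * pk_sig, 0)

      # truth: concentration of the occupied microenvironment
      wx <- works$x_m[p]; wy <- works$y_m[p]
      px <- parks$x_m[p]; py <- parks$y_m[p]
      pos_x <- ifelse(lab == "house", hx,
                      ifelse(lab == "outdoor", px,
                             ifelse(lab == "transportation", (hx + wx) / 2, wx)))
      pos_y <- ifelse(lab == "house", hy,
                      ifelse(lab == "outdoor", py,
                             ifelse(lab == "transportation", (hy + wy) / 2, wy)))
      out_loc <- field_value(field, pos_x, pos_y, mon_times)
      truth <- room
      for (l in setdiff(indoor_levels(), "house")) {
        sel <- lab == l
        truth[sel] <- pmax(infl[[l]][1] * out_loc[sel] + infl[[l]][2], 0)
      }
      truth[lab == "outdoor"] <- out_loc[lab == "outdoor"]
      list(
        monitor = tibble::tibble(participant_id = ids[p],
                                 timestamp = mon_times, pm25 = monitor),
        baseline = tibble::tibble(participant_id = ids[p],
                                  timestamp = mon_times,
                                  pm25 = pmax(base_home, 0)),
        personal = tibble::tibble(participant_id = ids[p],
                                  timestamp = mon_times, pm25 = truth)
      )
    })
  })

  list(
    diary = diary,
    track = track,
    home_monitor = dplyr::bind_rows(lapply(per_participant, `[[`, "monitor")),
    home_baseline = dplyr::bind_rows(lapply(per_participant, `[[`, "baseline")),
    personal = dplyr::bind_rows(lapply(per_participant, `[[`, "personal")),
    homes = homes
  )
}

#' Simulate the sensor network
#'
#' Stations at seeded uniform locations report hourly PM2.5 (field value
#' plus Gaussian noise, clipped at 0) and PM10 (PM2.5 divided by a smoothly
#' varying PM2.5/PM10 ratio around 0.55).
#'
#' @param scn A `sim_scenario`.
#' @param field The matching `outdoor_field`.
#' @return A tibble in sensor-table schema.
#' @export
simulate_sensors <- function(scn, field) {
  origin <- scenario_origin(scn)
  hours <- origin + 3600 * (seq_len(scn$n_days * 24) - 1)
  with_seed(scn$rng_seed + 5000L, {
    sx <- stats::runif(scn$n_sensors, 0, scn$domain_extent_m[1])
    sy <- stats::runif(scn$n_sensors, 0, scn$domain_extent_m[2])
    dplyr::bind_rows(lapply(seq_len(scn$n_sensors), function(s) {
      pm25 <- pmax(field_value(field, sx[s], sy[s], hours) +
                     stats::rnorm(length(hours), 0, scn$sensor_noise_sd), 0)
      hfrac <- (as.numeric(hours) %% 86400) / 3600
      ratio <- pmin(pmax(0.55 + 0.08 * sin(2 * pi * (hfrac - 3) / 24) +
                           stats::rnorm(length(hours), 0, 0.02), 0.3), 0.9)
      tibble::tibble(
        station_id = sprintf("S%04d", s),
        x_m = sx[s], y_m = sy[s], timestamp = hours,
        pm25 = round(pm25, 3), pm10 = round(pm25 / ratio, 3)
      )
    }))
  })
}

#' Simulate hourly meteorology
#'
#' @param scn A `sim_scenario`.
#' @return A tibble in met-table schema.
#' @export
simulate_met <- function(scn) {
  origin <- scenario_origin(scn)
  hours <- origin + 3600 * (seq_len(scn$n_days * 24) - 1)
  with_seed(scn$rng_seed + 6000L, {
    hfrac <- (as.numeric(hours) %% 86400) / 3600
    day_idx <- floor(as.numeric(hours - origin, units = "days")) + 1
    t_day <- stats::rnorm(scn$n_days, 0, 3)
    temp <- 5 + 6 * sin(2 * pi * (hfrac - 9) / 24) + t_day[day_idx] +
      stats::rnorm(length(hours), 0, 0.5)
    wind <- pmax(stats::rnorm(length(hours), 2.5, 1), 0)
    rh <- pmin(pmax(60 - 1.5 * (temp - 5) + stats::rnorm(length(hours), 0, 5),
                    15), 98)
    wet <- stats::runif(length(hours)) < 0.06
    precip <- ifelse(wet, round(stats::rexp(length(hours), 1 / 2), 2), 0)
    tibble::tibble(timestamp = hours, temp_c = round(temp, 2),
                   wind_ms = round(wind, 2), rh_pct = round(rh, 1),
                   precip_mm = precip)
  })
}

#' Simulate source-free indoor reference series
#'
#' Hourly indoor PM2.5 at instrumented reference sites per microenvironment
#' label, generated from the infiltration relation without episodic indoor
#' sources. These series are the training data for the hourly indoor
#' prediction models: an hourly regression captures infiltration-driven
#' variation but, by construction, not minute-scale peak events — the
#' designed analogue of hourly indoor models missing short-term
#' high-concentration episodes.
#'
#' @param scn A `sim_scenario`.
#' @param field The matching `outdoor_field`.
#' @param n_sites Reference sites per label.
#' @return A tibble with columns `microenv, site_id, x_m, y_m, timestamp,
#'   pm25`.
#' @export
simulate_indoor_reference <- function(scn, field, n_sites = 3) {
  origin <- scenario_origin(scn)
  hours <- origin + 3600 * (seq_len(scn$n_days * 24) - 1)
  yc <- scn$domain_extent_m[2] / 2
  with_seed(scn$rng_seed + 7000L, {
    dplyr::bind_rows(lapply(indoor_levels(), function(l) {
      # house references sit in residential zones; workplace-type labels mix
      # corridor and residential sites
      ys <- if (l == "house") {
        yc + sample(c(-1, 1), n_sites, replace = TRUE) *
          stats::runif(n_sites, scn$corridor_halfwidth_m + 1000,
                       scn$domain_extent_m[2] / 2 - 500)
      } else {
        ifelse(seq_len(n_sites) %% 2 == 1,
               yc + stats::runif(n_sites, -0.5, 0.5) * scn$corridor_halfwidth_m,
               stats::runif(n_sites, 0, scn$domain_extent_m[2]))
      }
      xs <- stats::runif(n_sites, 0.1 * scn$domain_extent_m[1],
                         0.9 * scn$domain_extent_m[1])
      dplyr::bind_rows(lapply(seq_len(n_sites), function(s) {
        out <- field_value(field, xs[s], ys[s], hours)
        val <- pmax(scn$infiltration[[l]][1] * out + scn$infiltration[[l]][2] +
                      stats::rnorm(length(hours), 0, scn$indoor_noise_sd), 0)
        tibble::tibble(microenv = l, site_id = sprintf("%s_R%d", l, s),
                       x_m = xs[s], y_m = ys[s], timestamp = hours,
                       pm25 = round(val, 3))
      }))
    }))
  })
}

#' Generate and write a complete synthetic study dataset
#'
#' Writes the six study CSV kinds plus home locations and the indoor
#' reference series to `out_dir`: `sensors.csv`, `diary.csv`, `gps.csv`,
#' `home_monitor.csv`, `personal.csv`, `met.csv`, `homes.csv`,
#' `indoor_reference.csv`. Output is byte-identical for a fixed scenario
#' (including its seed).
#'
#' @param scn A `sim_scenario`.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of file paths, invisibly.
#' @export
simulate_study <- function(scn, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  field <- simulate_outdoor_field(scn)
  parts <- simulate_participants(scn, field)
  sensors <- simulate_sensors(scn, field)
  met <- simulate_met(scn)
  ref <- simulate_indoor_reference(scn, field)
  round_pm <- function(df) { df$pm25 <- round(df$pm25, 3); df }
  round_xy <- function(df) { df$x_m <- round(df$x_m, 2); df$y_m <- round(df$y_m, 2); df }
  paths <- c(
    sensors = file.path(out_dir, "sensors.csv"),
    diary = file.path(out_dir, "diary.csv"),
    gps = file.path(out_dir, "gps.csv"),
    home_monitor = file.path(out_dir, "home_monitor.csv"),
    personal = file.path(out_dir, "personal.csv"),
    met = file.path(out_dir, "met.csv"),
    homes = file.path(out_dir, "homes.csv"),
    indoor_reference = file.path(out_dir, "indoor_reference.csv")
  )
  write_table_csv(round_xy(sensors), paths[["sensors"]])
  write_table_csv(parts$diary, paths[["diary"]])
  write_table_csv(round_xy(parts$track), paths[["gps"]])
  write_table_csv(round_pm(parts$home_monitor), paths[["home_monitor"]])
  write_table_csv(round_pm(parts$personal), paths[["personal"]])
  write_table_csv(met, paths[["met"]])
  write_table_csv(round_xy(parts$homes), paths[["homes"]])
  write_table_csv(ref, paths[["indoor_reference"]])
  invisible(paths)
}
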