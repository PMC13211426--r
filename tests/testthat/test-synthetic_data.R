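flat_outdoor <- function(mean_level = 15) {
  list(mean_level = mean_level, spatial_range_m = 3000, sill = 0, nugget = 0,
       diurnal_amp = 0, day_sd = 0)
}

test_that("degenerate field parameters yield a constant field at mean level", {
  scn <- sim_scenario("tiny", outdoor = flat_outdoor(15), urban_excess = 0,
                      rng_seed = 1)
  f <- simulate_outdoor_field(scn)
  set.seed(1)
  v <- field_value(f, runif(50, 0, 10000), runif(50, 0, 10000),
                   ts0(h = sample(0:23, 50, replace = TRUE)))
  expect_equal(v, rep(15, 50))
})

test_that("field evaluation is deterministic for a fixed scenario seed", {
  scn <- sim_scenario("tiny", rng_seed = 99)
  f1 <- simulate_outdoor_field(scn)
  f2 <- simulate_outdoor_field(scn)
  x <- c(1234, 5678); y <- c(4321, 8765); t <- ts0(h = c(3, 17))
  expect_identical(field_value(f1, x, y, t), field_value(f2, x, y, t))
})

test_that("empirical variogram of sampled field points recovers the range", {
  ranges <- vapply(1:3, function(seed) {
    scn <- sim_scenario("small", n_sensors = 500, urban_excess = 0,
                        rng_seed = seed)
    f <- simulate_outdoor_field(scn)
    set.seed(seed + 100)
    x <- runif(1000, 0, 10000); y <- runif(1000, 0, 10000)
    v <- field_value(f, x, y, rep(ts0(h = 12), 1000))
    fit_variogram(tibble::tibble(x_m = x, y_m = y, value = v))$range_m
  }, numeric(1))
  expect_lt(abs(mean(ranges) - 3000) / 3000, 0.25)
})

test_that("without peaks and with unit infiltration the home monitor equals outdoor at home", {
  scn <- sim_scenario("tiny", outdoor = flat_outdoor(20),
                      infiltration = list(house = c(1, 0), office = c(1, 0),
                                          educational_facility = c(1, 0),
                                          transportation = c(1, 0),
                                          other_indoor = c(1, 0)),
                      peak_process = list(rate_per_day = 0, magnitude_ugm3 = 0,
                                          decay_per_h = 1, room_fraction = 0),
                      monitor_noise_sd = 0, rng_seed = 2)
  f <- simulate_outdoor_field(scn)
  parts <- simulate_participants(scn, f)
  hm <- parts$home_monitor[parts$home_monitor$participant_id == "P01", ]
  home <- parts$homes[parts$homes$participant_id == "P01", ]
  outdoor <- field_value(f, home$x_m, home$y_m, hm$timestamp)
  expect_equal(hm$pm25, outdoor)
})

test_that("personal truth equals the home monitor while at home (no peaks, no noise)", {
  scn <- sim_scenario("tiny",
                      peak_process = list(rate_per_day = 0, magnitude_ugm3 = 0,
                                          decay_per_h = 1, room_fraction = 0),
                      monitor_noise_sd = 0, rng_seed = 3)
  f <- simulate_outdoor_field(scn)
  parts <- simulate_participants(scn, f)
  p1 <- parts$personal[parts$personal$participant_id == "P01", ]
  hm <- parts$home_monitor[parts$home_monitor$participant_id == "P01", ]
  dlab <- parts$diary[parts$diary$participant_id == "P01", ]
  slot_idx <- findInterval(as.numeric(p1$timestamp),
                           as.numeric(dlab$slot_start))
  at_home <- dlab$microenv[slot_idx] == "house"
  expect_true(any(at_home))
  expect_equal(p1$pm25[at_home], hm$pm25[at_home])
})

test_that("home monitor exceeds the source-free baseline on most participant-days", {
  # the designed indoor-peak bias: measured home series above the
  # infiltration-only series that hourly indoor models can capture
  frac_above <- unlist(lapply(1:20, function(seed) {
    scn <- sim_scenario("tiny", rng_seed = seed)
    f <- simulate_outdoor_field(scn)
    parts <- simulate_participants(scn, f)
    jt <- dplyr::inner_join(
      parts$home_monitor,
      dplyr::rename(parts$home_baseline, base = "pm25"),
      by = c("participant_id", "timestamp"))
    jt$date <- as.Date(jt$timestamp)
    agg <- stats::aggregate(cbind(pm25, base) ~ participant_id + date,
                            data = jt, FUN = mean)
    agg$pm25 > agg$base
  }))
  expect_gte(mean(frac_above), 0.8)
})

test_that("GPS-visited outdoor locations are dirtier than home cells when urban excess is on", {
  scn <- sim_scenario("tiny", rng_seed = 4)
  f <- simulate_outdoor_field(scn)
  parts <- simulate_participants(scn, f)
  dlab <- parts$diary
  trk <- parts$track
  slot_of <- as.POSIXct(floor(as.numeric(trk$timestamp) / 1800) * 1800,
                        origin = "1970-01-01", tz = "UTC")
  key <- paste(dlab$participant_id, format(dlab$slot_start, "%Y-%m-%d %H:%M"))
  trk$lab <- dlab$microenv[match(
    paste(trk$participant_id, format(slot_of, "%Y-%m-%d %H:%M")), key)]
  out_fix <- trk[trk$lab == "outdoor", ]
  c_gps <- field_value(f, out_fix$x_m, out_fix$y_m, out_fix$timestamp)
  homes <- parts$homes
  c_home <- unlist(lapply(seq_len(nrow(homes)), function(i)
    field_value(f, homes$x_m[i], homes$y_m[i], unique(out_fix$timestamp))))
  expect_gt(mean(c_gps), mean(c_home))
})

test_that("a fixed seed reproduces byte-identical study files", {
  scn <- sim_scenario("tiny", rng_seed = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- simulate_study(scn, d1)
  p2 <- simulate_study(scn, d2)
  for (k in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[k]])),
                     unname(tools::md5sum(p2[[k]])), label = k)
  }
})

test_that("all emitted tables pass schema validation with no rejections", {
  scn <- sim_scenario("tiny", rng_seed = 6)
  dir <- withr::local_tempdir()
  paths <- simulate_study(scn, dir)
  expect_equal(nrow(rejections(read_sensor_table(paths[["sensors"]]))), 0)
  expect_equal(nrow(rejections(read_diary(paths[["diary"]]))), 0)
  expect_equal(nrow(rejections(read_track(paths[["gps"]]))), 0)
  expect_equal(nrow(rejections(read_monitor_series(paths[["home_monitor"]]))), 0)
  expect_equal(nrow(rejections(read_monitor_series(paths[["personal"]]))), 0)
  expect_equal(nrow(rejections(read_met(paths[["met"]]))), 0)
})

test_that("scenario invariants are validated", {
  expect_error(sim_scenario("tiny", n_participants = 0))
  expect_error(sim_scenario("tiny", outdoor = list(
    mean_level = 15, spatial_range_m = 3000, sill = 1, nugget = 2,
    diurnal_amp = 0, day_sd = 0)))
})
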