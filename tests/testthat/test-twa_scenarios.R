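test_that("twa reduces correctly in degenerate cases", {
  expect_equal(twa(17.3, 5), 17.3)                      # single pair
  expect_equal(twa(c(4, 8, 12), c(2, 2, 2)), 8)         # equal weights -> mean
  expect_error(twa(c(1, 2), c(0, 0)), "undefined")
  expect_error(twa(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("twa matches hand arithmetic on the fixed-time two-term day", {
  # (26.48 * 15.86 + 15.30 * 3.34) / 19.2, computed independently
  oracle <- (26.48 * 15.86 + 15.30 * 3.34) / (15.86 + 3.34)
  expect_equal(twa(c(26.48, 15.30), c(15.86, 3.34)), oracle)
  expect_equal(round(oracle, 1), 24.5)
  expect_equal(scenario_s1(26.48, 15.30), oracle)
})

test_that("scenario S1 handles identical and zero inputs", {
  expect_equal(scenario_s1(10, 10), 10)
  expect_equal(scenario_s1(0, 12), 12 * 3.34 / 19.2)
  expect_true(is.na(scenario_s1(NA, 12)))
})

test_that("scenario S2 equals the slot-level brute-force weighted mean", {
  # 12 h house at 30, 2 h outdoor at 10, remainder office (excluded)
  labels <- c(rep("house", 24), rep("outdoor", 4), rep("office", 20))
  occ <- random_occupancy(1)
  occ$microenv <- labels
  occ$c_outdoor_gps <- 10
  hm <- monitor_from_values(rep(30, 144))
  s2 <- scenario_s2(occ, hm)
  expect_equal(s2$s2, (30 * 12 + 10 * 2) / 14)

  # random fixture vs independent slot-resolution oracle
  occ2 <- random_occupancy(21)
  hm2 <- monitor_from_values(runif(144, 5, 60))
  hm_slot <- vapply(occ2$slot_start, function(s) {
    mean(hm2$pm25[hm2$timestamp >= s & hm2$timestamp < s + 1800])
  }, numeric(1))
  keep_h <- occ2$microenv == "house"
  keep_o <- occ2$microenv == "outdoor"
  oracle <- (sum(hm_slot[keep_h] * 0.5) + sum(occ2$c_outdoor_gps[keep_o] * 0.5)) /
    ((sum(keep_h) + sum(keep_o)) * 0.5)
  expect_equal(scenario_s2(occ2, hm2)$s2, oracle)

  # all-house day -> daily mean of the home monitor
  occ3 <- random_occupancy(3)
  occ3$microenv <- rep("house", 48)
  expect_equal(scenario_s2(occ3, hm2)$s2, mean(hm_slot))
})

test_that("scenario S3 equals the generic TWA applied to the slot table", {
  occ <- random_occupancy(4)
  occ$c_indoor_pred <- runif(48, 5, 25)
  cfg <- study_config()
  s3 <- scenario_s3(occ, cfg)
  conc <- ifelse(occ$microenv == "outdoor", occ$c_outdoor_gps,
                 occ$c_indoor_pred)
  expect_equal(s3$s3, twa(conc, rep(0.5, 48)))

  # two-label arithmetic: 20 h house at 14, 4 h outdoor at 22
  occ2 <- random_occupancy(5)
  occ2$microenv <- c(rep("house", 40), rep("outdoor", 8))
  occ2$c_indoor_pred <- 14
  occ2$c_outdoor_gps <- 22
  expect_equal(scenario_s3(occ2, cfg)$s3, (14 * 20 + 22 * 4) / 24)

  # constant prediction everywhere -> that constant
  occ3 <- random_occupancy(6)
  occ3$c_indoor_pred <- 9
  occ3$c_outdoor_gps <- 9
  expect_equal(scenario_s3(occ3, cfg)$s3, 9)
})

test_that("scenario S3 excludes days with a missing label prediction", {
  occ <- random_occupancy(7)
  occ$c_indoor_pred <- ifelse(occ$microenv == "office", NA_real_,
                              runif(48, 5, 25))
  expect_true(is.na(scenario_s3(occ, study_config())$s3))
})

test_that("transportation routing to outdoor is a config switch", {
  occ <- random_occupancy(8)
  occ$microenv <- c(rep("house", 40), rep("transportation", 8))
  occ$c_indoor_pred <- 10
  occ$c_outdoor_gps <- 40
  s3_indoor <- scenario_s3(occ, study_config(transport_outdoor = FALSE))$s3
  s3_outdoor <- scenario_s3(occ, study_config(transport_outdoor = TRUE))$s3
  expect_equal(s3_indoor, 10)
  expect_equal(s3_outdoor, (10 * 20 + 40 * 4) / 24)
})

test_that("scenario outputs are bounded by their input concentrations and scale linearly", {
  cfg <- study_config()
  for (seed in 1:10) {
    occ <- random_occupancy(seed + 100)
    occ$c_indoor_pred <- runif(48, 2, 50)
    hm <- monitor_from_values(runif(144, 2, 60))
    s2 <- scenario_s2(occ, hm, cfg)$s2
    s3 <- scenario_s3(occ, cfg)$s3
    inputs_s3 <- ifelse(occ$microenv == "outdoor", occ$c_outdoor_gps,
                        occ$c_indoor_pred)
    expect_gte(s3, min(inputs_s3)); expect_lte(s3, max(inputs_s3))
    expect_gte(s2, min(c(hm$pm25, occ$c_outdoor_gps)))
    expect_lte(s2, max(c(hm$pm25, occ$c_outdoor_gps)))
    # scale equivariance
    k <- 3.7
    occ_k <- occ
    occ_k$c_indoor_pred <- occ_k$c_indoor_pred * k
    occ_k$c_outdoor_gps <- occ_k$c_outdoor_gps * k
    hm_k <- hm; hm_k$pm25 <- hm_k$pm25 * k
    expect_equal(scenario_s2(occ_k, hm_k, cfg)$s2, k * s2)
    expect_equal(scenario_s3(occ_k, cfg)$s3, k * s3)
    expect_equal(twa(inputs_s3 * k, rep(0.5, 48)),
                 k * twa(inputs_s3, rep(0.5, 48)))
  }
})

test_that("measured daily means follow the minute-weighted brute force", {
  expect_equal(measured_daily(monitor_from_values(rep(11, 144)))$measured, 11)
  half <- monitor_from_values(c(rep(10, 72), rep(20, 72)))
  expect_equal(measured_daily(half)$measured, 15)

  # gap-laden series vs brute force over present samples
  set.seed(31)
  vals <- runif(144, 3, 40)
  keep <- sort(sample(144, 130))
  gappy <- monitor_from_values(vals)[keep, ]
  got <- measured_daily(gappy)
  expect_equal(got$measured, mean(vals[keep]))

  # insufficient coverage (< 18 h) excludes the day
  short <- monitor_from_values(runif(100, 3, 40))  # ~16.7 h at 10-min cadence
  expect_true(is.na(measured_daily(short)$measured))
})
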