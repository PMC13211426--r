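make_track <- function(x, y, start = ts0(h = 8), id = "P01") {
  tibble::tibble(participant_id = id,
                 timestamp = start + 60 * (seq_along(x) - 1),
                 x_m = x, y_m = y)
}

test_that("a stationary track on a constant grid yields a constant series", {
  stack <- constant_stack(12)
  trk <- make_track(rep(750, 60), rep(750, 60))
  matched <- match_track_to_grid(trk, stack)
  expect_equal(matched$value, rep(12, 60))
  slots <- slot_average(matched)
  expect_equal(slots$value, c(12, 12))
})

test_that("a slot split across two cells averages their concentrations", {
  stack <- patterned_stack(function(col, row, k) if (col == 1) 10 else 20)
  # 30 fixes: 15 minutes in column 1, 15 in column 2
  trk <- make_track(c(rep(250, 15), rep(750, 15)), rep(250, 30))
  slots <- slot_average(match_track_to_grid(trk, stack))
  expect_equal(slots$value, 15)
})

test_that("vectorized matching equals a per-fix brute-force lookup", {
  stack <- patterned_stack(function(col, row, k) col * 10 + row + k,
                           n_hours = 6)
  set.seed(11)
  trk <- make_track(runif(120, 0, 1999), runif(120, 0, 1999),
                    start = ts0(h = 1, m = 17))
  matched <- match_track_to_grid(trk, stack)
  for (i in seq_len(nrow(trk))) {
    cell <- lookup_cell(stack$geom, trk$x_m[i], trk$y_m[i])
    dt <- abs(as.numeric(stack$times) - as.numeric(trk$timestamp[i]))
    k <- which(dt == min(dt))[1]  # ties -> earlier time
    expect_equal(matched$value[i], stack$values[cell$row, cell$col, k])
  }
})

test_that("out-of-extent fixes are clamped to boundary cells and counted", {
  stack <- constant_stack(8, n_cols = 2, n_rows = 2)
  trk <- make_track(c(-100, 500), c(500, 500))
  expect_message(matched <- match_track_to_grid(trk, stack), "1 fix")
  expect_equal(attr(matched, "n_clamped"), 1)
  expect_equal(matched$value, c(8, 8))
})

test_that("home-cell series is constant on a constant field and matches a permanently-home track", {
  stack <- constant_stack(12)
  hs <- home_cell_series(c(750, 750), stack)
  expect_equal(unique(hs$value), 12)
  expect_equal(nrow(hs), 48)

  stack2 <- patterned_stack(function(col, row, k) col + row * 5 + k)
  hs2 <- home_cell_series(c(1250, 750), stack2)
  trk <- make_track(rep(1250, 1440), rep(750, 1440), start = ts0())
  via_track <- slot_average(match_track_to_grid(trk, stack2))
  expect_equal(hs2$value, via_track$value)

  # manual lookups at three fixture timestamps
  for (h in c(0, 7, 23)) {
    expect_equal(hs2$value[hs2$slot_start == ts0(h = h)],
                 stack2$values[2, 3, h + 1])
  }
})

test_that("occupancy joins diary labels with concentrations slot by slot", {
  labels <- c(rep("house", 46), rep("outdoor", 2))
  diary <- diary_from_labels(labels)
  gps <- tibble::tibble(participant_id = "P01",
                        slot_start = ts0() + 1800 * (0:47),
                        value = seq(10, 10 + 47))
  home <- tibble::tibble(participant_id = "P01",
                         slot_start = ts0() + 1800 * (0:47), value = 9)
  occ <- build_occupancy(diary, gps, home)
  hrs <- occupancy_hours(occ)
  expect_equal(hrs$h_outdoor, 1.0)
  expect_equal(hrs$h_house, 23.0)
  expect_equal(hrs$gap_h, 0)
  # manual join oracle on a handful of slots
  expect_equal(occ$c_outdoor_gps[occ$slot_start == ts0(h = 5)], 20)
  expect_equal(occ$microenv[occ$slot_start == ts0(h = 23, m = 30)], "outdoor")
  expect_equal(unique(occ$c_outdoor_home), 9)

  all_house <- build_occupancy(diary_from_labels(rep("house", 48)), gps, home)
  expect_equal(sum(all_house$microenv == "outdoor"), 0)
})

test_that("slot accounting always totals 24 hours per participant-day", {
  labels <- rep("house", 48)
  diary <- diary_from_labels(labels)[-c(5, 6, 20), ]  # 1.5 h of gaps
  gps <- tibble::tibble(participant_id = "P01",
                        slot_start = ts0() + 1800 * (0:47), value = 10)
  occ <- build_occupancy(diary, gps, gps)
  hrs <- occupancy_hours(occ)
  lab_h <- sum(hrs[paste0("h_", microenv_levels())])
  expect_equal(lab_h + hrs$gap_h, 24)
})

test_that("small diary gaps inherit the previous label; large gaps exclude the day", {
  labels <- c(rep("house", 16), rep("office", 16), rep("house", 16))
  # 2-hour gap inside the office block
  diary <- diary_from_labels(labels)[-(20:23), ]
  gps <- tibble::tibble(participant_id = "P01",
                        slot_start = ts0() + 1800 * (0:47), value = 10)
  occ <- build_occupancy(diary, gps, gps)
  expect_false(any(occ$day_excluded))
  expect_equal(occ$microenv[20:23], rep("office", 4))
  expect_true(all(occ$imputed[20:23]))

  # > 4 h of gaps: day flagged excluded, labels left missing
  diary2 <- diary_from_labels(labels)[-(20:29), ]
  occ2 <- build_occupancy(diary2, gps, gps)
  expect_true(all(occ2$day_excluded))
  expect_true(all(is.na(occ2$microenv[20:29])))
})
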