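test_that("variogram fit degenerates gracefully on constant data", {
  set.seed(1)
  obs <- tibble::tibble(x_m = runif(20, 0, 5000), y_m = runif(20, 0, 5000),
                        value = 7)
  vg <- fit_variogram(obs)
  expect_lt(vg$sill, 1e-10)
})

test_that("variogram fit refuses tiny snapshots", {
  obs <- tibble::tibble(x_m = c(0, 100), y_m = c(0, 0), value = c(1, 2))
  expect_error(fit_variogram(obs), "fewer than 10 stations")
})

test_that("variogram recovers the generating spherical range within 25%", {
  ranges <- vapply(1:3, function(seed) {
    set.seed(seed)
    n <- 500
    x <- runif(n, 0, 8000); y <- runif(n, 0, 8000)
    D <- as.matrix(stats::dist(cbind(x, y)))
    u <- pmin(D / 2000, 1)
    Sigma <- 24 * (1 - (1.5 * u - 0.5 * u^3))
    diag(Sigma) <- 25 + 1e-8
    z <- 15 + as.numeric(crossprod(chol(Sigma), rnorm(n)))
    fit_variogram(tibble::tibble(x_m = x, y_m = y, value = z))$range_m
  }, numeric(1))
  expect_lt(abs(mean(ranges) - 2000) / 2000, 0.25)
})

test_that("3-station kriging matches the directly solved OK system", {
  # brute-force oracle: assemble and solve the 4x4 system by hand
  obs <- tibble::tibble(x_m = c(0, 1000, 400), y_m = c(0, 0, 800),
                        value = c(10, 20, 14))
  vg <- structure(list(model_form = "spherical", nugget = 0.5, psill = 9,
                       sill = 9.5, range_m = 1500), class = "variogram_model")
  g <- function(h) ifelse(h == 0, 0,
    0.5 + 9 * ifelse(h >= 1500, 1, 1.5 * h / 1500 - 0.5 * (h / 1500)^3))
  p <- c(300, 300)
  d <- function(a, b) sqrt(sum((a - b)^2))
  pts <- rbind(c(0, 0), c(1000, 0), c(400, 800))
  A <- matrix(0, 4, 4)
  for (i in 1:3) for (j in 1:3) A[i, j] <- g(d(pts[i, ], pts[j, ]))
  A[4, 1:3] <- 1; A[1:3, 4] <- 1
  b <- c(g(d(pts[1, ], p)), g(d(pts[2, ], p)), g(d(pts[3, ], p)), 1)
  lambda <- solve(A, b)[1:3]
  oracle <- sum(lambda * obs$value)

  pred <- krige_points(obs, vg, p[1], p[2])
  expect_equal(as.numeric(pred), oracle, tolerance = 1e-10)
  expect_equal(as.numeric(attr(pred, "weights")), lambda, tolerance = 1e-10)
})

test_that("kriging reproduces a constant field and sums weights to 1", {
  set.seed(3)
  obs <- tibble::tibble(x_m = runif(15, 0, 2000), y_m = runif(15, 0, 2000),
                        value = 9.5)
  vg <- structure(list(model_form = "spherical", nugget = 1, psill = 4,
                       sill = 5, range_m = 900), class = "variogram_model")
  geom <- grid_geometry(0, 0, 500, 4, 4)
  gf <- krige_grid(obs, vg, geom)
  expect_true(all(abs(gf$values - 9.5) < 1e-8))

  cc <- cell_centers(geom)
  pred <- krige_points(obs, vg, cc$x_center, cc$y_center)
  w <- attr(pred, "weights")
  expect_true(all(abs(rowSums(w, na.rm = TRUE) - 1) < 1e-8))
})

test_that("with zero nugget the predictor interpolates observations exactly", {
  set.seed(4)
  obs <- tibble::tibble(x_m = runif(12, 0, 2000), y_m = runif(12, 0, 2000),
                        value = runif(12, 5, 30))
  vg <- structure(list(model_form = "spherical", nugget = 0, psill = 8,
                       sill = 8, range_m = 1200), class = "variogram_model")
  pred <- krige_points(obs, vg, obs$x_m, obs$y_m)
  expect_equal(as.numeric(pred), obs$value, tolerance = 1e-6)
})

test_that("kriging is equivariant under adding a constant (unbiasedness)", {
  set.seed(5)
  obs <- tibble::tibble(x_m = runif(20, 0, 3000), y_m = runif(20, 0, 3000),
                        value = runif(20, 5, 25))
  vg <- structure(list(model_form = "spherical", nugget = 0.5, psill = 6,
                       sill = 6.5, range_m = 1000), class = "variogram_model")
  px <- runif(10, 0, 3000); py <- runif(10, 0, 3000)
  p1 <- krige_points(obs, vg, px, py)
  obs2 <- obs; obs2$value <- obs2$value + 100
  p2 <- krige_points(obs2, vg, px, py)
  expect_equal(as.numeric(p2), as.numeric(p1) + 100, tolerance = 1e-8)
})

test_that("duplicate station coordinates are averaged, not fatal", {
  obs <- tibble::tibble(x_m = c(0, 0, 1000, 500), y_m = c(0, 0, 0, 800),
                        value = c(10, 14, 20, 16))
  vg <- structure(list(model_form = "spherical", nugget = 0, psill = 5,
                       sill = 5, range_m = 1000), class = "variogram_model")
  expect_message(p <- krige_points(obs, vg, 0, 0), "duplicate")
  expect_equal(as.numeric(p), 12)  # exact interpolation of the averaged pair
})

test_that("cell lookup follows the half-open boundary convention", {
  geom <- grid_geometry(0, 0, 500, 4, 4)
  expect_equal(lookup_cell(geom, 0, 0)$col, 1L)
  expect_equal(lookup_cell(geom, 500, 0)$col, 2L)   # x0 + cell_size -> col 2
  expect_equal(lookup_cell(geom, 499.999, 0)$col, 1L)
  expect_error(lookup_cell(geom, -1, 0), "outside")
  clamped <- lookup_cell(geom, -1, 5000, clamp = TRUE)
  expect_equal(c(clamped$col, clamped$row), c(1L, 4L))
})

test_that("vectorized cell lookup matches an exhaustive per-cell scan", {
  geom <- grid_geometry(-250, 100, 500, 6, 5)
  set.seed(6)
  x <- runif(200, -250, -250 + 6 * 500 - 1e-6)
  y <- runif(200, 100, 100 + 5 * 500 - 1e-6)
  got <- lookup_cell(geom, x, y)
  # oracle: scan every cell for half-open membership
  for (k in seq_len(200)) {
    hit <- NULL
    for (cc in 1:6) for (rr in 1:5) {
      xlo <- geom$x0 + (cc - 1) * 500; ylo <- geom$y0 + (rr - 1) * 500
      if (x[k] >= xlo && x[k] < xlo + 500 && y[k] >= ylo && y[k] < ylo + 500) {
        hit <- c(cc, rr)
      }
    }
    expect_equal(c(got$col[k], got$row[k]), hit)
  }
})

test_that("hourly kriging averages sub-hourly readings first", {
  # two readings per hour per station; the kriged constant must match the
  # hourly station mean, not either raw reading
  set.seed(7)
  st <- tibble::tibble(x = runif(12, 0, 2000), y = runif(12, 0, 2000))
  sensors <- dplyr::bind_rows(lapply(1:12, function(i) tibble::tibble(
    station_id = sprintf("S%02d", i), x_m = st$x[i], y_m = st$y[i],
    timestamp = ts0() + c(0, 1800), pm25 = c(8, 12), pm10 = c(16, 24)
  )))
  class(sensors) <- c("sensor_table", class(sensors))
  geom <- grid_geometry(0, 0, 500, 4, 4)
  stack <- krige_sensor_hours(sensors, geom)
  expect_equal(length(stack$times), 1)
  expect_true(all(abs(stack$values - 10) < 1e-6))
})
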