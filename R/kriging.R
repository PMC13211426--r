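#' Spherical semivariogram function
#'
#' \eqn{\gamma(h) = n + p\,(1.5 h/r - 0.5 (h/r)^3)} for \eqn{0 < h < r},
#' \eqn{n + p} for \eqn{h \ge r}, and 0 at \eqn{h = 0} (so kriging is an
#' exact interpolator at station locations).
#'
#' @param h Distances (meters), non-negative.
#' @param nugget Nugget variance.
#' @param psill Partial sill (sill - nugget).
#' @param range_m Range (meters).
#' @return Semivariance values.
#' @export
spherical_gamma <- function(h, nugget, psill, range_m) {
  u <- pmin(h / range_m, 1)
  g <- nugget + psill * (1.5 * u - 0.5 * u^3)
  g[h == 0] <- 0
  g
}

#' Empirical semivariogram (Matheron estimator)
#'
#' Bins station pairs by separation distance and computes half the mean
#' squared difference per bin.
#'
#' @param x,y Planar station coordinates (meters).
#' @param value Observed values at the stations.
#' @param n_bins Number of distance bins.
#' @param cutoff Maximum pair distance considered; defaults to half the
#'   maximum separation.
#' @return A tibble with columns `dist` (bin mean distance), `gamma`
#'   (semivariance) and `n` (pair count); empty bins are dropped.
#' @export
empirical_variogram <- function(x, y, value, n_bins = 12, cutoff = NULL) {
  stopifnot(length(x) == length(y), length(x) == length(value))
  d <- as.matrix(stats::dist(cbind(x, y)))
  iu <- upper.tri(d)
  h <- d[iu]
  sq <- (outer(value, value, "-")^2)[iu]
  if (is.null(cutoff)) cutoff <- max(h) / 2
  keep <- h <= cutoff & h > 0
  h <- h[keep]; sq <- sq[keep]
  bins <- cut(h, breaks = seq(0, cutoff, length.out = n_bins + 1),
              include.lowest = TRUE)
  tibble::tibble(
    dist = as.numeric(tapply(h, bins, mean)),
    gamma = as.numeric(tapply(sq, bins, mean)) / 2,
    n = as.integer(tapply(sq, bins, length))
  ) |> tidyr::drop_na()
}

# Weighted least squares of (nugget, psill) for a fixed range: the spherical
# model is linear in both, so solve the 2x2 normal equations and clamp to the
# feasible cone (nugget >= 0, psill >= 0).
fit_ns_given_range <- function(ev, range_m) {
  g <- spherical_gamma(ev$dist, 0, 1, range_m)
  w <- ev$n
  X <- cbind(1, g)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * ev$gamma)
  beta <- tryCatch(solve(XtWX, XtWy), error = function(e) c(0, 0))
  nugget <- beta[1]; psill <- beta[2]
  if (nugget < 0) {
    nugget <- 0
    psill <- max(0, sum(w * g * ev$gamma) / sum(w * g^2))
  }
  if (psill < 0) {
    psill <- 0
    nugget <- max(0, sum(w * ev$gamma) / sum(w))
  }
  resid <- ev$gamma - spherical_gamma(ev$dist, nugget, psill, range_m)
  # spherical_gamma() zeroes h == 0, which never occurs in binned data
  list(nugget = nugget, psill = psill, wss = sum(w * resid^2))
}

#' Fit a spherical variogram model to a station snapshot
#'
#' Computes the Matheron empirical semivariogram and fits nugget, partial
#' sill, and range by weighted least squares (pair-count weights). The
#' spherical model is linear in nugget and partial sill given the range, so
#' the fit profiles over a range grid and polishes the best value with a
#' one-dimensional optimizer.
#'
#' @param obs A data frame with columns `x_m`, `y_m`, `value` — one row per
#'   station at a single time snapshot.
#' @param n_bins Number of distance bins for the empirical variogram.
#' @return An object of class `variogram_model` with fields `model_form`,
#'   `nugget`, `psill`, `sill` (= nugget + psill), `range_m`, and the
#'   empirical variogram used for the fit.
#' @export
fit_variogram <- function(obs, n_bins = 12) {
  obs <- obs[is.finite(obs$value), , drop = FALSE]
  if (nrow(obs) < 10) {
    stop("fit_variogram: fewer than 10 stations with finite values; ",
         "widen the time window", call. = FALSE)
  }
  ev <- empirical_variogram(obs$x_m, obs$y_m, obs$value, n_bins = n_bins)
  if (nrow(ev) < 3 || all(ev$gamma < 1e-12)) {
    # flat variogram: constant field
    vg <- list(model_form = "spherical", nugget = 0, psill = 0, sill = 0,
               range_m = max(ev$dist, 1), empirical = ev)
    class(vg) <- "variogram_model"
    return(vg)
  }
  r_grid <- exp(seq(log(min(ev$dist)), log(2 * max(ev$dist)), length.out = 25))
  wss <- vapply(r_grid, function(r) fit_ns_given_range(ev, r)$wss, numeric(1))
  best <- which.min(wss)
  lo <- r_grid[max(1, best - 1)]; hi <- r_grid[min(length(r_grid), best + 1)]
  opt <- stats::optimize(function(r) fit_ns_given_range(ev, r)$wss,
                         lower = lo, upper = hi)
  range_m <- opt$minimum
  ns <- fit_ns_given_range(ev, range_m)
  vg <- list(model_form = "spherical", nugget = ns$nugget, psill = ns$psill,
             sill = ns$nugget + ns$psill, range_m = range_m, empirical = ev)
  class(vg) <- "variogram_model"
  vg
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model> %s: nugget %.3g, partial sill %.3g, range %.0f m\n",
              x$model_form, x$nugget, x$psill, x$range_m))
  invisible(x)
}

#' Regular grid geometry
#'
#' Cell `(col, row)` (1-based) covers the half-open square
#' \eqn{[x_0+(col-1)s,\; x_0+col\,s) \times [y_0+(row-1)s,\; y_0+row\,s)}.
#'
#' @param x0,y0 Grid origin (lower-left corner), meters.
#' @param cell_size_m Cell side length, meters (500 by default).
#' @param n_cols,n_rows Grid dimensions.
#' @return An object of class `grid_geom`.
#' @export
grid_geometry <- function(x0, y0, cell_size_m = 500, n_cols, n_rows) {
  stopifnot(cell_size_m > 0, n_cols >= 1, n_rows >= 1)
  structure(list(x0 = x0, y0 = y0, cell_size_m = cell_size_m,
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows)),
            class = "grid_geom")
}

#' Cell centers of a grid geometry
#'
#' @param geom A `grid_geom`.
#' @return Tibble with `col`, `row`, `x_center`, `y_center`.
#' @export
cell_centers <- function(geom) {
  g <- expand.grid(col = seq_len(geom$n_cols), row = seq_len(geom$n_rows))
  tibble::tibble(
    col = g$col, row = g$row,
    x_center = geom$x0 + (g$col - 0.5) * geom$cell_size_m,
    y_center = geom$y0 + (g$row - 0.5) * geom$cell_size_m
  )
}

dedupe_stations <- function(obs) {
  key <- paste(obs$x_m, obs$y_m)
  if (!anyDuplicated(key)) return(obs)
  out <- obs |>
    dplyr::group_by(.data$x_m, .data$y_m) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  message(sprintf("kriging: %d duplicate station location(s) averaged",
                  nrow(obs) - nrow(out)))
  out
}

#' Ordinary-kriging prediction at arbitrary points
#'
#' Solves the ordinary-kriging system (semivariogram form, weights
#' constrained to sum to 1 via a Lagrange multiplier) for each prediction
#' point. When more than `max_neighbors` stations are available, each point
#' uses its `max_neighbors` nearest stations.
#'
#' @param obs Data frame with `x_m`, `y_m`, `value` (one time snapshot);
#'   duplicate station locations are averaged with a message.
#' @param vg A fitted `variogram_model`.
#' @param x,y Prediction coordinates.
#' @param max_neighbors Neighborhood size bound.
#' @return Numeric predictions; the kriging weights are attached as a
#'   `weights` attribute (points in rows, stations in columns; `NA` for
#'   stations outside a point's neighborhood).
#' @export
krige_points <- function(obs, vg, x, y, max_neighbors = 64) {
  obs <- dedupe_stations(obs[is.finite(obs$value), , drop = FALSE])
  n <- nrow(obs)
  if (n < 3) stop("krige_points: need at least 3 stations", call. = FALSE)
  m <- length(x)
  gamma_fun <- function(h) spherical_gamma(h, vg$nugget, vg$psill, vg$range_m)
  if (vg$sill <= 0) {
    # degenerate flat variogram: every weight pattern yields the same BLUP;
    # use the simple average (all weights equal), which reproduces constants
    pred <- rep(mean(obs$value), m)
    w <- matrix(1 / n, nrow = m, ncol = n)
    attr(pred, "weights") <- w
    return(pred)
  }
  preds <- numeric(m)
  wmat <- matrix(NA_real_, nrow = m, ncol = n)
  if (n <= max_neighbors) {
    D <- as.matrix(stats::dist(cbind(obs$x_m, obs$y_m)))
    A <- rbind(cbind(gamma_fun(D), 1), c(rep(1, n), 0))
    d0 <- sqrt(outer(x, obs$x_m, "-")^2 + outer(y, obs$y_m, "-")^2)
    B <- rbind(t(gamma_fun(d0)), rep(1, m))
    sol <- solve(A, B)
    wmat <- t(sol[seq_len(n), , drop = FALSE])
    preds <- as.numeric(wmat %*% obs$value)
  } else {
    for (k in seq_len(m)) {
      d0 <- sqrt((obs$x_m - x[k])^2 + (obs$y_m - y[k])^2)
      nb <- order(d0)[seq_len(max_neighbors)]
      Dn <- as.matrix(stats::dist(cbind(obs$x_m[nb], obs$y_m[nb])))
      A <- rbind(cbind(gamma_fun(Dn), 1), c(rep(1, length(nb)), 0))
      b <- c(gamma_fun(d0[nb]), 1)
      sol <- solve(A, b)
      wmat[k, nb] <- sol[seq_along(nb)]
      preds[k] <- sum(sol[seq_along(nb)] * obs$value[nb])
    }
  }
  attr(preds, "weights") <- wmat
  preds
}

#' Krige a station snapshot onto a grid
#'
#' Predicts at every cell center of `geom` by ordinary kriging; negative
#' predictions are clipped to zero (count recorded in the `n_clipped`
#' attribute).
#'
#' @param obs Station snapshot (`x_m`, `y_m`, `value`).
#' @param vg Fitted `variogram_model`.
#' @param geom Grid geometry from [grid_geometry()].
#' @param timestamp Optional timestamp carried on the result.
#' @param max_neighbors Neighborhood size bound.
#' @return A `grid_field`: list with `geom`, `timestamp` and a
#'   `n_rows x n_cols` matrix `values`.
#' @export
krige_grid <- function(obs, vg, geom, timestamp = NULL, max_neighbors = 64) {
  cc <- cell_centers(geom)
  pred <- krige_points(obs, vg, cc$x_center, cc$y_center,
                       max_neighbors = max_neighbors)
  n_clipped <- sum(pred < 0)
  if (n_clipped > 0) message(sprintf(
    "krige_grid: clipped %d negative prediction(s) to 0", n_clipped))
  vals <- matrix(pmax(as.numeric(pred), 0), nrow = geom$n_rows,
                 ncol = geom$n_cols, byrow = TRUE)
  structure(list(geom = geom, timestamp = timestamp, values = vals,
                 n_clipped = n_clipped),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field> %dx%d cells of %g m%s; mean %.2f ug/m3\n",
              x$geom$n_cols, x$geom$n_rows, x$geom$cell_size_m,
              if (!is.null(x$timestamp))
                paste0(" at ", format_timestamp(x$timestamp)) else "",
              mean(x$values)))
  invisible(x)
}

#' Locate the grid cell containing a point
#'
#' Half-open membership: a point exactly on a cell's lower/left edge belongs
#' to that cell; a point at `x0 + cell_size` is in column 2.
#'
#' @param grid A `grid_geom` or `grid_field`.
#' @param x,y Point coordinates (vectorized).
#' @param clamp If `TRUE`, points outside the extent are assigned the
#'   nearest boundary cell (with an `n_clamped` attribute); if `FALSE`
#'   (default) they raise an out-of-domain error.
#' @return Tibble with `col`, `row`, and `value` when `grid` is a
#'   `grid_field`.
#' @export
lookup_cell <- function(grid, x, y, clamp = FALSE) {
  geom <- if (inherits(grid, "grid_field")) grid$geom else grid
  col <- floor((x - geom$x0) / geom$cell_size_m) + 1
  row <- floor((y - geom$y0) / geom$cell_size_m) + 1
  outside <- col < 1 | col > geom$n_cols | row < 1 | row > geom$n_rows
  if (any(outside)) {
    if (!clamp) {
      stop(sprintf("lookup_cell: %d point(s) outside grid extent",
                   sum(outside)), call. = FALSE)
    }
    col <- pmin(pmax(col, 1), geom$n_cols)
    row <- pmin(pmax(row, 1), geom$n_rows)
  }
  out <- tibble::tibble(col = as.integer(col), row = as.integer(row))
  if (inherits(grid, "grid_field")) {
    out$value <- grid$values[cbind(out$row, out$col)]
  }
  attr(out, "n_clamped") <- sum(outside)
  out
}

#' Hourly kriging of a sensor table onto a grid
#'
#' Averages sub-hourly sensor readings to hourly station means, fits a
#' spherical variogram per hour, and kriges each hour onto the grid. Both
#' PM2.5 and PM10 can be processed by choosing `value_col`.
#'
#' @param sensors A validated `sensor_table`.
#' @param geom Grid geometry.
#' @param value_col `"pm25"` or `"pm10"`.
#' @param hours Optional POSIXct vector of hours to krige; defaults to every
#'   hour present in the data.
#' @param n_bins Distance bins for the hourly variogram fits.
#' @param max_neighbors Kriging neighborhood bound.
#' @return A `grid_stack`: list with `geom`, sorted `times`, and a 3-d array
#'   `values` of dimension `(n_rows, n_cols, n_times)`.
#' @export
krige_sensor_hours <- function(sensors, geom, value_col = "pm25",
                               hours = NULL, n_bins = 12,
                               max_neighbors = 64) {
  stopifnot(value_col %in% c("pm25", "pm10"))
  hourly <- sensors |>
    dplyr::mutate(hour = hour_floor(.data$timestamp)) |>
    dplyr::group_by(.data$station_id, .data$hour) |>
    dplyr::summarise(
      x_m = .data$x_m[1], y_m = .data$y_m[1],
      value = mean(.data[[value_col]], na.rm = TRUE),
      .groups = "drop"
    )
  if (is.null(hours)) hours <- sort(unique(hourly$hour))
  vals <- array(NA_real_, dim = c(geom$n_rows, geom$n_cols, length(hours)))
  for (k in seq_along(hours)) {
    snap <- hourly[hourly$hour == hours[k], c("x_m", "y_m", "value")]
    vg <- fit_variogram(snap, n_bins = n_bins)
    gf <- suppressMessages(
      krige_grid(snap, vg, geom, timestamp = hours[k],
                 max_neighbors = max_neighbors))
    vals[, , k] <- gf$values
  }
  structure(list(geom = geom, times = hours, values = vals,
                 value_col = value_col),
            class = "grid_stack")
}

#' @export
print.grid_stack <- function(x, ...) {
  cat(sprintf("<grid_stack> %s: %d hourly fields of %dx%d cells (%g m)\n",
              x$value_col, length(x$times), x$geom$n_cols, x$geom$n_rows,
              x$geom$cell_size_m))
  invisible(x)
}

# index of the temporally nearest stack time for each query time; ties go to
# the earlier field
nearest_time_index <- function(times, at) {
  idx <- findInterval(as.numeric(at), as.numeric(times))
  idx[idx < 1] <- 1
  below <- pmax(idx, 1)
  above <- pmin(idx + 1, length(times))
  d_below <- abs(as.numeric(at) - as.numeric(times)[below])
  d_above <- abs(as.numeric(times)[above] - as.numeric(at))
  ifelse(d_above < d_below, above, below)
}

#' Extract a concentration series from a grid stack at fixed coordinates
#'
#' Each query time is matched to the temporally nearest kriged field (ties
#' resolve to the earlier one) and each point to its half-open grid cell.
#'
#' @param stack A `grid_stack`.
#' @param x,y Point coordinates (vectorized, recycled against `at`).
#' @param at POSIXct query times.
#' @param clamp Passed to [lookup_cell()] for points outside the extent.
#' @return Numeric concentrations, same length as `at`.
#' @export
stack_lookup <- function(stack, x, y, at, clamp = FALSE) {
  n <- max(length(at), length(x))
  x <- rep_len(x, n); y <- rep_len(y, n); at <- rep_len(at, n)
  cell <- lookup_cell(stack$geom, x, y, clamp = clamp)
  ti <- nearest_time_index(stack$times, at)
  stack$values[cbind(cell$row, cell$col, ti)]
}
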