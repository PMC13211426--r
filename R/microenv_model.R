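#' Feature columns of the indoor prediction models
#'
#' The six hourly inputs of every microenvironment model: outdoor PM2.5,
#' outdoor PM2.5/PM10 ratio, temperature, wind speed, relative humidity,
#' and precipitation.
#'
#' @return Character vector of feature column names.
#' @export
indoor_feature_cols <- function() {
  c("outdoor_pm25", "ratio_pm25_pm10", "temp_c", "wind_ms", "rh_pct",
    "precip_mm")
}

check_indoor_features <- function(features) {
  missing <- setdiff(indoor_feature_cols(), names(features))
  if (length(missing) > 0) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- vapply(indoor_feature_cols(),
                function(cl) anyNA(features[[cl]]), logical(1))
  if (any(bad)) {
    stop("missing values in feature column(s): ",
         paste(indoor_feature_cols()[bad], collapse = ", "), call. = FALSE)
  }
  invisible(features)
}

#' Train an hourly indoor concentration model for one microenvironment
#'
#' Fits a tree-ensemble regressor of hourly indoor PM2.5 on the six
#' standard inputs. The house model uses an extremely randomized forest
#' (`ranger`, `splitrule = "extratrees"`); other indoor labels use gradient
#' boosting (`xgboost`). A seeded 20% holdout provides honest R2/RMSE/MAE
#' training metrics.
#'
#' @param features Data frame with the [indoor_feature_cols()] columns.
#' @param target Hourly indoor PM2.5 (ug/m3), same length as `nrow(features)`.
#' @param label Microenvironment label (one of [indoor_levels()], or
#'   `"pooled"`).
#' @param backend `"extratrees"` or `"xgboost"`; default chooses by label.
#' @param holdout_frac Fraction of rows held out for metrics.
#' @param seed Integer seed for the split and the ensemble.
#' @return An object of class `microenv_model` with fields `label`,
#'   `backend`, `fit`, and `metrics` (r2, rmse, mae, n_train, n_holdout).
#' @export
train_indoor_model <- function(features, target, label,
                               backend = NULL, holdout_frac = 0.2,
                               seed = 1L) {
  features <- tibble::as_tibble(features)[indoor_feature_cols()]
  check_indoor_features(features)
  n <- nrow(features)
  if (n < 100) {
    stop(sprintf("train_indoor_model('%s'): %d rows; need at least 100",
                 label, n), call. = FALSE)
  }
  stopifnot(length(target) == n, !anyNA(target))
  if (is.null(backend)) {
    backend <- if (identical(label, "house")) "extratrees" else "xgboost"
  }
  backend <- match.arg(backend, c("extratrees", "xgboost"))
  idx_hold <- with_seed(seed, sample.int(n, size = max(1, round(holdout_frac * n))))
  tr_x <- features[-idx_hold, , drop = FALSE]
  tr_y <- target[-idx_hold]
  ho_x <- features[idx_hold, , drop = FALSE]
  ho_y <- target[idx_hold]
  fit <- if (backend == "extratrees") {
    ranger::ranger(
      x = as.data.frame(tr_x), y = tr_y,
      num.trees = 300, splitrule = "extratrees", num.random.splits = 1,
      min.node.size = 5, seed = seed, num.threads = 1
    )
  } else {
    with_seed(seed, xgboost::xgb.train(
      data = xgboost::xgb.DMatrix(as.matrix(tr_x), label = tr_y, nthread = 1),
      nrounds = 200,
      params = list(eta = 0.1, max_depth = 6, subsample = 0.9, nthread = 1,
                    objective = "reg:squarederror"),
      verbose = 0
    ))
  }
  model <- structure(list(label = label, backend = backend, fit = fit,
                          seed = seed),
                     class = "microenv_model")
  pred <- predict_indoor(model, ho_x)
  sse <- sum((ho_y - pred)^2)
  sst <- sum((ho_y - mean(ho_y))^2)
  model$metrics <- list(
    r2 = if (sst > 0) 1 - sse / sst else NA_real_,
    rmse = sqrt(mean((ho_y - pred)^2)),
    mae = mean(abs(ho_y - pred)),
    n_train = nrow(tr_x), n_holdout = length(ho_y)
  )
  model
}

#' @export
print.microenv_model <- function(x, ...) {
  cat(sprintf("<microenv_model> '%s' (%s): holdout R2 %.3f, RMSE %.2f, MAE %.2f (n=%d)\n",
              x$label, x$backend,
              x$metrics$r2, x$metrics$rmse, x$metrics$mae, x$metrics$n_train))
  invisible(x)
}

#' Predict hourly indoor PM2.5
#'
#' @param model A `microenv_model`.
#' @param features Data frame with the [indoor_feature_cols()] columns; an
#'   absent or NA-bearing column is an error naming it.
#' @return Non-negative predicted concentrations (ug/m3).
#' @export
predict_indoor <- function(model, features) {
  features <- tibble::as_tibble(features)[indoor_feature_cols()]
  check_indoor_features(features)
  raw <- if (model$backend == "extratrees") {
    stats::predict(model$fit, data = as.data.frame(features),
                   num.threads = 1)$predictions
  } else {
    stats::predict(model$fit,
                   xgboost::xgb.DMatrix(as.matrix(features), nthread = 1))
  }
  pmax(as.numeric(raw), 0)
}

#' Assemble indoor-model features at locations and times
#'
#' Looks up kriged outdoor PM2.5 and PM10 at each (x, y, time) and joins the
#' hourly meteorology; the PM2.5/PM10 ratio is clamped into (0, 1].
#'
#' @param x,y Coordinates (meters).
#' @param times POSIXct times.
#' @param stack_pm25,stack_pm10 Kriged `grid_stack`s for the two size
#'   fractions.
#' @param met A validated `met_table`.
#' @return Tibble of [indoor_feature_cols()].
#' @export
make_indoor_features <- function(x, y, times, stack_pm25, stack_pm10, met) {
  pm25 <- stack_lookup(stack_pm25, x, y, times, clamp = TRUE)
  pm10 <- stack_lookup(stack_pm10, x, y, times, clamp = TRUE)
  ratio <- pmin(pmax(pm25 / pmax(pm10, 1e-9), 1e-6), 1)
  hrs <- hour_floor(times)
  mi <- match(as.numeric(hrs), as.numeric(hour_floor(met$timestamp)))
  if (anyNA(mi)) mi[is.na(mi)] <- nearest_time_index(met$timestamp, hrs[is.na(mi)])
  tibble::tibble(
    outdoor_pm25 = pm25,
    ratio_pm25_pm10 = ratio,
    temp_c = met$temp_c[mi],
    wind_ms = met$wind_ms[mi],
    rh_pct = met$rh_pct[mi],
    precip_mm = met$precip_mm[mi]
  )
}

#' Train one indoor model per microenvironment from a reference table
#'
#' Builds features at each reference site-hour from the kriged stacks and
#' meteorology, then trains a model per indoor label (house via extremely
#' randomized trees, others via gradient boosting). With
#' `cfg$pool_sparse_labels`, non-house labels with fewer than 100 rows share
#' one pooled model.
#'
#' @param reference Indoor reference table (`microenv, x_m, y_m, timestamp,
#'   pm25`), e.g. from [simulate_indoor_reference()] or field data.
#' @param stack_pm25,stack_pm10 Kriged outdoor stacks.
#' @param met A validated `met_table`.
#' @param cfg A `study_config` (supplies the seed and pooling flag).
#' @return Named list of `microenv_model`s, one per indoor label.
#' @export
train_microenv_models <- function(reference, stack_pm25, stack_pm10, met,
                                  cfg = study_config()) {
  labels <- indoor_levels()
  feats_all <- make_indoor_features(reference$x_m, reference$y_m,
                                    reference$timestamp,
                                    stack_pm25, stack_pm10, met)
  counts <- table(reference$microenv)
  sparse <- labels[labels != "house" &
                     (is.na(counts[labels]) | counts[labels] < 100)]
  models <- list()
  pooled <- NULL
  for (l in labels) {
    sel <- reference$microenv == l
    if (cfg$pool_sparse_labels && l %in% sparse) {
      if (is.null(pooled)) {
        psel <- reference$microenv != "house"
        pooled <- train_indoor_model(feats_all[psel, ], reference$pm25[psel],
                                     "pooled", seed = cfg$rng_seed)
      }
      models[[l]] <- pooled
    } else {
      models[[l]] <- train_indoor_model(feats_all[sel, ], reference$pm25[sel],
                                        l, seed = cfg$rng_seed)
    }
  }
  models
}
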