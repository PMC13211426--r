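#' RMSE and MAE of paired daily series
#'
#' \eqn{RMSE = \sqrt{\frac{1}{n}\sum (y_i - \hat y_i)^2}},
#' \eqn{MAE = \frac{1}{n}\sum |y_i - \hat y_i|} over matched
#' participant-days; pairs with a missing value on either side are dropped.
#'
#' @param pred Estimated daily series \eqn{y_i}.
#' @param meas Measured daily series \eqn{\hat y_i}; must be the same
#'   length as `pred`.
#' @return Named list with `rmse`, `mae` and the pair count `n`.
#' @export
rmse_mae <- function(pred, meas) {
  if (length(pred) != length(meas)) {
    stop("rmse_mae: series lengths differ; pairing error", call. = FALSE)
  }
  keep <- !is.na(pred) & !is.na(meas)
  pred <- pred[keep]; meas <- meas[keep]
  if (length(pred) < 1) stop("rmse_mae: no complete pairs", call. = FALSE)
  list(rmse = sqrt(mean((pred - meas)^2)),
       mae = mean(abs(pred - meas)),
       n = length(pred))
}

#' Summary metrics per scenario against measured exposure
#'
#' One row per series (measured, S1, S2, S3) with the distribution summary
#' (mean, sd, CV = 100*sd/mean on the pooled daily series, median, max) and,
#' for scenarios, the error metrics against the measured series on matched
#' participant-days (MAE, RMSE, Pearson r) and the ratio of means
#' (reported to 1 decimal place). Pearson r is reported as `NA` when either
#' series has zero variance.
#'
#' @param daily A `daily_exposure` table.
#' @return Tibble `series, n_days, mean, sd, cv_pct, median, max, mae,
#'   rmse, pearson_r, mean_ratio_to_measured`.
#' @export
summarize_scenarios <- function(daily) {
  meas_mean <- mean(daily$measured, na.rm = TRUE)
  one <- function(col) {
    v <- daily[[col]]
    keep <- !is.na(v) & !is.na(daily$measured)
    err <- if (col == "measured") list(rmse = NA_real_, mae = NA_real_)
           else rmse_mae(v[keep], daily$measured[keep])
    r <- NA_real_
    if (col != "measured" && sum(keep) >= 2 &&
        stats::sd(v[keep]) > 0 && stats::sd(daily$measured[keep]) > 0) {
      r <- stats::cor(v[keep], daily$measured[keep])
    }
    tibble::tibble(
      series = if (col == "measured") "measured" else toupper(col),
      n_days = sum(!is.na(v)),
      mean = mean(v, na.rm = TRUE),
      sd = stats::sd(v[!is.na(v)]),
      cv_pct = 100 * stats::sd(v[!is.na(v)]) / mean(v, na.rm = TRUE),
      median = stats::median(v, na.rm = TRUE),
      max = max(v, na.rm = TRUE),
      mae = err$mae, rmse = err$rmse, pearson_r = r,
      mean_ratio_to_measured = if (col == "measured") 1.0
        else round(mean(v, na.rm = TRUE) / meas_mean, 1)
    )
  }
  dplyr::bind_rows(lapply(c("measured", "s1", "s2", "s3"), one))
}

#' Paired and group comparisons of daily exposure series
#'
#' Paired two-sided t-tests of each scenario against the measured series on
#' matched participant-days (a degenerate all-zero difference is reported
#' as no difference, p = 1), plus a one-way ANOVA across the labeled daily
#' series groups.
#'
#' @param daily A `daily_exposure` table.
#' @param alpha Significance level annotated in the report.
#' @return List with `t_tests` (tibble: comparison, n, mean_diff, statistic,
#'   p_value, significant) and `anova` (tibble: f, df1, df2, p_value).
#' @export
paired_comparisons <- function(daily, alpha = 0.05) {
  tt <- lapply(c("s1", "s2", "s3"), function(sc) {
    keep <- !is.na(daily[[sc]]) & !is.na(daily$measured)
    x <- daily[[sc]][keep]; y <- daily$measured[keep]
    if (sum(keep) < 3) {
      return(tibble::tibble(comparison = paste0(toupper(sc), " vs measured"),
                            n = sum(keep), mean_diff = NA_real_,
                            statistic = NA_real_, p_value = NA_real_,
                            significant = NA, note = "insufficient pairs"))
    }
    d <- x - y
    if (stats::sd(d) == 0) {
      p <- if (mean(d) == 0) 1 else 0
      return(tibble::tibble(comparison = paste0(toupper(sc), " vs measured"),
                            n = length(d), mean_diff = mean(d),
                            statistic = NA_real_, p_value = p,
                            significant = p < alpha,
                            note = "degenerate differences"))
    }
    ht <- stats::t.test(x, y, paired = TRUE)
    tibble::tibble(comparison = paste0(toupper(sc), " vs measured"),
                   n = length(d), mean_diff = mean(d),
                   statistic = unname(ht$statistic),
                   p_value = ht$p.value, significant = ht$p.value < alpha,
                   note = NA_character_)
  })
  long <- tidyr::pivot_longer(
    dplyr::select(daily, "s1", "s2", "s3", "measured"),
    dplyr::everything(), names_to = "series", values_to = "value") |>
    tidyr::drop_na()
  an <- group_anova(long$value, long$series)
  list(t_tests = dplyr::bind_rows(tt), anova = an)
}

#' One-way ANOVA across labeled groups
#'
#' Thin wrapper around `stats::aov` returning the F test as a tibble; used
#' for comparing concentration distributions across microenvironments or
#' series.
#'
#' @param values Numeric observations.
#' @param groups Group labels (coerced to factor).
#' @return Tibble `f, df1, df2, p_value`.
#' @export
group_anova <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  tibble::tibble(f = s[["F value"]][1], df1 = s[["Df"]][1],
                 df2 = s[["Df"]][2], p_value = s[["Pr(>F)"]][1])
}
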