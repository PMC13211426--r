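#' Per-source exposure contribution rates
#'
#' Share of a day's TWA exposure attributable to each source:
#' \eqn{C_i T_i / (C_{TWA} \cdot T) \times 100} with \eqn{T} either the
#' literal 24 h of the printed convention (`"literal24"`) or the day's
#' accounted time \eqn{\sum_i T_i} (`"normalized"`, in which case the
#' shares sum to exactly 100). Under the literal convention the shares sum
#' to \eqn{(\sum T_i / 24) \cdot 100}, i.e. less than 100 whenever the
#' accounted time is under 24 h.
#'
#' @param conc Per-source concentrations \eqn{C_i} (ug/m3).
#' @param hours Per-source occupancy times \eqn{T_i} (hours).
#' @param convention `"normalized"` or `"literal24"`.
#' @param c_twa The day's TWA; defaults to [twa()] of the inputs.
#' @return Percent contributions, one per source.
#' @export
contribution_rates <- function(conc, hours,
                               convention = c("normalized", "literal24"),
                               c_twa = NULL) {
  convention <- match.arg(convention)
  if (is.null(c_twa)) c_twa <- twa(conc, hours)
  if (is.na(c_twa) || c_twa <= 0) {
    stop("contribution_rates: undefined for zero TWA", call. = FALSE)
  }
  denom_t <- if (convention == "literal24") 24 else sum(hours)
  conc * hours / (c_twa * denom_t) * 100
}

#' Select the percentile day of a daily distribution
#'
#' Nearest-rank selection: the \eqn{\lceil p n \rceil}-th order statistic of
#' the daily values. Ties are broken deterministically by earliest date
#' (then participant id).
#'
#' @param values Daily TWA concentrations.
#' @param p Percentile fraction in (0, 1].
#' @param dates Optional dates used as tie-break (defaults to input order).
#' @param ids Optional participant ids (secondary tie-break).
#' @return The index (into `values`) of the selected day.
#' @export
select_percentile_day <- function(values, p, dates = NULL, ids = NULL) {
  keep <- which(!is.na(values))
  if (length(keep) == 0) stop("select_percentile_day: no days", call. = FALSE)
  stopifnot(p > 0, p <= 1)
  if (is.null(dates)) dates <- seq_along(values)
  if (is.null(ids)) ids <- seq_along(values)
  ord <- keep[order(values[keep], dates[keep], ids[keep])]
  k <- min(max(ceiling(p * length(keep)), 1), length(keep))
  v_k <- values[ord[k]]
  tied <- keep[values[keep] == v_k]
  tied[order(dates[tied], ids[tied])][1]
}

# per participant-day indoor/outdoor exposure numerators (ug/m3 * h) for
# each scenario, from the slot tables
daily_source_terms <- function(occ, home_monitor, cfg = study_config()) {
  hm <- slot_series(home_monitor)
  out_like_s3 <- if (cfg$transport_outdoor) c("outdoor", "transportation")
                 else "outdoor"
  house_like_s2 <- if (cfg$s2_fold_other_into_house) indoor_levels() else "house"
  occj <- occ |>
    dplyr::left_join(dplyr::rename(hm, c_house_slot = "value"),
                     by = c("participant_id", "slot_start"))
  slot_terms <- occj |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(
      s2_in = sum(.data$c_house_slot[.data$microenv %in% house_like_s2],
                  na.rm = TRUE) * 0.5,
      s2_in_h = sum(.data$microenv %in% house_like_s2 &
                      !is.na(.data$c_house_slot)) * 0.5,
      s2_out = sum(.data$c_outdoor_gps[.data$microenv %in% "outdoor"],
                   na.rm = TRUE) * 0.5,
      s2_out_h = sum(.data$microenv %in% "outdoor" &
                       !is.na(.data$c_outdoor_gps)) * 0.5,
      s3_in = if ("c_indoor_pred" %in% names(occj))
        sum(.data$c_indoor_pred[!is.na(.data$microenv) &
                                  !(.data$microenv %in% out_like_s3)],
            na.rm = TRUE) * 0.5 else NA_real_,
      s3_in_h = sum(!is.na(.data$microenv) &
                      !(.data$microenv %in% out_like_s3)) * 0.5,
      s3_out = sum(.data$c_outdoor_gps[.data$microenv %in% out_like_s3],
                   na.rm = TRUE) * 0.5,
      s3_out_h = sum(.data$microenv %in% out_like_s3) * 0.5,
      c_house_daily = mean(.data$c_house_slot, na.rm = TRUE),
      c_outdoor_daily = mean(.data$c_outdoor_home, na.rm = TRUE),
      .groups = "drop"
    )
  slot_terms |>
    dplyr::mutate(
      s1_in = .data$c_house_daily * cfg$s1_time_house_h,
      s1_in_h = cfg$s1_time_house_h,
      s1_out = .data$c_outdoor_daily * cfg$s1_time_outdoor_h,
      s1_out_h = cfg$s1_time_outdoor_h
    )
}

#' CTE/RME indoor and outdoor contribution summary per scenario
#'
#' For each scenario, selects the day at the CTE (default 50th) and RME
#' (default 95th) percentile of the pooled participant-day TWA distribution
#' and reports that day's indoor and outdoor contribution rates under both
#' the normalized and the literal-24 h conventions.
#'
#' @param occ An `occupancy` tibble with `c_indoor_pred` attached.
#' @param home_monitor Home indoor `monitor_series`.
#' @param daily A `daily_exposure` table (for the scenario TWA
#'   distributions).
#' @param cfg A `study_config`.
#' @return Tibble `scenario, level, convention, indoor_pct, outdoor_pct,
#'   participant_id, date`.
#' @export
contribution_summary <- function(occ, home_monitor, daily,
                                 cfg = study_config()) {
  terms <- daily_source_terms(occ, home_monitor, cfg)
  daily <- dplyr::left_join(daily, terms, by = c("participant_id", "date"))
  levels_p <- c(CTE = cfg$cte_percentile, RME = cfg$rme_percentile)
  rows <- list()
  for (sc in c("s1", "s2", "s3")) {
    for (lvl in names(levels_p)) {
      idx <- select_percentile_day(daily[[sc]], levels_p[[lvl]],
                                   dates = daily$date,
                                   ids = daily$participant_id)
      num_in <- daily[[paste0(sc, "_in")]][idx]
      num_out <- daily[[paste0(sc, "_out")]][idx]
      acc_h <- daily[[paste0(sc, "_in_h")]][idx] +
        daily[[paste0(sc, "_out_h")]][idx]
      c_twa <- daily[[sc]][idx]
      for (conv in c("normalized", "literal24")) {
        denom_t <- if (conv == "literal24") 24 else acc_h
        rows[[length(rows) + 1]] <- tibble::tibble(
          scenario = toupper(sc), level = lvl, convention = conv,
          indoor_pct = num_in / (c_twa * denom_t) * 100,
          outdoor_pct = num_out / (c_twa * denom_t) * 100,
          participant_id = daily$participant_id[idx],
          date = daily$date[idx]
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
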