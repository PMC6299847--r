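# Daily aggregation of vital signs, fixed clinical threshold rules,
# subject-specific adaptive bands and moving-average trend decomposition.

#' Clinical threshold set
#'
#' The fixed protocol thresholds used on incoming vitals: blood pressure
#' above 140/80 mmHg, oxygen saturation below 85 %, and weight change of
#' more than 1 kg in 24 h or 1.4 kg over 3 days. All comparisons are
#' strict, matching the printed `>` / `<` forms.
#'
#' @param systolic_max systolic ceiling, mmHg.
#' @param diastolic_max diastolic ceiling, mmHg.
#' @param spo2_min saturation floor, percent.
#' @param weight_delta_1d 24 h weight-change bound, kg.
#' @param weight_delta_3d 3-day weight-change bound, kg.
#' @return list of class `clinical_thresholds`.
#' @export
clinical_thresholds <- function(systolic_max = 140, diastolic_max = 80,
                                spo2_min = 85, weight_delta_1d = 1.0,
                                weight_delta_3d = 1.4) {
  stopifnot(systolic_max > 0, diastolic_max > 0, spo2_min > 0,
            weight_delta_1d > 0, weight_delta_3d > 0)
  structure(list(systolic_max = systolic_max, diastolic_max = diastolic_max,
                 spo2_min = spo2_min, weight_delta_1d = weight_delta_1d,
                 weight_delta_3d = weight_delta_3d),
            class = "clinical_thresholds")
}

#' Representative daily value for one vital on one day
#'
#' Patients occasionally take two or three measurements in a day. For
#' oxygen saturation the higher reading is the day's representative, as
#' clinicians do; for blood pressure, pulse and weight the median of the
#' day's readings is used (mean of the central pair when the count is
#' even).
#'
#' @param readings tibble of readings (`kind`, `timestamp`, `value`) all of
#'   one kind on one civil day; at least one row.
#' @return one-row tibble `day`, `kind`, `value`, `n_readings`.
#' @export
daily_representative <- function(readings) {
  stopifnot(nrow(readings) >= 1)
  kind <- unique(readings$kind)
  day <- unique(civil_day(readings$timestamp))
  if (length(kind) != 1 || length(day) != 1)
    stop("daily_representative: readings must share one kind and one day")
  value <- if (kind == "spo2_percent") max(readings$value)
           else stats::median(readings$value)
  tibble::tibble(day = day, kind = kind, value = value,
                 n_readings = nrow(readings))
}

#' Aggregate a reading stream to one value per day and kind
#'
#' Applies [daily_representative()] across every (day, kind) group in a
#' vitals stream.
#'
#' @param readings tibble as returned by [read_vitals()].
#' @return tibble `day`, `kind`, `value`, `n_readings`; at most one row per
#'   (day, kind).
#' @export
daily_vitals <- function(readings) {
  if (nrow(readings) == 0)
    return(tibble::tibble(day = as.Date(character()), kind = character(),
                          value = numeric(), n_readings = integer()))
  readings |>
    dplyr::mutate(day = civil_day(.data$timestamp)) |>
    dplyr::group_by(.data$day, .data$kind) |>
    dplyr::summarise(
      value = if (.data$kind[1] == "spo2_percent") max(.data$value)
              else stats::median(.data$value),
      n_readings = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$day, .data$kind)
}

#' Fixed-threshold clinical alerts
#'
#' Fires a blood-pressure alert on any day whose representative systolic
#' exceeds `systolic_max` or diastolic exceeds `diastolic_max` (either
#' component suffices), and a saturation alert when SpO2 falls strictly
#' below `spo2_min`. Days without a representative value raise nothing.
#'
#' @param daily daily vitals from [daily_vitals()].
#' @param thresholds a [clinical_thresholds()] object.
#' @return alert tibble (see [empty_alerts()]); the observed value is the
#'   component that fired (systolic reported when both components exceed).
#' @export
clinical_alerts <- function(daily, thresholds = clinical_thresholds()) {
  wide <- daily |>
    dplyr::select("day", "kind", "value") |>
    tidyr::pivot_wider(names_from = "kind", values_from = "value")
  out <- list()
  sys <- wide[["systolic_mmHg"]]
  dia <- wide[["diastolic_mmHg"]]
  if (!is.null(sys) || !is.null(dia)) {
    sys_hit <- if (is.null(sys)) rep(FALSE, nrow(wide)) else
      !is.na(sys) & sys > thresholds$systolic_max
    dia_hit <- if (is.null(dia)) rep(FALSE, nrow(wide)) else
      !is.na(dia) & dia > thresholds$diastolic_max
    hit <- sys_hit | dia_hit
    if (any(hit)) {
      obs <- ifelse(sys_hit[hit], sys[hit], dia[hit])
      thr <- ifelse(sys_hit[hit], thresholds$systolic_max,
                    thresholds$diastolic_max)
      out$bp <- new_alerts(wide$day[hit], "clinical", "bp_over", obs, "over",
                           upper = thr)
    }
  }
  sp <- wide[["spo2_percent"]]
  if (!is.null(sp)) {
    hit <- !is.na(sp) & sp < thresholds$spo2_min
    if (any(hit))
      out$spo2 <- new_alerts(wide$day[hit], "clinical", "spo2_under",
                             sp[hit], "under", lower = thresholds$spo2_min)
  }
  log <- dplyr::bind_rows(c(list(empty_alerts()), out))
  dplyr::arrange(log, .data$day, .data$rule)
}

#' Short-term weight-change alerts
#'
#' Flags fluid-retention-scale weight changes: more than
#' `weight_delta_1d` kg relative to the previous civil day, or more than
#' `weight_delta_3d` kg relative to the day exactly three civil days
#' earlier. Both rules may fire on one day (two alerts); comparisons
#' require both endpoints present, and intermediate gaps in the 3-day rule
#' are allowed. Gains and losses both fire, with the direction recorded.
#'
#' @param daily_weights daily vitals restricted to `weight_kg`.
#' @param thresholds a [clinical_thresholds()] object.
#' @return alert tibble with rules `weight_24h` / `weight_3d`; `observed`
#'   is the signed change in kg.
#' @export
weight_change_alerts <- function(daily_weights,
                                 thresholds = clinical_thresholds()) {
  w <- daily_weights |>
    dplyr::filter(.data$kind == "weight_kg") |>
    dplyr::arrange(.data$day)
  if (nrow(w) == 0) return(empty_alerts())
  lookup <- stats::setNames(w$value, as.character(w$day))
  out <- list()
  for (lag in c(1L, 3L)) {
    ref <- lookup[as.character(w$day - lag)]
    delta <- unname(w$value - ref)
    bound <- if (lag == 1L) thresholds$weight_delta_1d else
      thresholds$weight_delta_3d
    hit <- !is.na(delta) & abs(delta) > bound
    if (any(hit)) {
      out[[as.character(lag)]] <- new_alerts(
        w$day[hit], "clinical", if (lag == 1L) "weight_24h" else "weight_3d",
        delta[hit], ifelse(delta[hit] > 0, "gain", "loss"),
        lower = -bound, upper = bound)
    }
  }
  log <- dplyr::bind_rows(c(list(empty_alerts()), out))
  dplyr::arrange(log, .data$day, .data$rule)
}

#' Subject-specific band for one vital
#'
#' Computes the trailing mean +/- `k` SD band (see [trailing_band()]) for
#' a single vital kind, either for one requested day or for every day in
#' the series.
#'
#' @param series daily vitals of one kind (`day`, `value`).
#' @param day optional single day to evaluate; default: all series days.
#' @param window_days trailing window, civil days (default 15).
#' @param k SD multiplier (default 2).
#' @param min_window_obs minimum window observations (default 5).
#' @return band tibble from [trailing_band()] with a `kind` column.
#' @export
personal_band <- function(series, day = NULL, window_days = 15, k = 2,
                          min_window_obs = 5) {
  kind <- unique(series$kind)
  if (length(kind) > 1) stop("personal_band: one vital kind at a time")
  eval_days <- if (is.null(day)) series$day else as.Date(day)
  band <- trailing_band(series$day, series$value, eval_days,
                        window_days = window_days, k = k,
                        min_window_obs = min_window_obs)
  band$kind <- if (length(kind) == 1) kind else NA_character_
  band
}

#' Alerts from subject-specific bands
#'
#' Flags any day whose representative value falls strictly outside its
#' trailing band. A zero-variance window yields a degenerate band equal to
#' the window mean, so any deviation from that constant fires.
#'
#' @inheritParams personal_band
#' @return alert tibble with rules `<kind>_band_over` / `<kind>_band_under`.
#' @export
personal_band_alerts <- function(series, window_days = 15, k = 2,
                                 min_window_obs = 5) {
  if (nrow(series) == 0) return(empty_alerts())
  band <- personal_band(series, NULL, window_days, k, min_window_obs)
  j <- dplyr::inner_join(series, band, by = "day",
                         suffix = c("", ".band"))
  hit <- !j$warmup & (j$value > j$upper | j$value < j$lower)
  if (!any(hit)) return(empty_alerts())
  kind <- unique(series$kind)
  new_alerts(j$day[hit], "clinical",
             paste0(kind, "_band_",
                    ifelse(j$value[hit] > j$upper[hit], "over", "under")),
             j$value[hit],
             ifelse(j$value[hit] > j$upper[hit], "over", "under"),
             lower = j$lower[hit], upper = j$upper[hit]) |>
    dplyr::arrange(.data$day)
}

#' Moving-average trend and residual decomposition
#'
#' The normal profile of a daily vital series is formed from moving
#' averages: a short centered moving average (the short-term trend), a
#' long centered moving average (the long-term trend), the residual about
#' the short-term trend, and a trailing-window standard deviation of those
#' residuals that tracks rising day-to-day variability.
#'
#' Missing days are tolerated: each centered window averages whatever
#' observations are present in it. Windows that would extend past the
#' observed span are left undefined.
#'
#' @param series daily vitals of one kind (`day`, `value`).
#' @param short_window odd centered window for the short trend, days
#'   (default 7).
#' @param long_window odd centered window for the long trend, days
#'   (default 29).
#' @return tibble over the full day grid: `day`, `kind`, `value`,
#'   `short_trend`, `long_trend`, `residual`, `residual_sd_window`.
#' @export
trend_decompose <- function(series, short_window = 7, long_window = 29) {
  stopifnot(short_window < long_window, short_window %% 2 == 1,
            long_window %% 2 == 1)
  kind <- unique(series$kind)
  days <- seq(min(series$day), max(series$day), by = "day")
  value <- stats::setNames(rep(NA_real_, length(days)), as.character(days))
  value[as.character(series$day)] <- series$value
  n <- length(days)
  centered_ma <- function(w) {
    half <- (w - 1) / 2
    out <- rep(NA_real_, n)
    if (n < w) return(out)
    for (i in (half + 1):(n - half)) {
      v <- value[(i - half):(i + half)]
      if (any(!is.na(v))) out[i] <- mean(v, na.rm = TRUE)
    }
    out
  }
  if (n < short_window || n < long_window)
    warning("trend_decompose: series shorter than window; trends undefined")
  short <- centered_ma(short_window)
  long <- centered_ma(long_window)
  resid <- unname(value) - short
  resid_sd <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1, i - short_window + 1)
    v <- resid[lo:i]
    v <- v[!is.na(v)]
    if (length(v) >= 2) resid_sd[i] <- stats::sd(v)
  }
  tibble::tibble(day = days, kind = kind, value = unname(value),
                 short_trend = short, long_trend = long, residual = resid,
                 residual_sd_window = resid_sd)
}
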