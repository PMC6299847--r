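# Adaptive habits alerting over period schemes, the consecutive-alert
# persistence filter, log merging and scheme evaluation against a
# ground-truth episode calendar.

#' Alert-engine configuration
#'
#' Bundles the adaptive-alerting parameters: the period scheme, the
#' 15-day trailing window over which each period's mean and SD are
#' tracked, the band half-width `k` (2 SD), the warm-up minimum, the
#' persistence requirement (consecutive same-type alert days before an
#' alert is deemed actionable) and which periods raise alerts.
#'
#' @param scheme a [period_scheme()]; default the three-period scheme,
#'   which raises portal alerts only for the all-day period.
#' @param window_days trailing window, civil days (default 15).
#' @param k SD multiplier (default 2).
#' @param min_window_obs minimum window observations before a band is
#'   defined (default 5).
#' @param persistence_m consecutive days of the same alert type required
#'   for the persistent flag (default 3).
#' @param alerting_periods period labels evaluated for alerts; defaults to
#'   the scheme's own alerting set.
#' @return list of class `alert_engine_config`.
#' @export
alert_engine_config <- function(scheme = scheme_v2_three_period(),
                                window_days = 15, k = 2, min_window_obs = 5,
                                persistence_m = 3, alerting_periods = NULL) {
  stopifnot(inherits(scheme, "period_scheme"),
            window_days >= min_window_obs, min_window_obs >= 1,
            persistence_m >= 1)
  if (is.null(alerting_periods)) alerting_periods <- scheme$alerting_periods
  if (!all(alerting_periods %in% scheme$periods$label))
    stop("alert_engine_config: alerting period not in scheme")
  structure(list(scheme = scheme, window_days = window_days, k = k,
                 min_window_obs = min_window_obs,
                 persistence_m = persistence_m,
                 alerting_periods = alerting_periods),
            class = "alert_engine_config")
}

#' Adaptive habits alerts from period counts
#'
#' For each evaluated (day, period), the threshold band is the mean plus or
#' minus `k` sample SDs of that period's counts over the trailing
#' `window_days` civil days (the current day excluded). A count strictly
#' outside the band raises a habits alert with the direction recorded;
#' warm-up days (too few window observations) raise nothing.
#'
#' @param period_counts tibble `day`, `period`, `n` from [period_counts()].
#' @param config an [alert_engine_config()].
#' @return alert tibble with rules `habits_over` / `habits_under` and the
#'   period label attached.
#' @export
habit_alerts <- function(period_counts, config = alert_engine_config()) {
  stopifnot(inherits(config, "alert_engine_config"))
  out <- list(empty_alerts())
  for (p in config$alerting_periods) {
    s <- period_counts[period_counts$period == p, ]
    if (nrow(s) == 0) next
    band <- trailing_band(s$day, s$n, window_days = config$window_days,
                          k = config$k,
                          min_window_obs = config$min_window_obs)
    hit <- !band$warmup & (s$n > band$upper | s$n < band$lower)
    if (!any(hit)) next
    over <- s$n[hit] > band$upper[hit]
    out[[p]] <- new_alerts(s$day[hit], "habits",
                           ifelse(over, "habits_over", "habits_under"),
                           s$n[hit], ifelse(over, "over", "under"),
                           period = p, lower = band$lower[hit],
                           upper = band$upper[hit])
  }
  dplyr::bind_rows(out) |> dplyr::arrange(.data$day, .data$period)
}

#' Persistence filter over an alert log
#'
#' Clinicians act only on several consecutive alerts of the same type.
#' Marks `persistent = TRUE` on day d exactly when the same alert type —
#' same category, rule, period and direction — fired on each of the `m`
#' consecutive civil days ending at d. `m = 1` marks every alert.
#'
#' @param alerts alert tibble.
#' @param m required run length in days (default 3).
#' @return the alert tibble with `persistent` recomputed.
#' @export
persistence_filter <- function(alerts, m = 3) {
  stopifnot(m >= 1)
  if (nrow(alerts) == 0) return(alerts)
  alerts |>
    dplyr::group_by(.data$category, .data$rule, .data$period,
                    .data$direction) |>
    dplyr::group_modify(function(g, key) {
      days <- sort(unique(g$day))
      run <- rep(1L, length(days))
      if (length(days) > 1) {
        for (i in 2:length(days)) {
          if (days[i] - days[i - 1] == 1) run[i] <- run[i - 1] + 1L
        }
      }
      persistent_days <- days[run >= m]
      g$persistent <- g$day %in% persistent_days
      g
    }) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(alert_cols)) |>
    dplyr::arrange(.data$day, .data$category, .data$rule)
}

#' Merge clinical and habits alert logs
#'
#' Produces one chronological log, stably sorted by day then category
#' (clinical before habits) then rule, so repeated runs give identical
#' output.
#'
#' @param clinical,habits alert tibbles.
#' @return unified alert tibble.
#' @export
merge_alert_log <- function(clinical, habits) {
  log <- dplyr::bind_rows(empty_alerts(), clinical, habits)
  log |>
    dplyr::arrange(.data$day,
                   factor(.data$category, levels = c("clinical", "habits")),
                   .data$rule)
}

#' Compare alerting schemes against a ground-truth episode calendar
#'
#' Scores each configuration's habits alerts against known episode days
#' (available for synthetic runs): an alert on a day inside an episode, or
#' within `grace_days` after it, is a true positive; any other alert is a
#' false alarm. Sensitivity is the fraction of episodes with at least one
#' true-positive alert; the false-alarm rate is false-alarm days per
#' evaluable non-episode day.
#'
#' @param period_counts tibble `day`, `period`, `n`.
#' @param configs list of [alert_engine_config()] objects.
#' @param truth episode calendar tibble with `start_day`, `end_day`
#'   (Dates) and optionally `kind`.
#' @param grace_days days after episode end still credited (default 2).
#' @return tibble `scheme`, `n_alert_days`, `n_true_positive`,
#'   `n_false_alarms`, `sensitivity`, `false_alarm_rate`,
#'   `alerts_per_week`.
#' @export
scheme_comparison <- function(period_counts, configs, truth,
                              grace_days = 2) {
  if (is.null(truth) || nrow(truth) == 0)
    stop("scheme_comparison: ground-truth episode calendar required")
  episode_days <- unique(do.call(c, purrr::pmap(
    truth[, c("start_day", "end_day")],
    function(start_day, end_day) seq(start_day, end_day + grace_days,
                                     by = "day"))))
  rows <- purrr::map(configs, function(cfg) {
    al <- habit_alerts(period_counts, cfg)
    alert_days <- unique(al$day)
    tp_days <- alert_days[alert_days %in% episode_days]
    fa_days <- alert_days[!(alert_days %in% episode_days)]
    detected <- purrr::pmap_lgl(
      truth[, c("start_day", "end_day")],
      function(start_day, end_day)
        any(alert_days >= start_day & alert_days <= end_day + grace_days))
    all_days <- sort(unique(period_counts$day))
    evaluable <- all_days[all_days >= min(all_days) + cfg$window_days]
    eval_non_episode <- evaluable[!(evaluable %in% episode_days)]
    tibble::tibble(
      scheme = cfg$scheme$name,
      n_alert_days = length(alert_days),
      n_true_positive = length(tp_days),
      n_false_alarms = length(fa_days),
      sensitivity = mean(detected),
      false_alarm_rate = if (length(eval_non_episode) > 0)
        length(fa_days) / length(eval_non_episode) else NA_real_,
      alerts_per_week = if (length(evaluable) > 0)
        nrow(al) * 7 / length(evaluable) else NA_real_)
  })
  dplyr::bind_rows(rows)
}
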