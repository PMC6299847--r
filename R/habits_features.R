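# Habits-parameter extraction from motion and occupancy event streams:
# hourly/period movement counts, mean hourly profile, first/last movement
# times, time-to-next-move quantiles, and bed/chair occupancy features.

#' Hourly movement counts
#'
#' Counts PIR motion events per civil day in half-open hourly bins
#' `[h:00, h+1:00)`, h = 0..23. Days inside the monitored span with no
#' events appear with all-zero counts, so downstream period counts and
#' adaptive bands see genuine zero-activity days.
#'
#' @param events motion events ([read_events()] output); passing usage
#'   events is an error.
#' @param location optional location filter (e.g. `"living_room"`).
#' @param span optional Date vector of length 2 giving the monitored day
#'   range; defaults to the range of the events.
#' @return tibble `day`, `hour` (0..23), `n`, complete over the span.
#' @export
hourly_counts <- function(events, location = NULL, span = NULL) {
  if (any(events$kind != "motion"))
    stop("hourly_counts: only motion events may be binned")
  if (!is.null(location)) events <- events[events$location %in% location, ]
  if (is.null(span)) {
    if (nrow(events) == 0) stop("hourly_counts: no events and no span given")
    span <- range(civil_day(events$timestamp))
  }
  days <- seq(span[1], span[2], by = "day")
  grid <- tidyr::expand_grid(day = days, hour = 0:23)
  if (nrow(events) == 0) return(dplyr::mutate(grid, n = 0L))
  tallied <- tibble::tibble(
    day = civil_day(events$timestamp),
    hour = as.integer(floor(time_of_day_s(events$timestamp) / 3600))
  ) |>
    dplyr::count(.data$day, .data$hour)
  grid |>
    dplyr::left_join(tallied, by = c("day", "hour")) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    dplyr::arrange(.data$day, .data$hour)
}

#' Alerting-period schemes
#'
#' A period scheme partitions (possibly overlapping) the 24 h day into
#' labelled alerting periods with whole-hour, half-open boundaries.
#' Midnight-spanning periods (e.g. night-time 22:00-06:00) are written
#' with `end_hour <= start_hour` and are attributed to the day containing
#' their start. Two schemes ship as built-ins:
#' * `scheme_v1_four_period()`: four six-hour periods 00-06, 06-12, 12-18,
#'   18-24, all raising alerts.
#' * `scheme_v2_three_period()`: all-day (00-24), night-time (22-06) and
#'   morning (06-10); only the all-day period raises portal alerts, the
#'   other periods are evaluated for inspection.
#'
#' @param name scheme label.
#' @param periods tibble with `label`, `start_hour`, `end_hour` (integers;
#'   `end_hour` exclusive, 24 = midnight; `end_hour <= start_hour` wraps).
#' @param alerting_periods labels of periods that raise alerts.
#' @return list of class `period_scheme`.
#' @export
period_scheme <- function(name, periods, alerting_periods = periods$label) {
  stopifnot(all(c("label", "start_hour", "end_hour") %in% names(periods)))
  if (any(periods$start_hour != floor(periods$start_hour)) ||
      any(periods$end_hour != floor(periods$end_hour)))
    stop("period_scheme: period boundaries must fall on whole hours")
  if (any(periods$start_hour < 0 | periods$start_hour > 23 |
          periods$end_hour < 1 | periods$end_hour > 24))
    stop("period_scheme: hours must lie in 0..24")
  if (!all(alerting_periods %in% periods$label))
    stop("period_scheme: unknown alerting period label")
  structure(list(name = name, periods = tibble::as_tibble(periods),
                 alerting_periods = alerting_periods),
            class = "period_scheme")
}

#' @rdname period_scheme
#' @export
scheme_v1_four_period <- function() {
  period_scheme("v1_four_period", tibble::tibble(
    label = c("p1_00_06", "p2_06_12", "p3_12_18", "p4_18_24"),
    start_hour = c(0L, 6L, 12L, 18L), end_hour = c(6L, 12L, 18L, 24L)))
}

#' @rdname period_scheme
#' @export
scheme_v2_three_period <- function() {
  period_scheme("v2_three_period", tibble::tibble(
    label = c("all_day", "night", "morning"),
    start_hour = c(0L, 22L, 6L), end_hour = c(24L, 6L, 10L)),
    alerting_periods = "all_day")
}

period_hours <- function(start_hour, end_hour) {
  if (end_hour > start_hour) {
    tibble::tibble(hour = start_hour:(end_hour - 1), day_offset = 0L)
  } else {
    dplyr::bind_rows(
      tibble::tibble(hour = start_hour:23L, day_offset = 0L),
      tibble::tibble(hour = 0L:(end_hour - 1L), day_offset = 1L))
  }
}

#' Per-day period counts under a scheme
#'
#' Accumulates hourly counts into each scheme period. A wrapping period on
#' day d uses that day's late hours plus the early hours of day d+1; its
#' `complete` flag is FALSE when the following day lies outside the data.
#'
#' @param hourly output of [hourly_counts()].
#' @param scheme a [period_scheme()].
#' @return tibble `day`, `period`, `n`, `complete`.
#' @export
period_counts <- function(hourly, scheme) {
  stopifnot(inherits(scheme, "period_scheme"))
  days <- sort(unique(hourly$day))
  out <- purrr::pmap(scheme$periods, function(label, start_hour, end_hour) {
    ph <- period_hours(start_hour, end_hour)
    parts <- purrr::pmap(ph, function(hour, day_offset) {
      h <- hourly[hourly$hour == hour, c("day", "n")]
      h$day <- h$day - day_offset   # contribution attributed to start day
      h
    })
    dplyr::bind_rows(parts) |>
      dplyr::filter(.data$day %in% days) |>
      dplyr::group_by(.data$day) |>
      dplyr::summarise(n = sum(.data$n), n_hours = dplyr::n(),
                       .groups = "drop") |>
      dplyr::mutate(period = label,
                    complete = .data$n_hours == nrow(ph)) |>
      dplyr::select("day", "period", "n", "complete")
  })
  dplyr::bind_rows(out) |> dplyr::arrange(.data$day, .data$period)
}

#' Mean hourly activity profile
#'
#' Averages the hourly counts over a window of days (20 by default) to
#' give the subject's circadian activity profile, from which wake, meal
#' and bed times can be read off.
#'
#' @param hourly output of [hourly_counts()].
#' @param window_days number of most recent days to average (default 20).
#' @param end_day last day of the window; defaults to the last day present.
#' @return tibble `hour`, `mean_n` (24 rows), with attribute `n_days`.
#' @export
mean_hourly_profile <- function(hourly, window_days = 20, end_day = NULL) {
  if (nrow(hourly) == 0) stop("mean_hourly_profile: empty input")
  if (is.null(end_day)) end_day <- max(hourly$day)
  win <- hourly[hourly$day > end_day - window_days & hourly$day <= end_day, ]
  if (nrow(win) == 0) stop("mean_hourly_profile: empty window")
  prof <- win |>
    dplyr::group_by(.data$hour) |>
    dplyr::summarise(mean_n = mean(.data$n), .groups = "drop")
  attr(prof, "n_days") <- length(unique(win$day))
  prof
}

#' First and last movement times per day
#'
#' Estimates the morning rise and evening retire routine from motion
#' events alone: the first movement at or after `earliest_cutoff` and the
#' last movement before `latest_cutoff`, per civil day. Missing when no
#' event qualifies.
#'
#' @param events motion events, one location.
#' @param earliest_cutoff clock time (`"HH:MM"`) from which the first
#'   movement is sought; default `"05:00"` (use `"04:00"` for earlier
#'   risers).
#' @param latest_cutoff exclusive clock bound for the last movement;
#'   default `"24:00"` (midnight).
#' @param span optional Date range to cover (days with no events appear
#'   with missing times).
#' @return tibble `day`, `first_movement_s`, `last_movement_s`
#'   (seconds since midnight, NA when missing).
#' @export
first_last_movement <- function(events, earliest_cutoff = "05:00",
                                latest_cutoff = "24:00", span = NULL) {
  lo <- parse_clock(earliest_cutoff)
  hi <- parse_clock(latest_cutoff)
  if (is.null(span)) {
    if (nrow(events) == 0) stop("first_last_movement: no events and no span")
    span <- range(civil_day(events$timestamp))
  }
  days <- seq(span[1], span[2], by = "day")
  tod <- time_of_day_s(events$timestamp)
  dd <- civil_day(events$timestamp)
  per_day <- lapply(days, function(d) {
    t <- tod[dd == d]
    first <- t[t >= lo & t < hi]
    last <- t[t < hi]
    tibble::tibble(
      day = d,
      first_movement_s = if (length(first)) min(first) else NA_real_,
      last_movement_s = if (length(last)) max(last) else NA_real_)
  })
  dplyr::bind_rows(per_day)
}

#' Time-to-next-move quantiles per day
#'
#' The intervals between consecutive motion events within a civil day form
#' that day's time-to-next-move distribution; its quantiles (10th, median,
#' 90th by default) summarise activity tempo. Days with fewer than
#' `min_moves` events are excluded (returned with NA quantiles) — 30 is the
#' usual threshold, with 15 or 10 used for sparser subjects. Quantiles use
#' linear interpolation between order statistics.
#'
#' @param events motion events, sorted.
#' @param min_moves minimum events for a day to qualify (default 30).
#' @param probs quantile levels (default 0.1, 0.5, 0.9).
#' @param span optional Date range to cover.
#' @return tibble `day`, `n_events`, one column `ttnm_q<100p>` in seconds
#'   per level.
#' @export
time_to_next_move_quantiles <- function(events, min_moves = 30,
                                        probs = c(0.1, 0.5, 0.9),
                                        span = NULL) {
  if (is.null(span)) {
    if (nrow(events) == 0) stop("time_to_next_move_quantiles: no events")
    span <- range(civil_day(events$timestamp))
  }
  days <- seq(span[1], span[2], by = "day")
  qnames <- paste0("ttnm_q", round(100 * probs))
  dd <- civil_day(events$timestamp)
  per_day <- lapply(days, function(d) {
    t <- sort(as.numeric(events$timestamp[dd == d]))
    row <- tibble::tibble(day = d, n_events = length(t))
    if (length(t) >= min_moves && length(t) >= 2) {
      q <- stats::quantile(diff(t), probs = probs, names = FALSE, type = 7)
    } else {
      q <- rep(NA_real_, length(probs))
    }
    row[qnames] <- as.list(q)
    row
  })
  dplyr::bind_rows(per_day)
}

#' Occupancy intervals from bed/chair usage events
#'
#' Pairs consecutive `usage_started` / `usage_ended` messages from one
#' pressure sensor into occupancy intervals. The sensors debounce at the
#' hardware level (a state change is only sent after 30 s in the new
#' state); the same rule is re-applied defensively here, merging an
#' ended-to-started gap shorter than `merge_gap_s`, so hardware-filtered
#' and raw streams behave identically. A trailing unmatched start is
#' closed at the stream end and flagged truncated; orphan end events are
#' dropped and counted in the attached anomaly report.
#'
#' @param events usage events for one sensor, sorted by time.
#' @param merge_gap_s gaps shorter than this (seconds) are merged
#'   (default 30).
#' @return tibble `start`, `end` (POSIXct), `source` (`bed`/`chair`),
#'   `truncated`; attribute `anomalies` lists dropped orphans and repeats.
#' @export
occupancy_intervals <- function(events, merge_gap_s = 30) {
  ev <- events[events$kind %in% c("usage_started", "usage_ended"), ]
  ev <- ev[order(ev$timestamp), ]
  source <- if (nrow(ev) > 0 && any(ev$location == "chair")) "chair" else "bed"
  open <- NULL
  starts <- ends <- as.POSIXct(character(), tz = "UTC")
  truncated <- logical()
  n_orphan_end <- 0L
  n_repeat_start <- 0L
  for (i in seq_len(nrow(ev))) {
    k <- ev$kind[i]; t <- ev$timestamp[i]
    if (k == "usage_started") {
      if (is.null(open)) open <- t else n_repeat_start <- n_repeat_start + 1L
    } else {
      if (is.null(open)) {
        n_orphan_end <- n_orphan_end + 1L
      } else {
        starts <- c(starts, open); ends <- c(ends, t)
        truncated <- c(truncated, FALSE)
        open <- NULL
      }
    }
  }
  if (!is.null(open)) {
    starts <- c(starts, open)
    ends <- c(ends, max(ev$timestamp))
    truncated <- c(truncated, TRUE)
  }
  iv <- tibble::tibble(start = starts, end = ends, truncated = truncated)
  iv <- iv[iv$end >= iv$start, ]
  # defensive re-debounce: merge brief exits
  if (nrow(iv) > 1) {
    keep <- rep(TRUE, nrow(iv))
    for (i in 2:nrow(iv)) {
      prev <- max(which(keep[1:(i - 1)]))
      gap <- as.numeric(iv$start[i]) - as.numeric(iv$end[prev])
      if (gap < merge_gap_s) {
        iv$end[prev] <- iv$end[i]
        iv$truncated[prev] <- iv$truncated[prev] || iv$truncated[i]
        keep[i] <- FALSE
      }
    }
    iv <- iv[keep, ]
  }
  iv$source <- source
  iv <- iv[, c("start", "end", "source", "truncated")]
  attr(iv, "anomalies") <- list(orphan_ends = n_orphan_end,
                                repeat_starts = n_repeat_start)
  iv
}

# Split intervals at civil midnights; returns start/end/source/truncated
# with every piece inside one civil day.
split_at_midnight <- function(intervals) {
  if (nrow(intervals) == 0) return(intervals)
  pieces <- purrr::pmap(intervals, function(start, end, source, truncated) {
    bounds <- as.numeric(start)
    d <- civil_day(start)
    while (TRUE) {
      nxt <- as.numeric(as.POSIXct(paste0(d + 1, "T00:00:00"),
                                   format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
      if (nxt >= as.numeric(end)) break
      bounds <- c(bounds, nxt)
      d <- d + 1
    }
    bounds <- c(bounds, as.numeric(end))
    tibble::tibble(
      start = as.POSIXct(bounds[-length(bounds)], tz = "UTC"),
      end = as.POSIXct(bounds[-1], tz = "UTC"),
      source = source, truncated = truncated)
  })
  dplyr::bind_rows(pieces)
}

#' Total daily occupancy
#'
#' Accumulates occupancy intervals into per-day totals, splitting any
#' interval that crosses civil midnight so each day receives only its own
#' portion. Days inside the span with no occupancy report 0.
#'
#' @param intervals output of [occupancy_intervals()].
#' @param span optional Date range to cover.
#' @return tibble `day`, `occupancy_s`.
#' @export
daily_occupancy <- function(intervals, span = NULL) {
  if (nrow(intervals) == 0 && is.null(span))
    return(tibble::tibble(day = as.Date(character()), occupancy_s = numeric()))
  pieces <- split_at_midnight(intervals)
  if (is.null(span))
    span <- range(c(civil_day(intervals$start), civil_day(intervals$end)))
  days <- seq(span[1], span[2], by = "day")
  totals <- if (nrow(pieces) > 0) {
    pieces |>
      dplyr::mutate(day = civil_day(.data$start),
                    dur = as.numeric(.data$end) - as.numeric(.data$start)) |>
      dplyr::group_by(.data$day) |>
      dplyr::summarise(occupancy_s = sum(.data$dur), .groups = "drop")
  } else {
    tibble::tibble(day = as.Date(character()), occupancy_s = numeric())
  }
  tibble::tibble(day = days) |>
    dplyr::left_join(totals, by = "day") |>
    dplyr::mutate(occupancy_s = tidyr::replace_na(.data$occupancy_s, 0))
}

#' Longest occupancies per day
#'
#' Orders each day's occupancy spells by decreasing length and keeps the
#' top `k` (five by default) — the stacked lengths profile uninterrupted
#' sleep and hence sleep quality. Intervals are split at midnight first,
#' consistently with [daily_occupancy()].
#'
#' @param intervals output of [occupancy_intervals()].
#' @param day optional single day; if given, returns a descending numeric
#'   vector of durations (seconds) for that day.
#' @param k how many spells to keep (default 5).
#' @return tibble `day`, `rank`, `duration_s` (or a numeric vector when
#'   `day` is given).
#' @export
longest_occupancies <- function(intervals, day = NULL, k = 5) {
  pieces <- split_at_midnight(intervals)
  if (nrow(pieces) == 0) {
    if (!is.null(day)) return(numeric(0))
    return(tibble::tibble(day = as.Date(character()), rank = integer(),
                          duration_s = numeric()))
  }
  tab <- pieces |>
    dplyr::mutate(day = civil_day(.data$start),
                  duration_s = as.numeric(.data$end) -
                    as.numeric(.data$start)) |>
    dplyr::group_by(.data$day) |>
    dplyr::arrange(dplyr::desc(.data$duration_s), .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("day", "rank", "duration_s")
  if (!is.null(day)) {
    d <- as.Date(day)
    return(tab$duration_s[tab$day == d])
  }
  tab
}

#' Assemble per-day habits features
#'
#' One row per civil day combining the habits-parameter families: period
#' movement counts under a scheme, first/last movement times,
#' time-to-next-move quantiles, total occupancy and the k longest
#' occupancy spells.
#'
#' @param motion_events motion events (typically living room).
#' @param usage_events bed/chair usage events, or NULL.
#' @param scheme a [period_scheme()] (default the three-period scheme).
#' @param min_moves threshold for time-to-next-move days (default 30).
#' @param earliest_cutoff first-movement clock cutoff (default "05:00").
#' @param k_occupancy number of longest spells kept (default 5).
#' @return wide tibble keyed by `day`.
#' @export
day_features <- function(motion_events, usage_events = NULL,
                         scheme = scheme_v2_three_period(), min_moves = 30,
                         earliest_cutoff = "05:00", k_occupancy = 5) {
  span <- range(civil_day(motion_events$timestamp))
  hc <- hourly_counts(motion_events, span = span)
  pc <- period_counts(hc, scheme) |>
    dplyr::select("day", "period", "n") |>
    tidyr::pivot_wider(names_from = "period", values_from = "n",
                       names_prefix = "n_")
  fl <- first_last_movement(motion_events, earliest_cutoff = earliest_cutoff,
                            span = span)
  tt <- time_to_next_move_quantiles(motion_events, min_moves = min_moves,
                                    span = span)
  out <- pc |>
    dplyr::left_join(fl, by = "day") |>
    dplyr::left_join(tt, by = "day")
  if (!is.null(usage_events) && nrow(usage_events) > 0) {
    iv <- occupancy_intervals(usage_events)
    occ <- daily_occupancy(iv, span = span)
    top <- longest_occupancies(iv, k = k_occupancy) |>
      tidyr::pivot_wider(names_from = "rank", values_from = "duration_s",
                         names_prefix = "occ_top")
    out <- out |>
      dplyr::left_join(occ, by = "day") |>
      dplyr::left_join(top, by = "day")
  }
  out
}
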