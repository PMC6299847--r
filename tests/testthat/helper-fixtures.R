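# In-code fixtures and independent brute-force oracles used across the
# suite. The oracles deliberately avoid the package's own code paths.

mk_ts <- function(date, clock) {
  parse_ts(paste0(date, "T", clock))
}

motion_events <- function(timestamps, location = "living_room",
                          sensor_id = "pir1") {
  tibble::tibble(sensor_id = sensor_id, location = location,
                 kind = "motion", timestamp = timestamps)
}

usage_events <- function(timestamps, kinds, location = "bed",
                         sensor_id = "bed1") {
  tibble::tibble(sensor_id = sensor_id, location = location,
                 kind = kinds, timestamp = timestamps)
}

random_motion_day <- function(date, n, sensor_id = "pir1") {
  secs <- sort(round(runif(n, 0, 86399)))
  motion_events(mk_ts(date, "00:00:00") + secs, sensor_id = sensor_id)
}

# -- oracles ----------------------------------------------------------

# per-hour tally by explicit loop over events
oracle_hour_tally <- function(secs_of_day) {
  out <- integer(24)
  for (s in secs_of_day) {
    h <- floor(s / 3600) + 1
    out[h] <- out[h] + 1L
  }
  out
}

# quantile by explicit sort-and-interpolate between order statistics
# (same definition as type-7: position 1 + p*(n-1))
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  pos <- 1 + p * (n - 1)
  lo <- floor(pos); hi <- ceiling(pos)
  x[lo] + (pos - lo) * (x[hi] - x[lo])
}

# per-day occupancy by 1 s membership counting
oracle_daily_occupancy <- function(starts, ends, days) {
  vapply(days, function(d) {
    d0 <- as.numeric(mk_ts(d, "00:00:00"))
    secs <- d0 + 0:86399
    inside <- rep(FALSE, length(secs))
    for (i in seq_along(starts)) {
      inside <- inside | (secs >= as.numeric(starts[i]) &
                            secs < as.numeric(ends[i]))
    }
    sum(inside)
  }, numeric(1))
}

# trailing-window mean/sd band by explicit summation
oracle_band <- function(days, values, d, window_days = 15, k = 2,
                        min_obs = 5) {
  sel <- days >= (d - window_days) & days <= (d - 1)
  v <- values[sel]
  n <- length(v)
  if (n < min_obs) return(NULL)
  m <- sum(v) / n
  s <- if (n > 1) sqrt(sum((v - m)^2) / (n - 1)) else 0
  c(lower = m - k * s, upper = m + k * s, mean = m, sd = s)
}

# day-by-day loop implementation of the adaptive alert procedure
oracle_adaptive_alerts <- function(counts, window_days = 15, k = 2,
                                   min_obs = 5) {
  fired <- logical(length(counts))
  for (i in seq_along(counts)) {
    win <- counts[max(1, i - window_days):(i - 1)]
    if (i == 1) win <- numeric(0)
    if (length(win) < min_obs) next
    m <- mean(win); s <- sd(win)
    fired[i] <- counts[i] > m + k * s || counts[i] < m - k * s
  }
  fired
}
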