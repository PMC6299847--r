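test_that("hourly bins are half-open and zero days appear", {
  ev <- motion_events(mk_ts("2023-01-05", c("07:05:00", "07:59:59",
                                            "08:00:00")))
  hc <- hourly_counts(ev)
  expect_equal(hc$n[hc$hour == 7], 2)
  expect_equal(hc$n[hc$hour == 8], 1)
  expect_equal(sum(hc$n), 3)

  hc <- hourly_counts(motion_events(parse_ts(character(0))),
                      span = as.Date(c("2023-01-05", "2023-01-05")))
  expect_equal(nrow(hc), 24)
  expect_true(all(hc$n == 0))

  expect_error(hourly_counts(usage_events(mk_ts("2023-01-05", "08:00:00"),
                                          "usage_started")), "motion")
})

test_that("hourly counts match a brute-force tally on random days", {
  set.seed(11)
  for (r in 1:30) {
    ev <- random_motion_day("2023-04-02", sample(50:1000, 1))
    hc <- hourly_counts(ev)
    expect_equal(hc$n, oracle_hour_tally(time_of_day_s(ev$timestamp)))
  }
})

test_that("period counts conserve the all-day total and handle wrap", {
  set.seed(12)
  ev <- dplyr::bind_rows(lapply(0:9, function(i)
    random_motion_day(as.Date("2023-04-01") + i, 200)))
  hc <- hourly_counts(ev)
  v1 <- period_counts(hc, scheme_v1_four_period())
  v2 <- period_counts(hc, scheme_v2_three_period())
  tot_v1 <- v1 |> dplyr::group_by(day) |> dplyr::summarise(n = sum(n))
  all_day <- v2[v2$period == "all_day", ]
  expect_equal(tot_v1$n, all_day$n)
  per_day <- hc |> dplyr::group_by(day) |> dplyr::summarise(n = sum(n))
  expect_equal(all_day$n, per_day$n)

  # night period on day d = hours 22-23 of d plus 0-5 of d+1
  night <- v2[v2$period == "night" & v2$day == as.Date("2023-04-03"), ]
  manual <- sum(hc$n[hc$day == as.Date("2023-04-03") & hc$hour >= 22]) +
    sum(hc$n[hc$day == as.Date("2023-04-04") & hc$hour < 6])
  expect_equal(night$n, manual)
  # the final day's night period is incomplete (no next day)
  expect_false(v2$complete[v2$period == "night" &
                             v2$day == max(v2$day)])
})

test_that("uniform activity gives equal six-hour period counts", {
  secs <- rep(3600 * (0:23) + 1800, each = 2)   # 2 events per hour
  ev <- motion_events(mk_ts("2023-04-01", "00:00:00") + secs)
  pc <- period_counts(hourly_counts(ev), scheme_v1_four_period())
  expect_true(all(pc$n == 12))
})

test_that("non-whole-hour period boundaries are rejected", {
  expect_error(period_scheme("bad", tibble::tibble(
    label = "x", start_hour = 1.5, end_hour = 3)), "whole hours")
})

test_that("mean hourly profile equals column means over the window", {
  set.seed(13)
  ev <- dplyr::bind_rows(lapply(0:19, function(i)
    random_motion_day(as.Date("2023-05-01") + i, 150)))
  hc <- hourly_counts(ev)
  prof <- mean_hourly_profile(hc, window_days = 20)
  manual <- vapply(0:23, function(h) mean(hc$n[hc$hour == h]), numeric(1))
  expect_equal(prof$mean_n, manual)
  expect_equal(attr(prof, "n_days"), 20)

  # 20 identical days reproduce any single day
  one <- hc[hc$day == min(hc$day), ]
  rep20 <- dplyr::bind_rows(lapply(0:19, function(i)
    dplyr::mutate(one, day = day + i)))
  prof <- mean_hourly_profile(rep20)
  expect_equal(prof$mean_n, as.numeric(one$n))
})

test_that("first/last movement respects cutoffs and missingness", {
  ev <- motion_events(mk_ts("2023-06-01", c("04:30:00", "05:10:00",
                                            "21:50:00")))
  fl <- first_last_movement(ev, earliest_cutoff = "05:00")
  expect_equal(fl$first_movement_s, parse_clock("05:10"))
  expect_equal(fl$last_movement_s, parse_clock("21:50"))

  fl <- first_last_movement(ev, earliest_cutoff = "04:00")
  expect_equal(fl$first_movement_s, parse_clock("04:30"))

  ev2 <- motion_events(mk_ts("2023-06-01", "03:00:00"))
  fl <- first_last_movement(ev2, earliest_cutoff = "05:00",
                            latest_cutoff = "04:00")
  expect_true(is.na(fl$first_movement_s))
})

test_that("time-to-next-move quantiles: degeneracy, exclusion, oracle", {
  # 40 events exactly 10 minutes apart
  ev <- motion_events(mk_ts("2023-06-01", "06:00:00") + 600 * (0:39))
  tt <- time_to_next_move_quantiles(ev)
  expect_equal(c(tt$ttnm_q10, tt$ttnm_q50, tt$ttnm_q90), c(600, 600, 600))
  expect_equal(tt$n_events, 40)

  # below the threshold the day is excluded; a lower threshold admits it
  ev <- motion_events(mk_ts("2023-06-01", "06:00:00") + 600 * (0:19))
  expect_true(is.na(time_to_next_move_quantiles(ev)$ttnm_q50))
  expect_false(is.na(time_to_next_move_quantiles(ev,
                                                 min_moves = 15)$ttnm_q50))

  set.seed(21)
  for (r in 1:30) {
    ev <- random_motion_day("2023-06-02", 100)
    tt <- time_to_next_move_quantiles(ev)
    gaps <- diff(sort(as.numeric(ev$timestamp)))
    expect_equal(tt$ttnm_q10, oracle_quantile(gaps, 0.1))
    expect_equal(tt$ttnm_q50, oracle_quantile(gaps, 0.5))
    expect_equal(tt$ttnm_q90, oracle_quantile(gaps, 0.9))
    expect_true(tt$ttnm_q10 <= tt$ttnm_q50 && tt$ttnm_q50 <= tt$ttnm_q90)
  }
})

test_that("quantiles are invariant under uniform time translation", {
  set.seed(22)
  secs <- sort(round(runif(80, 0, 79000)))   # leaves room to shift
  ev <- motion_events(mk_ts("2023-06-03", "00:00:00") + secs)
  shift <- motion_events(ev$timestamp + 3600)  # still within the day
  a <- time_to_next_move_quantiles(ev)
  b <- time_to_next_move_quantiles(shift)
  expect_equal(a$ttnm_q90, b$ttnm_q90)
})

test_that("occupancy pairing, 30 s merge and anomaly handling", {
  # overnight interval
  ev <- usage_events(c(mk_ts("2023-07-01", "23:00:00"),
                       mk_ts("2023-07-02", "07:00:00")),
                     c("usage_started", "usage_ended"))
  iv <- occupancy_intervals(ev)
  expect_equal(as.numeric(iv$end) - as.numeric(iv$start), 8 * 3600)

  # brief exit under 30 s is merged away
  t0 <- mk_ts("2023-07-01", "22:00:00")
  ev <- usage_events(t0 + c(0, 1000, 1020, 4600),
                     c("usage_started", "usage_ended",
                       "usage_started", "usage_ended"))
  iv <- occupancy_intervals(ev)
  expect_equal(nrow(iv), 1)
  expect_equal(as.numeric(iv$end) - as.numeric(iv$start), 4600)
  # a 30 s gap is kept (strict merge rule)
  ev <- usage_events(t0 + c(0, 1000, 1030, 4600),
                     c("usage_started", "usage_ended",
                       "usage_started", "usage_ended"))
  expect_equal(nrow(occupancy_intervals(ev)), 2)

  # trailing start truncates at stream end; orphan end dropped
  ev <- usage_events(t0 + c(0, 100, 5000),
                     c("usage_ended", "usage_started", "usage_started"))
  iv <- occupancy_intervals(ev)
  expect_true(any(iv$truncated))
  expect_equal(attr(iv, "anomalies")$orphan_ends, 1)

  # alternating valid pairs stay disjoint
  ev <- usage_events(t0 + c(0, 100, 200, 300, 400, 500),
                     rep(c("usage_started", "usage_ended"), 3))
  iv <- occupancy_intervals(ev)
  expect_equal(nrow(iv), 3)
  expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)]))
})

test_that("daily occupancy splits at midnight and matches the 1 s oracle", {
  ev <- usage_events(c(mk_ts("2023-07-01", "23:00:00"),
                       mk_ts("2023-07-02", "07:00:00")),
                     c("usage_started", "usage_ended"))
  occ <- daily_occupancy(occupancy_intervals(ev))
  expect_equal(occ$occupancy_s[occ$day == as.Date("2023-07-01")], 3600)
  expect_equal(occ$occupancy_s[occ$day == as.Date("2023-07-02")], 25200)

  expect_equal(nrow(daily_occupancy(occupancy_intervals(
    usage_events(parse_ts(character(0)), character(0))))), 0)

  set.seed(31)
  for (r in 1:10) {
    # random disjoint intervals over three days
    bounds <- sort(sample(0:(3 * 86400 - 1), 12))
    starts <- mk_ts("2023-07-10", "00:00:00") + bounds[c(TRUE, FALSE)]
    ends <- mk_ts("2023-07-10", "00:00:00") + bounds[c(FALSE, TRUE)]
    iv <- tibble::tibble(start = starts, end = ends, source = "bed",
                         truncated = FALSE)
    days <- as.Date("2023-07-10") + 0:2
    occ <- daily_occupancy(iv, span = range(days))
    expect_equal(occ$occupancy_s,
                 oracle_daily_occupancy(starts, ends, days))
  }
})

test_that("occupancy totals are invariant to ordering and interior splits", {
  t0 <- mk_ts("2023-07-20", "21:00:00")
  iv <- tibble::tibble(start = t0 + c(0, 7200, 20000),
                       end = t0 + c(3600, 10000, 30000),
                       source = "bed", truncated = FALSE)
  base <- daily_occupancy(iv)
  shuffled <- daily_occupancy(iv[c(3, 1, 2), ])
  expect_equal(base, shuffled)
  # split the second interval at an interior point
  split <- tibble::tibble(
    start = t0 + c(0, 7200, 9000, 20000),
    end = t0 + c(3600, 9000, 10000, 30000),
    source = "bed", truncated = FALSE)
  expect_equal(daily_occupancy(split)$occupancy_s, base$occupancy_s)
})

test_that("longest occupancies are ordered, capped at k, split-consistent", {
  t0 <- mk_ts("2023-08-01", "01:00:00")
  iv <- tibble::tibble(start = t0 + c(0, 4 * 3600, 10 * 3600),
                       end = t0 + c(3 * 3600, 9 * 3600, 11 * 3600),
                       source = "bed", truncated = FALSE)
  top <- longest_occupancies(iv, day = as.Date("2023-08-01"))
  expect_equal(top, c(5, 3, 1) * 3600)

  iv7 <- tibble::tibble(start = t0 + 3600 * seq(0, 18, by = 3),
                        end = t0 + 3600 * seq(0, 18, by = 3) +
                          600 * (1:7),
                        source = "bed", truncated = FALSE)
  top <- longest_occupancies(iv7, day = as.Date("2023-08-01"))
  expect_length(top, 5)
  expect_true(all(diff(top) <= 0))

  expect_equal(longest_occupancies(iv, day = as.Date("2023-09-01")),
               numeric(0))
})

test_that("day_features assembles all families keyed by day", {
  set.seed(41)
  motion <- dplyr::bind_rows(lapply(0:6, function(i)
    random_motion_day(as.Date("2023-09-01") + i, 120)))
  usage <- usage_events(
    c(mk_ts("2023-09-01", "22:00:00"), mk_ts("2023-09-02", "06:30:00"),
      mk_ts("2023-09-02", "22:15:00"), mk_ts("2023-09-03", "06:10:00")),
    rep(c("usage_started", "usage_ended"), 2))
  df <- day_features(motion, usage)
  expect_equal(nrow(df), 7)
  expect_true(all(c("n_all_day", "n_night", "n_morning",
                    "first_movement_s", "last_movement_s", "ttnm_q50",
                    "occupancy_s", "occ_top1") %in% names(df)))
  # re-run is identical (pure function of the stream)
  expect_identical(df, day_features(motion, usage))
})
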