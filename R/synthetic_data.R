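# Seeded generator of frail-elderly home-monitoring datasets: PIR motion
# events from a circadian inhomogeneous Poisson process gated by a
# wake/sleep routine, bed-sensor usage events from a nightly sleep block
# with interruptions, and daily vitals with baseline noise, episode
# effects and imperfect compliance. Every run records its ground truth so
# pipeline recovery and alerting metrics can be scored exactly.

#' Default circadian movement-rate profile
#'
#' Expected living-room PIR events per hour while awake: quiet night,
#' breakfast and evening peaks, totalling roughly 60-70 events over a
#' typical waking day (the magnitude seen in real deployments).
#'
#' @return numeric vector of 24 hourly rates (events/hour).
#' @export
default_hourly_rate <- function() {
  c(0, 0, 0, 0, 0, 0.5,           # 00-05: asleep
    3, 6, 8, 5, 4, 4,             # 06-11: rise, breakfast, morning
    6, 4, 3, 3, 5, 8,             # 12-17: lunch, afternoon, dinner prep
    6, 4, 3, 2, 1, 0.5)           # 18-23: evening, retire
}

#' Routine profile of a simulated subject
#'
#' @param wake_time mean wake clock time (`"HH:MM"`), default 06:30.
#' @param wake_sd_min SD of wake time, minutes.
#' @param bed_time mean bed clock time, default 22:00.
#' @param bed_sd_min SD of bed time, minutes.
#' @param hourly_rate 24 expected motion events/hour while awake.
#' @param night_rate motion events/hour while in bed (bedroom sensor),
#'   near zero for a sound sleeper.
#' @param interruptions_per_night mean number of sleep interruptions.
#' @param interruption_mean_min mean interruption length, minutes.
#' @return list of class `routine_profile`.
#' @export
routine_profile <- function(wake_time = "06:30", wake_sd_min = 20,
                            bed_time = "22:00", bed_sd_min = 20,
                            hourly_rate = default_hourly_rate(),
                            night_rate = 0.2,
                            interruptions_per_night = 1,
                            interruption_mean_min = 10) {
  stopifnot(length(hourly_rate) == 24, all(hourly_rate >= 0),
            night_rate >= 0, interruptions_per_night >= 0,
            interruption_mean_min > 0)
  wake_s <- parse_clock(wake_time); bed_s <- parse_clock(bed_time)
  if (!(wake_s < bed_s)) stop("routine_profile: wake must precede bed time")
  structure(list(wake_s = wake_s, wake_sd_s = wake_sd_min * 60,
                 bed_s = bed_s, bed_sd_s = bed_sd_min * 60,
                 hourly_rate = hourly_rate, night_rate = night_rate,
                 interruptions_per_night = interruptions_per_night,
                 interruption_mean_s = interruption_mean_min * 60),
            class = "routine_profile")
}

#' Vitals profile of a simulated subject
#'
#' Per-kind baseline mean and SD, plus the measurement-compliance
#' structure: the daily probability that the subject takes a reading at
#' all, and the probability that a compliant day has more than one
#' reading. Compliance in real deployments is generally over 60 %; the
#' default emulates a reasonably compliant subject.
#'
#' @param baselines named list `kind = c(mean, sd)` for any subset of the
#'   vital kinds.
#' @param compliance_prob daily probability of measuring (default 0.8).
#' @param multi_read_prob probability of a second reading on a compliant
#'   day (default 0.15).
#' @return list of class `vitals_profile`.
#' @export
vitals_profile <- function(baselines = list(
                             systolic_mmHg = c(145, 8),
                             diastolic_mmHg = c(80, 6),
                             pulse_bpm = c(72, 5),
                             spo2_percent = c(94, 1.5),
                             weight_kg = c(70, 0.3)),
                           compliance_prob = 0.8, multi_read_prob = 0.15) {
  stopifnot(compliance_prob >= 0, compliance_prob <= 1,
            multi_read_prob >= 0, multi_read_prob <= 1)
  stopifnot(all(names(baselines) %in% vital_kinds),
            all(vapply(baselines, function(b) b[2] >= 0, logical(1))))
  structure(list(baselines = baselines, compliance_prob = compliance_prob,
                 multi_read_prob = multi_read_prob),
            class = "vitals_profile")
}

episode_kinds <- c("hypertensive", "copd_exacerbation", "fall_inactivity",
                   "nocturnal_restlessness", "absence", "visitor")

#' A scripted episode with known effects
#'
#' Episodes perturb the routine and/or vitals over a day range and revert
#' afterwards, unless marked `progressive`, in which case numeric effects
#' ramp linearly from zero at onset to full strength on the final day.
#' Recognised effects: `rate_mult`, `night_rate_add`, `interruptions_add`,
#' `occupancy_mult`, `bed_shift_min`, `wake_shift_min`, `absent_hours`,
#' `visitor_hours`, `visitor_mult`, `spo2_delta`, `spo2_max`,
#' `systolic_delta`, `diastolic_delta`, `pulse_delta`, `weight_delta`,
#' `compliance_prob`.
#'
#' @param kind one of `hypertensive`, `copd_exacerbation`,
#'   `fall_inactivity`, `nocturnal_restlessness`, `absence`, `visitor`.
#' @param start_day first affected day index (1-based).
#' @param duration_days length in days.
#' @param effects named list of effect values.
#' @param progressive ramp numeric effects over the duration?
#' @return list of class `episode`.
#' @export
episode <- function(kind, start_day, duration_days, effects = list(),
                    progressive = FALSE) {
  kind <- match.arg(kind, episode_kinds)
  stopifnot(start_day >= 1, duration_days >= 1)
  structure(list(kind = kind, start_day = start_day,
                 duration_days = duration_days, effects = effects,
                 progressive = progressive),
            class = "episode")
}

base_effects <- function() {
  list(rate_mult = 1, night_rate_add = 0, interruptions_add = 0,
       occupancy_mult = 1, bed_shift_min = 0, wake_shift_min = 0,
       absent_hours = integer(0), visitor_hours = integer(0),
       visitor_mult = 1, spo2_delta = 0, spo2_max = Inf,
       systolic_delta = 0, diastolic_delta = 0, pulse_delta = 0,
       weight_delta = 0, compliance_prob = NA_real_)
}

# Combined effect state on day index d: multiplicative effects multiply,
# additive effects sum, caps take the minimum. Progressive episodes scale
# linearly from onset to full effect on their last day.
effects_for_day <- function(episodes, d) {
  eff <- base_effects()
  for (ep in episodes) {
    last <- ep$start_day + ep$duration_days - 1
    if (d < ep$start_day || d > last) next
    frac <- if (ep$progressive && ep$duration_days > 1)
      (d - ep$start_day) / (ep$duration_days - 1) else 1
    e <- ep$effects
    scale_mult <- function(m) if (frac == 1) m else 1 + frac * (m - 1)
    if (!is.null(e$rate_mult)) eff$rate_mult <- eff$rate_mult *
        scale_mult(e$rate_mult)
    if (!is.null(e$occupancy_mult)) eff$occupancy_mult <- eff$occupancy_mult *
        scale_mult(e$occupancy_mult)
    if (!is.null(e$visitor_mult)) eff$visitor_mult <- eff$visitor_mult *
        scale_mult(e$visitor_mult)
    for (nm in c("night_rate_add", "interruptions_add", "bed_shift_min",
                 "wake_shift_min", "spo2_delta", "systolic_delta",
                 "diastolic_delta", "pulse_delta", "weight_delta"))
      if (!is.null(e[[nm]])) eff[[nm]] <- eff[[nm]] + frac * e[[nm]]
    if (!is.null(e$spo2_max)) eff$spo2_max <- min(eff$spo2_max, e$spo2_max)
    if (!is.null(e$absent_hours))
      eff$absent_hours <- union(eff$absent_hours, e$absent_hours)
    if (!is.null(e$visitor_hours))
      eff$visitor_hours <- union(eff$visitor_hours, e$visitor_hours)
    if (!is.null(e$compliance_prob))
      eff$compliance_prob <- if (is.na(eff$compliance_prob))
        e$compliance_prob else max(eff$compliance_prob, e$compliance_prob)
  }
  eff
}

day_ts <- function(date, seconds) {
  as.POSIXct(paste0(date, "T00:00:00"), format = "%Y-%m-%dT%H:%M:%S",
             tz = "UTC") + seconds
}

rnorm_clamped <- function(n, mean, sd, width = 3) {
  pmin(pmax(stats::rnorm(n, mean, sd), mean - width * sd), mean + width * sd)
}

#' Simulate one monitored patient
#'
#' Generates `n_days` of home monitoring under a fixed seed:
#' * living-room motion events from an inhomogeneous Poisson process with
#'   piecewise-constant hourly rates, gated by the day's realised
#'   wake/bed times and modified by episode effects (absence hours go
#'   silent, visitor hours multiply the rate);
#' * bedroom motion during the in-bed window at the (episode-modified)
#'   night rate;
#' * bed-sensor `usage_started`/`usage_ended` events from the nightly
#'   sleep block minus Poisson-count, exponential-length interruptions,
#'   pre-debounced so no emitted state persists under 30 s;
#' * vitals on compliant days as baseline + episode delta + Gaussian
#'   noise, occasionally twice a day.
#'
#' Identical inputs and seed give byte-identical output.
#'
#' @param routine a [routine_profile()].
#' @param vitals a [vitals_profile()].
#' @param episodes list of [episode()] objects.
#' @param n_days number of monitored days (>= 1).
#' @param seed integer seed fixing all randomness.
#' @param patient_id label stamped into sensor ids.
#' @param start_date first monitored civil day.
#' @return list with `events` (sensor-event tibble), `vitals`
#'   (reading tibble) and `truth` (ground-truth list: per-day table,
#'   episode calendar, per-day true vital means, expected occupancy).
#' @export
simulate_patient <- function(routine, vitals, episodes = list(), n_days,
                             seed, patient_id = "p1",
                             start_date = as.Date("2023-01-02")) {
  stopifnot(inherits(routine, "routine_profile"),
            inherits(vitals, "vitals_profile"), n_days >= 1)
  if (any(routine$hourly_rate < 0)) stop("negative rate")
  set.seed(as.integer(seed %% 2147483647))
  dates <- start_date + seq_len(n_days) - 1
  eff <- lapply(seq_len(n_days + 1), function(d)
    effects_for_day(episodes, min(d, n_days)))

  # realised wake/bed clock times, day 1..n_days+1 (the extra wake closes
  # the final night)
  wake_s <- rnorm_clamped(n_days + 1, routine$wake_s, routine$wake_sd_s)
  bed_s <- rnorm_clamped(n_days + 1, routine$bed_s, routine$bed_sd_s)
  for (d in seq_len(n_days + 1)) {
    wake_s[d] <- wake_s[d] + eff[[d]]$wake_shift_min * 60
    bed_s[d] <- bed_s[d] + eff[[d]]$bed_shift_min * 60
    if (bed_s[d] <= wake_s[d] + 3600) bed_s[d] <- wake_s[d] + 3600
    bed_s[d] <- min(bed_s[d], 86100)
    wake_s[d] <- max(wake_s[d], 300)
  }

  span_end <- day_ts(start_date + n_days, 0)

  # --- daytime living-room motion -----------------------------------
  motion <- list()
  for (d in seq_len(n_days)) {
    e <- eff[[d]]
    times <- numeric(0)
    for (h in 0:23) {
      lo <- max(h * 3600, wake_s[d]); hi <- min((h + 1) * 3600, bed_s[d])
      if (hi <= lo) next
      if (h %in% e$absent_hours) next
      rate <- routine$hourly_rate[h + 1] * e$rate_mult
      if (h %in% e$visitor_hours) rate <- rate * e$visitor_mult
      lambda <- rate * (hi - lo) / 3600
      n <- stats::rpois(1, lambda)
      if (n > 0) times <- c(times, stats::runif(n, lo, hi))
    }
    if (length(times) > 0)
      motion[[length(motion) + 1]] <- tibble::tibble(
        sensor_id = paste0(patient_id, "_pir_lr"), location = "living_room",
        kind = "motion", timestamp = day_ts(dates[d], sort(times)))
  }

  # --- nightly sleep block, interruptions, bed events, night motion --
  night_rows <- list()
  bed_events <- list()
  night_motion <- list()
  for (d in seq_len(n_days)) {
    e <- eff[[d]]
    t0 <- as.numeric(day_ts(dates[d], bed_s[d]))
    t1 <- as.numeric(day_ts(dates[d] + 1, wake_s[d + 1]))
    dur <- t1 - t0
    mult <- min(e$occupancy_mult, eff[[min(d + 1, n_days + 1)]]$occupancy_mult)
    if (mult < 1) {        # shrink the block about its midpoint
      mid <- (t0 + t1) / 2
      t0 <- mid - dur * mult / 2
      t1 <- mid + dur * mult / 2
      dur <- t1 - t0
    }
    k_int <- stats::rpois(1, routine$interruptions_per_night +
                               e$interruptions_add)
    segs <- tibble::tibble(start = t0, end = t1)
    if (k_int > 0) {
      istart <- sort(stats::runif(k_int, t0 + 600, t1 - 600))
      ilen <- pmax(60, stats::rexp(k_int, 1 / routine$interruption_mean_s))
      ilen <- pmin(ilen, dur / 4)
      cur <- t0
      starts <- ends <- numeric(0)
      for (j in seq_len(k_int)) {
        if (istart[j] > cur + 60 && istart[j] + ilen[j] < t1 - 60) {
          starts <- c(starts, cur); ends <- c(ends, istart[j])
          cur <- istart[j] + ilen[j]
        }
      }
      starts <- c(starts, cur); ends <- c(ends, t1)
      segs <- tibble::tibble(start = starts, end = ends)
      segs <- segs[segs$end - segs$start >= 30, ]
    }
    segs <- segs[segs$start < as.numeric(span_end), ]
    segs$end <- pmin(segs$end, as.numeric(span_end))
    if (nrow(segs) > 0) {
      bed_events[[d]] <- tibble::tibble(
        sensor_id = paste0(patient_id, "_bed"), location = "bed",
        kind = rep(c("usage_started", "usage_ended"), nrow(segs)),
        timestamp = as.POSIXct(as.vector(rbind(segs$start, segs$end)),
                               tz = "UTC"))
    }
    night_rate <- routine$night_rate + e$night_rate_add
    night_end <- min(t1, as.numeric(span_end))
    if (night_rate > 0 && night_end > t0) {
      n <- stats::rpois(1, night_rate * (night_end - t0) / 3600)
      if (n > 0) {
        tt <- sort(stats::runif(n, t0, night_end))
        night_motion[[d]] <- tibble::tibble(
          sensor_id = paste0(patient_id, "_pir_br"), location = "bedroom",
          kind = "motion", timestamp = as.POSIXct(tt, tz = "UTC"))
      }
    }
    occ <- sum(segs$end - segs$start)
    night_rows[[d]] <- tibble::tibble(
      morning_day = dates[d] + 1, block_start = as.POSIXct(t0, tz = "UTC"),
      block_end = as.POSIXct(min(t1, as.numeric(span_end)), tz = "UTC"),
      occupancy_s = occ)
  }

  # --- vitals --------------------------------------------------------
  vital_rows <- list()
  truth_vitals <- list()
  for (d in seq_len(n_days)) {
    e <- eff[[d]]
    p <- if (!is.na(e$compliance_prob)) e$compliance_prob else
      vitals$compliance_prob
    measured <- stats::runif(1) < p
    n_reads <- if (measured && stats::runif(1) < vitals$multi_read_prob)
      2L else if (measured) 1L else 0L
    read_times <- if (n_reads >= 1) {
      t1r <- min(max(28800 + stats::rnorm(1, 0, 1800), 21600), 39600)
      if (n_reads == 2) c(t1r, t1r + 4 * 3600) else t1r
    } else numeric(0)
    for (kind in names(vitals$baselines)) {
      b <- vitals$baselines[[kind]]
      delta <- switch(kind,
        systolic_mmHg = e$systolic_delta, diastolic_mmHg = e$diastolic_delta,
        pulse_bpm = e$pulse_delta, spo2_percent = e$spo2_delta,
        weight_kg = e$weight_delta, 0)
      mu <- b[1] + delta
      truth_vitals[[length(truth_vitals) + 1]] <- tibble::tibble(
        day = dates[d], kind = kind, mean = mu)
      if (n_reads == 0) next
      val <- stats::rnorm(n_reads, mu, b[2])
      if (kind == "spo2_percent")
        val <- pmin(pmax(val, 40), min(100, e$spo2_max))
      val <- if (kind == "weight_kg") round(val, 1) else round(val)
      vital_rows[[length(vital_rows) + 1]] <- tibble::tibble(
        kind = kind, timestamp = day_ts(dates[d], round(read_times)),
        value = val)
    }
  }

  events <- dplyr::bind_rows(c(motion, night_motion, bed_events)) |>
    dplyr::mutate(timestamp = as.POSIXct(round(as.numeric(.data$timestamp)),
                                         tz = "UTC")) |>
    dplyr::arrange(.data$sensor_id, .data$timestamp)
  vitals_out <- dplyr::bind_rows(vital_rows)
  if (nrow(vitals_out) > 0)
    vitals_out <- dplyr::arrange(vitals_out, .data$kind, .data$timestamp)

  episodes <- Filter(function(ep) ep$start_day <= n_days, episodes)
  ep_cal <- if (length(episodes) > 0) {
    dplyr::bind_rows(lapply(episodes, function(ep) tibble::tibble(
      kind = ep$kind,
      start_day = start_date + ep$start_day - 1,
      end_day = start_date + min(ep$start_day + ep$duration_days - 2,
                                 n_days - 1),
      progressive = ep$progressive,
      confounder = ep$kind %in% c("absence", "visitor"))))
  } else {
    tibble::tibble(kind = character(), start_day = as.Date(character()),
                   end_day = as.Date(character()), progressive = logical(),
                   confounder = logical())
  }
  in_ep <- vapply(seq_len(n_days), function(d)
    any(vapply(episodes, function(ep)
      d >= ep$start_day & d <= ep$start_day + ep$duration_days - 1,
      logical(1))), logical(1))

  truth <- list(
    days = tibble::tibble(
      day = dates, day_index = seq_len(n_days),
      wake_s = wake_s[seq_len(n_days)], bed_s = bed_s[seq_len(n_days)],
      rate_mult = vapply(eff[seq_len(n_days)], `[[`, numeric(1), "rate_mult"),
      occupancy_mult = vapply(eff[seq_len(n_days)], `[[`, numeric(1),
                              "occupancy_mult"),
      in_episode = if (n_days > 0) in_ep else logical(0)),
    episodes = ep_cal,
    nights = dplyr::bind_rows(night_rows),
    vitals_true = dplyr::bind_rows(truth_vitals),
    params = list(routine = routine, vitals = vitals, seed = seed,
                  n_days = n_days, start_date = start_date,
                  patient_id = patient_id))
  list(events = events, vitals = vitals_out, truth = truth)
}

#' Expected steady-state daily bed occupancy
#'
#' Under the routine's configuration the nightly sleep block runs from bed
#' time to the next wake time, losing the expected interruption time; in
#' steady state each civil day accumulates one full block (its morning
#' portion plus the evening portion of the next night).
#'
#' @param routine a [routine_profile()].
#' @return expected seconds of bed occupancy per civil day.
#' @export
expected_daily_occupancy <- function(routine) {
  block <- 86400 - routine$bed_s + routine$wake_s
  block - routine$interruptions_per_night * routine$interruption_mean_s
}

string_hash <- function(x) {
  h <- 0
  for (c in utf8ToInt(x)) h <- (h * 31 + c) %% 1048573
  h
}

#' Simulate a cohort of patients
#'
#' Runs [simulate_patient()] for each spec with an independent sub-seed
#' derived deterministically from the master seed and the patient id.
#'
#' @param specs named list; each element a list with `routine`, `vitals`,
#'   `episodes`, `n_days` (names are the patient ids).
#' @param seed master seed.
#' @param out_dir optional directory: per-patient `*_events.csv` /
#'   `*_vitals.csv` plus a `manifest.csv` are written there.
#' @return named list of [simulate_patient()] results, with attribute
#'   `manifest`.
#' @export
simulate_cohort <- function(specs, seed, out_dir = NULL) {
  stopifnot(length(specs) >= 1)
  ids <- names(specs)
  if (is.null(ids) || any(ids == "") || anyDuplicated(ids))
    stop("simulate_cohort: specs must carry unique patient ids as names")
  res <- list()
  manifest <- list()
  for (id in ids) {
    sp <- specs[[id]]
    sub_seed <- (as.numeric(seed) * 10007 + string_hash(id)) %% 2147483647
    res[[id]] <- simulate_patient(sp$routine, sp$vitals,
                                  sp$episodes %||% list(), sp$n_days,
                                  seed = sub_seed, patient_id = id)
    files <- character(0)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      ef <- file.path(out_dir, paste0(id, "_events.csv"))
      vf <- file.path(out_dir, paste0(id, "_vitals.csv"))
      write_table(res[[id]]$events, ef)
      write_table(res[[id]]$vitals, vf)
      files <- c(ef, vf)
    }
    manifest[[id]] <- tibble::tibble(
      patient_id = id, sub_seed = sub_seed, n_days = sp$n_days,
      n_events = nrow(res[[id]]$events),
      n_vitals = nrow(res[[id]]$vitals),
      files = paste(basename(files), collapse = ";"))
  }
  manifest <- dplyr::bind_rows(manifest)
  if (!is.null(out_dir))
    write_table(manifest, file.path(out_dir, "manifest.csv"))
  attr(res, "manifest") <- manifest
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Library of case-study-like scenarios
#'
#' Named episode bundles reproducing the qualitative phenomenology of four
#' monitored cases:
#' * `patient1_like` — congestive heart failure with hypertension: blood
#'   pressure above target until a mid-monitoring medication change,
#'   restless nights and occasional early retirement to the bedroom.
#' * `patient2_like` — a fall followed by a long spell of daytime
#'   inactivity (reduced movement counts, longer time-to-next-move) with
#'   extra time in bed and slow recovery.
#' * `patient3_like` — COPD with an exacerbation window in which oxygen
#'   saturation drops below the 85 % referral threshold on every episode
#'   day by construction (the episode caps saturation below the
#'   threshold and makes measurement certain), alongside slightly raised
#'   daytime movement counts.
#' * `patient4_like` — progressive respiratory decline: a steady
#'   progressive saturation fall plus a drastic bed-occupancy collapse
#'   between days 80 and 90 and terminal decline from day 125.
#'
#' @param n_days optional named overrides of each scenario's day count.
#' @return named list of cohort specs usable with [simulate_cohort()] or
#'   [simulate_patient()].
#' @export
scenario_library <- function(n_days = NULL) {
  lib <- list(
    patient1_like = list(
      n_days = 150,
      routine = routine_profile(night_rate = 0.3),
      vitals = vitals_profile(baselines = list(
        systolic_mmHg = c(120, 8), diastolic_mmHg = c(72, 6),
        pulse_bpm = c(74, 6), weight_kg = c(68, 0.3))),
      episodes = list(
        episode("hypertensive", 1, 70,
                list(systolic_delta = 27, diastolic_delta = 10)),
        episode("nocturnal_restlessness", 110, 7,
                list(night_rate_add = 8, interruptions_add = 3)),
        episode("nocturnal_restlessness", 130, 2,
                list(bed_shift_min = -150)))),
    patient2_like = list(
      n_days = 150,
      routine = routine_profile(),
      vitals = vitals_profile(baselines = list(
        systolic_mmHg = c(132, 8), diastolic_mmHg = c(78, 6),
        pulse_bpm = c(70, 5), weight_kg = c(74, 0.3))),
      episodes = list(
        episode("fall_inactivity", 65, 30,
                list(rate_mult = 0.4, occupancy_mult = 1.12,
                     wake_shift_min = 45)))),
    patient3_like = list(
      n_days = 212,
      routine = routine_profile(wake_time = "05:30"),
      vitals = vitals_profile(baselines = list(
        spo2_percent = c(94, 1.5), pulse_bpm = c(76, 5))),
      episodes = list(
        episode("copd_exacerbation", 100, 21,
                list(spo2_delta = -11, spo2_max = 84.4, rate_mult = 1.15,
                     compliance_prob = 1)),
        episode("copd_exacerbation", 200, 5,
                list(spo2_delta = -11, spo2_max = 84.4, rate_mult = 1.15,
                     compliance_prob = 1)))),
    patient4_like = list(
      n_days = 135,
      routine = routine_profile(bed_time = "22:30",
                                interruptions_per_night = 2),
      vitals = vitals_profile(baselines = list(
        spo2_percent = c(93, 1.5), pulse_bpm = c(78, 6))),
      episodes = list(
        episode("copd_exacerbation", 30, 106,
                list(spo2_delta = -8), progressive = TRUE),
        episode("copd_exacerbation", 80, 11,
                list(occupancy_mult = 0.45, night_rate_add = 2)),
        episode("copd_exacerbation", 125, 11,
                list(occupancy_mult = 0.4, night_rate_add = 3),
                progressive = TRUE))))
  if (!is.null(n_days))
    for (nm in names(n_days)) lib[[nm]]$n_days <- n_days[[nm]]
  lib
}

#' Cohort specs with absence and visitor confounders
#'
#' Builds patient specs whose calendars mix one genuine inactivity
#' episode with part-day absences and afternoon visitors — the two
#' classic causes of spurious period alerts (an empty afternoon looks
#' like underactivity to a six-hour period; a visitor looks like
#' overactivity). Used to compare the four-period and all-day-only
#' alerting schemes.
#'
#' @param n_patients cohort size (default 4).
#' @param n_days days per patient (default 120).
#' @return named list of specs for [simulate_cohort()].
#' @export
confounded_cohort_specs <- function(n_patients = 4, n_days = 120) {
  mk <- function() list(
    n_days = n_days,
    routine = routine_profile(),
    vitals = vitals_profile(),
    episodes = list(
      episode("fall_inactivity", max(2, round(n_days * 0.75)), 10,
              list(rate_mult = 0.35)),
      episode("absence", max(2, round(n_days * 0.25)), 1,
              list(absent_hours = 8:15)),
      episode("absence", max(2, round(n_days * 0.45)), 1,
              list(absent_hours = 12:19)),
      episode("visitor", max(2, round(n_days * 0.33)), 1,
              list(visitor_hours = 13:17, visitor_mult = 3)),
      episode("visitor", max(2, round(n_days * 0.58)), 1,
              list(visitor_hours = 14:18, visitor_mult = 3))))
  stats::setNames(lapply(seq_len(n_patients), function(i) mk()),
                  paste0("p", seq_len(n_patients)))
}
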