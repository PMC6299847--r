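---
title: "Methods: habits features, adaptive alerting and the synthetic patient model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habits features, adaptive alerting and the synthetic patient model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telehabits)
```

This vignette is the package's account of its models and the choices
behind them: what each statistic assumes, which parameters matter and
why they default as they do, what the synthetic patients do and do not
emulate, and where the sharp edges are.

## The monitoring problem

A frail elderly person living alone is monitored by two kinds of
sensor. Clinical devices (blood-pressure meter, pulse oximeter, weight
scale) produce a handful of timestamped readings per day at the
patient's initiative. Ambient devices produce continuous streams: a PIR
motion sensor emits an event whenever movement crosses its field, and a
pressure mat under the mattress or chair cushion reports
`usage_started`/`usage_ended` transitions, debounced in hardware so that
no state shorter than 30 s is ever reported. The analytic task is to
turn these streams into a stable picture of the person's *habits* — when
they rise, how much they move, how they sleep — and to flag days that
deviate, alongside conventional vital-sign threshold checks.

All timestamps are local naive civil datetimes and the day boundary is
local midnight. We deliberately do not convert to UTC or correct for
daylight-saving transitions: monitored homes sit in a single time zone,
and a DST shift shows up as a genuine one-hour shift in the behavioural
record (a spring wake-time jump is a property of the data, not an
artefact to remove). A 23 h or 25 h civil day is therefore legal, and
the daily occupancy bound rises to 90 000 s on a 25 h day.

## Daily vitals and clinical rules

Patients occasionally measure two or three times in a day. The daily
representative is the **maximum** for SpO₂ — the clinical convention,
since poor probe contact biases oximetry downward — and the **median**
for blood pressure, pulse and weight (mean of the central pair on even
counts; the choice matters little and the median is robust to a single
fumbled reading).

Fixed rules follow the deployment protocol, all with strict
inequalities as printed on the protocol card: systolic > 140 mmHg *or*
diastolic > 80 mmHg (either component suffices — the clinical
convention for a combined stage target), SpO₂ < 85 %, and weight change
> 1 kg against the previous day or > 1.4 kg against the day exactly
three civil days earlier. The three-day comparison tolerates missing
intermediate days, since sparse weighing is exactly when the rule is
most needed; both gain and loss directions are reported with labels,
leaving triage to the reviewer (fluid retention is a gain, but an
unexplained loss is also actionable).

## Adaptive (subject-specific) bands

Habit counts have no population reference ranges, so thresholds are
subject-specific: for each monitored series the band on day *d* is the
mean ± *k*·SD (default *k* = 2) of the observations in the trailing 15
civil days **strictly before** *d*. Excluding the current day means a
deviant day cannot widen its own band; a window of 15 days is long
enough to average over weekly structure yet short enough to track slow
drift. We use the sample (n−1) SD. A band is undefined until at least
`min_window_obs = 5` observations exist ("warm-up") — with fewer, the SD
estimate is too noisy to gate an alert. A zero-variance window produces
a degenerate band equal to the constant, so *any* deviation fires; this
sharp behaviour is intentional and documented, and a configuration
epsilon can widen it where sensors are genuinely noiseless.

Two period schemes are built in. The four-period scheme (00–06, 06–12,
12–18, 18–24) evaluates every period; the three-period scheme (all-day,
night 22:00–06:00, morning 06:00–10:00) evaluates night and morning for
inspection but raises portal alerts **only for the all-day period**,
which is the configuration that survived deployment experience: a
part-day absence empties one six-hour period (an underactivity false
alarm) and an afternoon visitor inflates another, while the all-day
count barely moves. Midnight-spanning periods are attributed to the day
containing their start; period boundaries must fall on whole hours, and
bins and periods are half-open so no event is double-counted.

The persistence filter marks an alert actionable only when the same
type — same category, rule, period and direction — fired on each of
*m* consecutive days ending at the current one. The deployment practice
was "several consecutive alerts"; we default to *m* = 3, the smallest
value beyond two consistent with "several", and expose it.

## Habits features

Hourly binning (half-open, `[h, h+1)`) is fine enough to localise
activities and coarse enough to smooth minute-scale noise. The mean
hourly profile over a 20-day window exposes the circadian routine.
First/last movement times estimate the bed/wake routine when no bed
sensor is present; the first-movement search starts at a cutoff
(default 05:00, configurable to 04:00 for early risers) to avoid
counting nocturnal bathroom trips as rising. Time-to-next-move
quantiles are computed from intervals between consecutive events
*within* one civil day, only for days with at least `min_moves` events
(default 30; 15 or 10 are appropriate for sparser subjects — it is an
analysis parameter, not a constant), using linear interpolation between
order statistics. The 10th quantile tracks the tempo of short tasks,
the 90th the long gaps of inactivity that lengthen during exacerbations.

Occupancy intervals come from pairing consecutive start/end messages.
The hardware's 30 s debounce is re-applied defensively at ingest
(gaps < 30 s between an end and the next start are merged), so raw and
hardware-filtered streams produce identical features. A trailing
unmatched start is closed at stream end and flagged truncated; orphan
ends are dropped and counted. Intervals are split at civil midnight
before daily accumulation, making totals invariant to interior splits,
and the five longest spells per day summarise sleep fragmentation.

## The synthetic patient

The generator exists so that every pipeline stage can be scored against
known truth. Its defaults are the study conditions, chosen once:

* **Motion**: a piecewise-constant-rate (hourly) Poisson process while
  awake — the simplest process consistent with hourly-profile evidence;
  there is no self-exciting structure. The default profile sums to
  roughly 65 events over a waking day, in the 60–70/day range seen in
  real living-room deployments, with breakfast and evening peaks.
* **Routine**: wake 06:30 ± 20 min, bed 22:00 ± 20 min (per-day
  truncated-normal draws), a near-zero in-bed bedroom motion rate
  (0.2/h), and one sleep interruption per night on average
  (Poisson count, exponential length, mean 10 min).
* **Vitals**: per-kind Gaussian baselines (e.g. SpO₂ 94 ± 1.5 %, weight
  ± 0.3 kg), daily measurement probability 0.8 — comfortably in the
  "generally over 60 %" band of real deployments — and a 15 % chance of
  a second reading, values rounded as the devices round.
* **Episodes** perturb these with known timing: rate multipliers,
  occupancy multipliers (shrinking the sleep block about its midpoint),
  vitals deltas, compliance overrides, part-day absence hours and
  visitor hours. Progressive episodes ramp linearly. Absences and
  visitor days are flagged as confounders in the truth calendar, so
  scoring can treat alerts on them as false alarms.

The `patient3_like` exacerbation sets the SpO₂ mean 11 points down *and*
caps readings at 84.4 % with compliance forced to 1: this guarantees by
construction that the < 85 % rule fires on every episode day, which is
what makes the scenario a useful end-to-end probe of the clinical path.
The cap is an evaluation device, not a physiological claim.

What the simulator does **not** emulate: multi-occupant homes, sensor
dropouts and radio failures, physiologically mechanistic vitals
dynamics (no autocorrelation beyond episode structure), room-transition
geometry and walking speed. Passing recovery tests therefore shows the
*pipeline* is correct and calibrated under these idealised conditions;
it does not validate clinical performance on real homes.

## Recovery checks and their arithmetic

Three properties tie the pipeline to the truth record: the median
first-movement time on non-episode days lands within 30 min of the
configured wake time (first movement necessarily trails waking by a few
minutes at morning rates of ~3 events/h); mean daily occupancy on
interior days lands within 5 % of `expected_daily_occupancy()` (the
sleep block minus expected interruption time — in steady state each
civil day accumulates exactly one block: its own morning plus the next
night's evening); and the SpO₂ baseline is recovered within 2 standard
errors using **single-reading** days only, because the max rule biases
multi-reading days upward by about `multi_read_prob · E[max of 2] · σ`
≈ 0.13 %, a known and intended property of the representative, not of
the generator.

The adaptive-alert calibration check runs the engine over i.i.d.
Poisson(60) daily counts (500 days × 100 seeds) and compares the alert
rate with an independent day-by-day loop implementation of the same
procedure; the observed rate (≈ 7 %) is far above the Gaussian 2σ
nominal 4.6 % because a 15-day window estimates the SD noisily and the
counts are discrete — a property of the deployed procedure itself that
the engine must reproduce, not a defect to correct.

## Numerical and degenerate-input choices

Quantiles interpolate linearly between order statistics; trailing
windows are closed on calendar days, not row counts, so gaps shrink the
effective sample and can re-enter warm-up; trend decomposition uses
centered moving averages (defaults 7 and 29 days, odd so the window
centres on a day) over whatever observations are present, leaves edges
undefined, and reports the trailing sample SD of residuals as the
variability track. Exact duplicate rows at ingest are dropped as
retransmissions and counted; near-duplicates are kept. Merged alert
logs sort stably by day, then clinical before habits, then rule, so
repeated runs are byte-identical. Cohort sub-seeds derive from a fixed
polynomial hash of the patient id, keeping every seed below 2³¹.

## Problem sizes

The shipped analyses simulate the four scenario patients at their
native lengths (150, 150, 212 and 135 days) and a four-patient
confounded cohort at 120 days; the calibration study uses 500-day
series over 100 seeds. These sizes give Monte-Carlo standard errors
small relative to every tolerance above while keeping a full run in the
low minutes on one core.

## Known limitations

Alert scoring credits any alert day inside an episode (or within a
2-day grace window after it) as a true positive without distinguishing
rules; the weight rules' gain/loss symmetry is a reporting choice, not
deployment-verified; the trend decomposition is the moving-average form
only — no seasonal or robust variants; and the all-day portal policy is
implemented as configuration, not re-derived from data.
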