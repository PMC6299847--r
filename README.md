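# telehabits

Integrated telehealth + telecare analytics for remote monitoring of frail
elderly patients living alone. The package is written for teams running
(or studying) combined home-monitoring deployments in which the same
platform collects

* **clinical vitals** — blood pressure, pulse, oxygen saturation (SpO₂)
  and weight, measured daily by the patient; and
* **habits data** — passive-infrared (PIR) motion events and bed/chair
  pressure-sensor occupancy, collected continuously,

and in which a nurse reviews a portal of automatically raised alerts.
Everything from raw event streams to the alert log is implemented as
plain functions over tidy tables, and a seeded synthetic-patient
simulator with recorded ground truth makes the whole pipeline testable
without any patient data.

## What it computes

**Habits features** (per civil day, midnight to midnight):

* movement counts in 1 h bins and in configurable day periods, under the
  two deployed schemes — four six-hour periods (00–06, 06–12, 12–18,
  18–24) and three periods (all-day, night-time 22:00–06:00, morning
  06:00–10:00);
* the mean hourly activity profile over a 20-day window;
* times of first movement after a cutoff (default 05:00) and last
  movement before midnight;
* quantiles (10th/50th/90th) of the time-to-next-move intervals for days
  with at least `min_moves` events (default 30);
* bed/chair occupancy from paired `usage_started`/`usage_ended` events
  (30 s debounce), split at midnight, with daily totals and the five
  longest occupancy spells per day.

**Alerting**:

* fixed clinical thresholds: systolic/diastolic above **140/80 mmHg**,
  SpO₂ below **85 %**, weight change over **1 kg in 24 h** or **1.4 kg in
  3 days** (all strict inequalities);
* subject-specific adaptive thresholds: for a daily series `x_t` (a
  period's movement count, or a vital), the band is

  `mean(x in trailing 15 days) ± 2 · SD(x in trailing 15 days)`

  computed over the days strictly before `t` (so a deviant day cannot
  widen its own band), with a warm-up rule requiring at least 5
  observations; values strictly outside the band raise over/under
  alerts;
* a persistence filter that marks an alert actionable only after `m`
  consecutive days of the same alert type (default 3);
* moving-average trend/residual decomposition of vital series (short and
  long centered windows, trailing residual SD) for retrospective review.

**Simulation**: `simulate_patient()` draws motion events from an
inhomogeneous Poisson process with an hourly circadian rate profile,
gated by per-day wake/bed times; bed events from a nightly sleep block
with Poisson-count, exponential-length interruptions; and vitals with
imperfect daily compliance. Scripted episodes (hypertension, COPD
exacerbation, fall inactivity, restless nights, absences, visitors)
perturb rates, occupancy and vitals with known timing, recorded in a
ground-truth object. `scenario_library()` ships four case-study-like
patients.

## Worked example

```r
library(telehabits)

res <- run_pipeline(pipeline_config(scenario = "patient3_like", seed = 4,
                                    condition = "COPD",
                                    out_dir = "p3_run"))
dplyr::filter(res$alerts, persistent)
#> # A tibble: 22 × 9
#>   day        category rule      period observed lower upper direction persistent
#>   <date>     <chr>    <chr>     <chr>     <dbl> <dbl> <dbl> <chr>     <lgl>
#> 1 2023-04-13 clinical spo2_und… <NA>         83    85    NA under     TRUE
#> 2 2023-04-14 clinical spo2_und… <NA>         82    85    NA under     TRUE
#> 3 2023-04-15 clinical spo2_und… <NA>         84    85    NA under     TRUE
#> # …
```

The simulated COPD patient's scripted exacerbation (monitoring days
100–120) drives the daily SpO₂ representative below the 85 % referral
threshold; the rule fires on every exacerbation day and the persistence
filter marks the runs of 3+ consecutive days a nurse would act on.

```r
s <- summarize_patient(res)
s$compliance
#> # A tibble: 2 × 3
#>   kind         n_days_measured compliance_pct
#>   <chr>                  <int>          <dbl>
#> 1 pulse_bpm                173           81.6
#> 2 spo2_percent             173           81.6

res$scheme_metrics
#> # A tibble: 2 × 7
#>   scheme          n_alert_days n_true_positive n_false_alarms sensitivity …
#> 1 v1_four_period            57              11             46           1
#> 2 v2_three_period           21               7             14           1
```

Both period schemes detect the scripted episodes, but the four-period
scheme raises over three times as many false alarms — the behaviour that
motivated moving portal alerting to the all-day period only.

## Interchange formats

Two CSV formats (UTF-8, header row, ISO-8601 local timestamps at 1 s
resolution); samples in `inst/extdata/`:

* `events.csv`: `sensor_id,location,kind,timestamp` with `kind` one of
  `motion`, `usage_started`, `usage_ended`;
* `vitals.csv`: `kind,timestamp,value` with `kind` one of
  `systolic_mmHg`, `diastolic_mmHg`, `pulse_bpm`, `spo2_percent`,
  `weight_kg`.

A YAML run configuration (`inst/extdata/example_config.yaml`) drives
`run_pipeline()` via `read_pipeline_config()`.

## Analysis workflow

`analysis/01_simulate.R` … `05_summaries.R` are thin narrative drivers
over the package: simulate the scenario patients and a confounded cohort,
extract features, run the alerting pipeline, compare the two period
schemes and tabulate per-patient summaries under `results/`.

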