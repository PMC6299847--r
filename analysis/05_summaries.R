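#!/usr/bin/env Rscript
# Per-patient summaries a reviewing clinician would scan: monitored days,
# compliance per vital, alert counts by rule.

suppressMessages({library(telehabits); library(dplyr)})

rows <- list()
for (id in names(scenario_library())) {
  s <- summarize_patient(file.path("results/alerts", id))
  rows[[id]] <- s$compliance |>
    mutate(patient = id, monitored_days = s$monitored_days, .before = 1)
  message(sprintf("%s: %d monitored days; compliance %s", id,
                  s$monitored_days,
                  paste(sprintf("%s %.0f%%", s$compliance$kind,
                                s$compliance$compliance_pct),
                        collapse = ", ")))
}
write_table(bind_rows(rows), "results/compliance.csv")
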