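#!/usr/bin/env Rscript
# Daily vitals aggregation and the full alert log (clinical thresholds,
# adaptive bands, persistence) per patient, via the one-config pipeline.

suppressMessages({library(telehabits); library(dplyr)})

conditions <- c(patient1_like = "CHF", patient2_like = "CHF",
                patient3_like = "COPD", patient4_like = "COPD")
for (id in names(conditions)) {
  res <- run_pipeline(pipeline_config(
    events_path = file.path("results/data", paste0(id, "_events.csv")),
    vitals_path = file.path("results/data", paste0(id, "_vitals.csv")),
    condition = conditions[[id]],
    out_dir = file.path("results/alerts", id)))
  n_pers <- sum(res$alerts$persistent)
  message(sprintf("%s (%s): %d alerts, %d persistent (%s)", id,
                  conditions[[id]], nrow(res$alerts), n_pers,
                  paste(unique(res$alerts$rule), collapse = ", ")))
}
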