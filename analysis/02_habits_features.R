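#!/usr/bin/env Rscript
# Extract the habits-parameter families for every simulated patient:
# period counts under both schemes, first/last movement, time-to-next-move
# quantiles and bed occupancy. Tables land under results/features/.

suppressMessages({library(telehabits); library(dplyr)})

out <- "results/features"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ids <- names(scenario_library())
for (id in ids) {
  events <- read_events(file.path("results/data", paste0(id, "_events.csv")))
  motion <- events |> filter(kind == "motion", location == "living_room")
  usage <- events |> filter(kind != "motion")
  feats <- day_features(motion, if (nrow(usage)) usage else NULL)
  write_table(feats, file.path(out, paste0(id, "_day_features.csv")))

  hc <- hourly_counts(motion)
  prof <- mean_hourly_profile(hc, window_days = 20)
  write_table(prof, file.path(out, paste0(id, "_hourly_profile.csv")))
  message(sprintf("%s: %d days, busiest hour %02d:00 (%.1f events/h on average)",
                  id, nrow(feats), prof$hour[which.max(prof$mean_n)],
                  max(prof$mean_n)))
}
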