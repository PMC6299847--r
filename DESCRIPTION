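Package: telehabits
Title: Integrated Telehealth and Telecare Analytics for Home Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytics for combined remote monitoring of frail elderly
    patients: ingest of ambient-sensor event streams (passive-infrared
    motion, bed/chair pressure) and daily vital-sign readings (blood
    pressure, pulse, oxygen saturation, weight); extraction of daily
    habits features (hourly movement counts, period counts, first/last
    movement times, time-to-next-move quantiles, bed occupancy);
    clinical threshold alerts and subject-specific adaptive mean +/- 2 SD
    alerts over trailing windows with a consecutive-alert persistence
    filter; and a seeded synthetic patient simulator with recorded
    ground truth (circadian movement profiles, sleep blocks with
    interruptions, exacerbation episodes, imperfect compliance) so the
    whole pipeline and its alerting metrics can be evaluated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
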