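Package: vaportox
Title: First-Tier Toxicological Risk Assessment for Vaporized Cannabis
    Concentrate Additives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for first-tier toxicological risk assessment of additives
    in vaporized cannabis concentrates. Implements categorical hazard
    screening (respiratory sensitizers, phenolic acetates, supplements and
    major food allergens), safety-limit derivation from a point of departure
    with a six-category uncertainty-factor ledger and a 10,000-fold cap,
    threshold-of-toxicological-concern (TTC) routing for data-poor
    substances, inhalation exposure assessment with dose-unit conversion,
    consumption-telemetry percentile summaries, risk characterization with
    back-calculated maximum allowable concentrations, and a seeded synthetic
    usage-log simulator so the full pipeline is testable without proprietary
    device data. Substance dossiers round-trip through JSON and CSV, results
    come back as tibbles with tidy() and glance() methods, and a
    command-line interface supports scripted batch screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
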