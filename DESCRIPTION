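Package: calvesense
Title: Field Performance and Decision-Tree Economics of an Intravaginal
    Calving Sensor
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating remote calving-alarm sensors in dairy
    herds. Provides a generic decision-tree engine with expected
    monetary value rollback, exhaustive path enumeration and one-way
    sensitivity sweeps; parity-specific calving-economics trees built from a
    market and epidemiology parameter table; field-performance statistics
    (binomial proportions with Wald confidence intervals, interval
    summaries, two-sample t tests from raw data or summary statistics,
    chi-square tests, circular alert-time densities, APGAR and dystocia
    scoring); a discrete-event simulator of the intravaginal probe firmware
    (suspension countdown, light and temperature triggers, six-probe
    central unit, GSM alert dispatch); and a seeded synthetic cohort
    generator so the whole pipeline runs without access to raw on-farm
    records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
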