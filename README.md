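# calvesense

Evaluation toolkit for remote calving-alarm sensors in dairy herds. An
intravaginal probe, expelled at the onset of the expulsive phase of labor
(stage II), detects its own expulsion through light and temperature sensors
and phones the farmer via a GSM central unit. Deciding whether such a
device pays — and characterising how well it performs — requires three
kinds of analysis that this package bundles for veterinarians,
precision-livestock researchers and farm economists:

* **Field-performance statistics** — diagnostic sensitivity and category
  frequencies with 95% Wald confidence intervals
  (`p̂ ± z·sqrt(p̂(1−p̂)/n)`), alarm-to-expulsion interval summaries,
  pooled/Welch two-sample t tests (from raw data *or* from published
  summary statistics), chi-square tests, circular alert time-of-day
  densities with night-window shares, and APGAR/dystocia scoring.
* **Decision-tree economics** — a generic expected-monetary-value engine
  (backward-induction `rollback()`, exhaustive `enumerate_paths()` as a
  built-in oracle, one-way sensitivity sweeps, Graphviz DOT and JSON
  export) plus parity-specific calving trees driven by a market and
  epidemiology parameter table: at each calving the tree chooses
  *apply sensor* vs *no sensor* through chance nodes for semen type, calf
  sex, alarm reception, calving difficulty and calf survival, with payoff =
  calf market value − sensor cost.
* **Device simulation and synthetic cohorts** — a discrete-event state
  machine of the probe firmware (60-min suspension countdown, light /
  temperature-gradient triggers, one expulsion signal, six-probe central
  unit, GSM dispatch with failure modelling) and a seeded cohort generator
  calibrated to the published field statistics (86.3% alarm sensitivity,
  19/63 dystocia among alarmed, moment-matched truncated-normal intervals,
  33.8% of alerts in 22:00–06:00), so the entire pipeline runs with no
  access to the raw on-farm records.

## Worked example

Reconstruct the published frequency table from its counts (73 monitored
deliveries, 63 alarms, difficulty scores 44/10/5/4/0 among the alarmed;
missed alarms carry no score):

```r
library(calvesense)

records <- data.frame(
  alarm = c(rep(TRUE, 63), rep(FALSE, 10)),
  dystocia_score = c(rep(0L, 44), rep(1L, 10), rep(2L, 5), rep(3L, 4),
                     rep(NA, 10))
)
frequency_table(records)
#>  category  k  n  rate ci_low ci_high
#>     alarm 63 73 86.30  78.41   94.19
#>  no alarm 10 73 13.70   5.81   21.59
#>   score 0 44 73 60.27  49.05   71.50
#>   score 1 10 73 13.70   5.81   21.59
#>   score 2  5 73  6.85   1.05   12.64
#>   score 3  4 73  5.48   0.26   10.70
#>   score 4  0 73  0.00   0.00    0.00
#> Dystocia among alarmed deliveries: 19/63 = 30.2%
```

The alarm row is the device's diagnostic sensitivity: 86.30% (Wald 95% CI
78.41–94.19). Dystocia complicated 30.2% of alarmed deliveries.

Compare expulsion intervals between eutocia (44 deliveries, 56:54 ±
33:39 min) and dystocia (19, 80:16 ± 29:48) directly from those published
summaries:

```r
two_sample_ttest_summary(44, parse_minutes("56:54"), parse_minutes("33:39"),
                         19, parse_minutes("80:16"), parse_minutes("29:48"))
#> Two-sample t-test (pooled): t = -2.6141, df = 61.00, p = 0.01125
```

Dystocic calvings take significantly longer from alarm to expulsion.

Evaluate the economics under the default parameter table:

```r
calving_scenario()
#> Calving-sensor economics (EUR per monitored delivery), structure 'mortality_marginal':
#>       parity EMV with sensor EMV without incremental  decision
#>  primiparous           84.91       85.77       -0.85 no sensor
#>  pluriparous           78.72       80.02       -1.30 no sensor
```

Each EMV is the probability-weighted calf value net of sensor cost;
`incremental` is the gain from monitoring. Under this documented tree
structure the EUR 10 per-calving cost slightly outweighs the mortality
benefit — and the per-delivery incomes of ~EUR 119.5/123.6 previously
reported for this device with proprietary software are not derivable from
the published parameter table at all (they exceed the maximum attainable
primiparous calf value), which is why the scenario output names its
structure and the test suite pins the model down with closed-form
properties instead (e.g. a perfect free sensor must yield exactly
`unmonitored mortality × expected calf value` ≈ 10.60 EUR for primiparous
dams). See the methods vignette for the full account.

Everything is also scriptable from a shell:

```sh
Rscript inst/scripts/calvesense simulate --seed 7 --n 73 --out cohort.csv
Rscript inst/scripts/calvesense stats --input cohort.csv --out report.json
Rscript inst/scripts/calvesense tree --out scenario.json
Rscript inst/scripts/calvesense sensitivity --parameter sensor_sensitivity \
    --range 0.5 --steps 11 --out sweep.csv
```

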