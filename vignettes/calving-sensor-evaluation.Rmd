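---
title: "Evaluating an intravaginal calving-alarm sensor: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating an intravaginal calving-alarm sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calvesense)
```

## The problem

Timely calving assistance reduces perinatal calf mortality and postpartum
disease in dairy cattle, but the onset of the expulsive phase of labor
(stage II) is hard to predict and often missed, especially at night. One
monitoring strategy is an intravaginal probe, anchored against the external
cervical os, that detects its own expulsion — the fetal membranes entering
the birth canal push it out — through a light sensor and a temperature
sensor, and radios a central unit that phones the farmer via GSM.

`calvesense` packages the analysis such an evaluation needs: the
field-performance statistics of the alarm, a decision-tree economic model
of whether monitoring pays, a discrete-event simulation of the probe
firmware, and a synthetic cohort generator so the whole pipeline runs,
and is testable, without the raw on-farm records.

## The decision-tree model

The economic core is a risk-neutral expected-monetary-value (EMV) decision
tree. Terminal nodes carry payoffs in EUR; chance nodes average their
children under branch probabilities; decision nodes take the maximum.
`rollback()` evaluates a tree by backward induction, and
`enumerate_paths()` re-evaluates it by exhaustive root-to-terminal path
enumeration — an independent route used throughout the test suite as an
oracle: for every tree the probability-weighted path payoffs must equal the
rollback EMV to within 1e-9, and on trees with few decision nodes the
rollback policy must attain the maximum over all policies enumerated
exhaustively.

Numerical conventions, chosen once and fixed:

* **Tie-break.** Equal-EMV branches at a decision node resolve to the first
  branch in declaration order, so results are deterministic.
* **Probability sums.** Chance-branch probabilities must sum to 1. Sums off
  by at most 1e-6 are renormalized with a warning (guarding against float
  drift in programmatically built trees); anything larger is a validation
  error. Published parameter tables whose printed probabilities are rounded
  (the calf-sex split 0.485/0.516 sums to 1.001) are renormalized at the
  parameter layer, in `economic_parameters()`, not silently inside the
  engine.
* **Clamping in sweeps.** A relative sweep can push a probability past 1
  (±50% of 0.863 reaches 1.29). The effective value is clamped to the
  boundary and the grid point flagged; the nominal grid stays strictly
  increasing so the sweep remains well defined.
* Payoffs are kept at full double precision and rounded only for display.

## The calving-economics trees

`build_calving_tree()` instantiates the model for one dam parity class and
one management option. The parameter table (defaults in
`economic_parameters()`, also shipped as
`inst/extdata/table1-parameters.yaml`) holds calf market values, semen-use
probabilities, sensor sensitivity 0.863, dystocia probabilities by calf
type, and perinatal mortality with monitoring (0 primiparous, 0.017
pluriparous) and without (0.11, 0.127), plus the EUR 10 per-calving sensor
cost.

The published figure of the original tree is not fully legible, so the
structure here is an explicit, versioned interpretation
(`structure_id`):

* `mortality_marginal` (default): semen type → calf sex → alarm received
  (sensor arm only) → calving difficulty → calf survival, with mortality
  depending on parity and on whether the calving was actually monitored (a
  missed alarm inherits the unmonitored mortality — a missed alarm *is* an
  unmonitored calving). The dystocia node is structural: the published
  mortality rates are marginal, so difficulty does not further modulate
  survival, and the ±25% dystocia sweep is exactly flat — a deliberate,
  testable consequence.
* `mortality_within_dystocia`: the survival node sits only under the
  dystocia branch, i.e. the mortality rates are read as conditional on a
  difficult calving and eutocic calves always survive. Provided for
  comparison; it makes the dystocia sweeps informative.

Other fixed choices: a dead calf pays 0 EUR (no salvage or disposal term);
sorted semen is female with configurable purity, default 1.0 (commercial
purity is nearer 0.9, but the herd practice being modelled treats sorted
inseminations as producing heifer calves); the horizon is a single calving,
in EUR, undiscounted — longer-term consequences (milk yield, fertility,
culling, veterinary fees) are deliberately out of scope.

Under the default table the model gives, per monitored delivery,
primiparous EMVs of 84.91 EUR with the sensor against 85.77 without
(incremental −0.85), and pluriparous 78.72 against 80.02 (−1.30).
Previously reported per-delivery incomes for this device of roughly
EUR 119.5 (primiparous) and 123.6 (pluriparous), obtained with proprietary
decision-tree software, are **not reproducible from the parameter table**:
they exceed the largest attainable primiparous calf value (≈96.4 EUR
expected), so whatever quantity they measure involves unprinted payoff
components. The package therefore reports its own EMVs with an explicit
structure identifier and makes no attempt to force-fit those figures;
instead the tests pin down properties any correct implementation must have
— the incremental EMV is non-decreasing in sensor sensitivity and
non-increasing in sensor cost, is exactly zero when both arms share
mortality at zero cost, and equals `unmonitored mortality × expected calf
value` (≈10.60 EUR primiparous) for a perfect free sensor.

## Field statistics

* **Proportions.** `proportion_with_ci()` uses the Wald normal
  approximation, `100·k/n ± z·100·sqrt(p̂(1−p̂)/n)` with the exact quantile
  `z = qnorm(0.975) ≈ 1.959964`, clamped to [0, 100]. This choice
  reproduces the published category bounds to within ±0.02; the published
  table itself contains two internal rounding inconsistencies at that scale
  (an upper bound printed 94.20 where the computation gives 94.19, and
  21.57 vs 21.59 for two rows with identical counts), which is why
  comparisons use the ±0.02 tolerance. The Wald interval collapses to zero
  width at p̂ ∈ {0, 1}; that degeneracy is reported, not patched.
* **Score denominators.** Difficulty scores exist only for deliveries where
  the alarm allowed the calving to be attended; missed-alarm rows carry
  `NA` and count in the cohort denominator but in no score category,
  matching how the field table was tabulated.
* **t tests.** `two_sample_ttest()` (raw data) delegates to
  `stats::t.test`; `two_sample_ttest_summary()` implements the pooled and
  Welch statistics in closed form from n/mean/sd — the only route available
  when just published summaries exist. The two routes agree to 1e-9 on raw
  data, which the tests assert. From the published summaries (44
  eutocic deliveries, 56:54 ± 33:39 min, vs 19 dystocic, 80:16 ± 29:48) the
  pooled test gives p ≈ 0.0113, consistent with the p = 0.012 computed from
  the raw records.
* **Quartiles** use linear interpolation (`quantile` type 7), stated
  because published quartiles are not recomputable without the raw data.
* **Alert clock times** are summarized as a circular 24 h histogram density
  (integrating to 1) plus the shares of the 00:00–06:00 and wrapping
  22:00–06:00 windows. The original fitted density curve is unnamed, so no
  parametric fit is attempted.
* Durations printed as `mm:ss` ("80:16") parse to decimal minutes via
  `parse_minutes()`.

## The probe state machine

States: `inactive → suspended → monitoring → ejected → off`. After
activation the probe ignores its sensors for a 60 min countdown (time to
insert the device); it then ejects on light above a threshold **or** an
absolute temperature slope of at least 1 °C/min, emits exactly one radio
signal, and turns off; `off` is absorbing. The numeric thresholds are
unpublished, so both are configuration, not constants: the light threshold
defaults low (the photodetector responds at dusk-level brightness) and the
temperature trigger accepts gradients in either direction, estimated as a
first difference over consecutive samples. The central unit registers at
most six probes, assigns progressive numbers, and converts signals into
SMS + call alerts; with GSM down the alert is recorded as undelivered —
the failure mode that accounted for the missed alarms in the field, where
the probes themselves triggered correctly. Temperatures outside the rated
−20…+55 °C log a warning and continue. `simulate_probe()` is vectorised
for speed; a property test folds `probe_step()` sample-by-sample over
random traces and asserts identical outcomes, so the fold semantics are
enforced rather than assumed.

## The synthetic cohort generator

`generate_cohort()` draws each delivery independently: alarm ~
Bernoulli(0.863); dystocia at 19/63 with severity split 10:5:4 over scores
1–3 (score 4 observed zero times, kept configurable); alarm-to-expulsion
intervals from truncated normals; application-to-calving spans mean 5.10,
sd 3.58 on 0–18 days; alert times from a two-window mixture putting 33.8%
of mass uniformly in 22:00–06:00 and the rest uniformly in 06:00–22:00
(implying ≈25.4% in 00:00–06:00, close to the observed 24.6%).

Two calibration points deserve emphasis:

* **Moment matching.** The interval targets are the *truncated* mean and
  sd. Parameterising a truncated normal naively at (57, 33) on [15, 146]
  yields a realised mean near 63 min; `match_truncnorm()` therefore solves
  for underlying (μ, σ) whose truncated moments hit the targets
  (least-squares via `optim`). For the dystocia interval the target sd 30
  on [24, 126] is infeasible — no truncated normal beats the uniform limit
  `(126−24)/√12 ≈ 29.4` — so the matcher lands at sd ≈ 29.2 with the mean
  essentially exact; this is the closest member of the family, accepted
  and documented rather than tuned.
* **Independence.** Dystocia is drawn at the same rate for non-alarmed
  deliveries (their scores are unobserved in real data), days-to-calving is
  independent of dystocia (the field difference, 4.4 vs 5.4 d, was not
  significant), and a truncated *lognormal* family is available behind
  `interval_family` for skew-sensitivity checks.

Unprinted quantities fixed once at realistic values: the parity mix
defaults to 35% primiparous (a typical replacement share in commercial
dairy herds); semen use follows the economics table (85% sorted in
heifers, 15% beef in older cows); APGAR components degrade stochastically
with dystocia severity (all field calves were born alive, so the generator
emulates vitality scoring, not mortality). GSM failure defaults to
`1 − p_alarm`, matching the attribution of missed alarms to the network:
`generate_trace()` always places the physical expulsion event in the
signal trace (light step plus a −3 °C/min cooling ramp toward ambient),
and failure is injected only at `dispatch_alert()`. Traces compress the
multi-day pre-calving span to a minutes-scale re-enactment with expulsion
defaulting to suspension + U(15, 180) min.

What passing tests show — and what they do not. Parameter recovery on a
20,000-delivery cohort (alarm rate within ±0.6 points of 86.3%, night
share within ±2 points of 33.8%, eutocia interval mean within ±1 min of
57) demonstrates that the generator and estimators are mutually
consistent, not that real calvings follow truncated normals or that
dystocia is independent of gestation length; cohort-level conclusions
about a real herd still require real records, which the CSV reader
ingests in the same schema.

## Problem sizes and runtime choices

The shipped tests use 60–100 random trees (depth ≤ 5, ≤ 4 branches) for
the rollback/enumeration oracle, exhaustive policy search on trees with
few decision nodes, cohorts of 8,000–20,000 for Monte-Carlo recovery at
the tolerances above, and 10,000 random traces plus 2,000 end-to-end GSM
draws for the probe properties — sizes at which the binomial tolerances
quoted are comfortably wider than sampling noise under the fixed seeds.

## Known limitations

* The economics are single-calving and short-term by design; replacement
  costs, milk and fertility losses are out of scope.
* The EMV model is risk-neutral; no utility curves, value-of-information
  or multi-criteria extensions.
* The generator draws deliveries independently; herd-level clustering
  (season, sire, pen) is not modelled.
* The probe simulation abstracts the radio link and SIM handling to a
  single GSM-available flag and models zero radio latency.
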