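---
title: "Screening controlled-substance orders: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening controlled-substance orders: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxscreen)
```

## The problem

Clinical decision support (CDS) systems embedded in an electronic health
record (EHR) can screen every opioid or benzodiazepine prescription order
at the moment the drug is selected, check the patient's record for risk
factors for misuse, diversion or overdose, and show the prescriber an
alert offering a choice: continue the prescription or cancel it.
`rxscreen` re-creates such a system as an inspectable, testable pipeline:
the rule engine, the prescriber-response taxonomy, a synthetic EHR
generator to drive it, and the statistics used to evaluate it (stratified
rates, categorical tests, Shewhart p-charts with special-cause rules).

The package is aimed at two audiences: informaticists who want an
executable, fully specified reference for this class of alerting logic,
and methodologists who want the surrounding measurement machinery —
"decision influenced" rates, trend tests over risk-factor counts, control
charts over monthly proportions — with every convention written down.

## The screening model

Every opioid/benzodiazepine order is evaluated against the patient's
history *strictly before the order time*: the alert fires at medication
selection, before the order exists, so nothing about the order itself (or
simultaneous sibling orders) can contribute to its own triggers.

The prescription alert fires when at least one of seven triggers is met:

| trigger | definition (defaults) |
|---|---|
| early refill | an active completed prior order of the same class with > 50% of its days supply remaining |
| repeated on-site administration | ≥ 2 distinct ED/urgent-care visits with on-site opioid/benzodiazepine administration in the prior 30 days |
| prescription frequency | ≥ 3 completed opioid/benzodiazepine orders in the prior 30 days |
| overdose history | any prior overdose presentation (lifetime) |
| positive toxicology | a positive blood-alcohol, cocaine or marijuana screen (unbounded lookback) |
| co-prescribing | an opioid ordered over an active benzodiazepine, or vice versa |
| extended-release to a naive patient | an extended-release opioid ordered with no opioid exposure in the prior 45 days |

Two further alerts fire independently of the prescription alert and of
each other: a **90-day alert** when continuous opioid therapy (gaps of up
to 7 days bridged) reaches 90 days, suggesting a pain agreement, and a
**naloxone alert** for patients at high overdose risk (co-prescribed
classes, combined daily morphine milligram equivalents strictly above 50,
or overdose history), suppressed by default when a naloxone prescription
is already active.

Morphine milligram equivalents (MME) are `strength_mg x units_per_day x
factor`, with the per-drug factor taken from a user-replaceable catalog
(`default_drug_catalog()` ships standard published factors: morphine 1,
hydrocodone 1, oxycodone 1.5, hydromorphone 4, codeine 0.15, tramadol
0.1). No reference version of the conversion table is canonical, so the
factors are configuration, never code.

### Temporal conventions

All windows are day-granular and *open at both ends*: an event counts
toward a window of `w` days at time `t` when its age `t - t_e` is
strictly positive and strictly below `w`. An event exactly `w` days old,
or at exactly `t`, does not count. Prescription coverage is the half-open
interval `[order_time, order_time + days_supply)`, so a 10-day supply
started 10 days ago is no longer active. Cancelled orders never create
exposure. These conventions are exercised directly by boundary tests and
by brute-force oracles over randomly generated histories.

Two windows the underlying clinical concepts leave open are exposed as
parameters with defaults chosen once: the opioid-naive lookback (45 days)
and the continuous-therapy gap tolerance (7 days). Sensible alternatives
(30/90-day naivety, 0–14-day tolerance) only rescale the corresponding
alert volumes; nothing in the engine depends on the specific values.

## Prescriber responses and the outcome taxonomy

Each fired prescription alert receives exactly one response, continue or
cancel. The *encounter* is the unit of analysis; an encounter whose
prescriber clicked cancel at least once is **decision influenced**.
Influenced encounters partition into **cancelled** (a controlled
prescription was still completed during the encounter — e.g. a
replacement order) and **none ordered** (no controlled prescription
completed). Encounters whose alerts were all continued are **continued**.
By construction

```
continued + cancelled + none_ordered = encounters with an alert
cancelled + none_ordered            = decision influenced
```

and `classify_encounters()` maintains these identities exactly; they are
asserted on every synthetic cohort in the test suite.

Responses to the 90-day and naloxone alerts are measured as follow-up
events — a pain agreement initiated, a naloxone prescription completed —
inside a 30-day horizon after the alert (the horizon is a package choice;
the source deployments report the fraction responding without fixing a
window).

## The synthetic cohort generator

`generate_cohort()` emulates the event stream such a deployment would
produce, at configurable scale. Design choices that matter:

**Planted factors, not rejection sampling.** Each trigger's defining
history is constructed directly — for early refill, a completed same-class
order two days before the index order with an 80%-full supply; for the
90-day alert, a chain of three 30-day supplies ending five days before the
index order; and so on. A planted factor therefore *always* fires its
trigger, and configured prevalences are the exact per-encounter firing
probabilities.

**Encounter isolation.** A patient's encounters are spaced at least 100
days apart (gap = 100 days + an exponential with mean 120). Planted
histories reach at most 95 days back and index supplies are at most 30
days, so no event planted for one encounter can satisfy any trigger
window of another encounter, and no trigger ever arises "organically".
This is what makes the generator's parameters interpretable — and it is
also what real data does *not* look like: real patients accumulate
overlapping prescriptions, repeat visits and genuinely ambiguous
histories. Passing recovery tests therefore demonstrates the correctness
of the engine's logic, not its calibration on any real population.

**Patient-level lifetime factors.** Overdose history and positive
toxicology have unbounded lookback, so they are planted per patient,
before the first encounter; every encounter of a flagged patient fires
them. Their prevalences are consequently recovered at patient level
(binomial in the number of patients), while the five windowed factors are
recovered at encounter level.

**Calibration.** Default per-trigger prevalences are proportional to the
trigger mix observed in a large multi-year deployment and scaled (by a
one-dimensional root-find inside `calibrate_prevalences()`) so the
implied alert rate is exactly the configured target, 23.5% of prescribing
encounters. One interaction is handled analytically: in a dual-class
encounter an early-refill plant (an active prior opioid) necessarily
makes the benzodiazepine sibling order fire co-prescribing, so the
co-prescribing sampling probability is shrunk to keep its marginal
prevalence exact.

**Responses.** Cancel probability is `plogis(intercept + slope x
trigger_count)`. The default is a flat 18.1% (`qlogis(0.181)`, slope 0),
the aggregate rate the analytics layer is calibrated around; a positive
slope reproduces the empirically observed increase of influence with the
number of risk factors. A cancelled initial order is followed by a
completed replacement with probability 0.62. An optional step change
(different intercept from a configured month on) exists solely to
exercise special-cause detection with a known change point.

Defaults place encounters over January 2016 – July 2019 with drug mix
75.6% opioid / 21.6% benzodiazepine / 2.8% both, 90-day-therapy
prevalence 11.9% and high-MME prevalence 10.6% among opioid encounters.

## Analytics

`rate_table()` produces decision-influenced rates per stratum with an
"all" cell; cells always partition the "all" counts exactly (missing
strata form an explicit `(missing)` cell). Contrasts between strata use
Pearson's chi-square (`stats::chisq.test`, no continuity correction);
ordered strata (number of triggers met) use the Cochran–Armitage trend
test in its signed-z form, whose square equals the standard chi-square
trend component and `stats::prop.trend.test`'s statistic — the test suite
checks both identities plus a permutation oracle.

### Rate reporting convention

Reported percentages are computed at full precision, rounded half-up to
two decimals and then half-up to one. The two-stage convention mirrors
report tables exported at two decimals and displayed at one, and it is
the convention under which the package's worked-example table reproduces
its source counts digit for digit (a handful of rates sit exactly on a
`x.x45` boundary, where one-stage rounding differs). Internal computation
is never rounded.

### p-charts and special-cause rules

`build_p_chart()` is a standard Shewhart p-chart: monthly proportion
`p_i = x_i / n_i`, center line pooled over the baseline period only
(calendar 2016 in the study design this mirrors; post-baseline data never
move the center), per-month sigma `sqrt(pbar (1 - pbar) / n_i)`, and zone
limits at 1, 2 and 3 sigma truncated to `[0, 1]`. The pooled (sum x /
sum n) center is the textbook p-chart definition; an average-of-monthly-
proportions center would weight small months up and is not used.

`detect_special_cause()` implements the standard rule set, each rule
individually toggleable with its run length exposed:

1. a point beyond 3 sigma;
2. 8 consecutive points on one side of the center line — points exactly
   on the center break the run (the common SPC convention);
3. 6 consecutive strictly increasing or decreasing points (ties break
   the run);
4. 2 of 3 consecutive points beyond 2 sigma on the same side;
5. 15 consecutive points within 1 sigma.

The shift rule's power is verified by simulation: a log-odds step of
+0.8 in cancel propensity at a known month, on a cohort sized to ~150
alerted encounters per month, is detected within 12 months in
effectively every replicate (the acceptance suite requires ≥ 95% of
200 seeded replicates).

## Problem sizes and degenerate inputs

The routine test suite runs cohorts between a few hundred and 12,000
patients; the full-pipeline recovery check uses ~100,000 prescribing
encounters (50,000 patients), at which size screening takes on the order
of ten seconds. Degenerate inputs are defined, not accidental: empty
event streams ingest to empty history sets; an empty drug catalog or an
empty p-chart baseline is a configuration error; a trend table that is
all successes or all failures returns z = 0, p = 1; zero-denominator rate
cells report `NA` and are flagged rather than dropped.

## Known limitations

* The generator's independence and isolation assumptions (no organic
  risk accumulation, independent planted factors, no seasonality) are
  deliberately unrealistic; see above for what that does and does not
  validate.
* The response model knows nothing about dose or duration modification
  of replacement prescriptions — only whether a controlled order
  completed — matching the coarseness of the cancel/continue signal
  itself.
* Chart reproduction for real deployments is structural (same
  construction and rules), not numeric: monthly series of real systems
  are not part of the package.
* The anomalously high influence rate sometimes reported for
  "other/unknown" prescriber types in deployment data is treated as a
  data artifact and is not a behavior the generator emulates.
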