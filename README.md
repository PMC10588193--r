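# rxscreen

Prescription risk screening, alerting and response analytics for
controlled substances.

Clinical decision support (CDS) embedded in an EHR can screen every
opioid or benzodiazepine order at the moment the drug is selected and
alert the prescriber when the patient's record carries risk factors for
misuse, diversion or overdose. `rxscreen` re-creates that system as a
testable pipeline:

* **Rule engine** — screens each order against seven risk triggers
  (early refill with > 50% of supply remaining; ≥ 2 ED/urgent-care visits
  with on-site administration in 30 days; ≥ 3 controlled prescriptions in
  30 days; overdose history; positive toxicology for blood alcohol,
  cocaine or marijuana; opioid–benzodiazepine co-prescribing;
  extended-release opioid to an opioid-naive patient) plus two
  independent guideline alerts: 90 days of continuous opioid therapy
  (pain agreement) and high overdose risk (naloxone co-prescribing, with
  daily morphine milligram equivalents MME = strength × units/day ×
  catalog factor, high risk at MME > 50).
* **Response model** — one continue/cancel response per fired alert;
  encounters where the prescriber cancelled at least once are *decision
  influenced*, partitioned exhaustively into *cancelled* (a controlled
  prescription still completed) and *none ordered*.
* **Synthetic EHR generator** — plants each trigger's defining history
  directly so configured prevalences are exact firing probabilities;
  calibrated so the default alert rate is 23.5% of prescribing encounters
  with cancel-given-alert 18.1%.
* **Analytics** — stratified rate tables, Pearson chi-square,
  Cochran–Armitage trend test (signed z with pooled-proportion variance),
  and Shewhart p-charts (center p̄ = Σx/Σn over a baseline period, limits
  p̄ ± k·√(p̄(1−p̄)/nᵢ), k = 1,2,3) with the standard special-cause rules
  (beyond 3σ; 8-point shift; 6-point trend; 2-of-3 beyond 2σ; 15 within
  1σ).

## Worked example

```r
library(rxscreen)

catalog   <- default_drug_catalog()
cohort    <- generate_cohort(simulation_config(n_patients = 5000, seed = 42))
decisions <- screen_cohort(cohort$events, catalog)
responses <- sample_responses(cohort, decisions)
outcomes  <- classify_encounters(decisions, responses)

rate_table(outcomes, by = "drug_class")
#> # A tibble: 4 × 6
#>   stratum        n_encounters n_influenced  rate rate_percent empty
#> 1 all                    2758          506 0.183         18.4 FALSE
#> 2 benzodiazepine          567          100 0.176         17.6 FALSE
#> 3 both                     69           21 0.304         30.4 FALSE
#> 4 opioid                 2122          385 0.181         18.1 FALSE
```

2,758 of this cohort's encounters fired an alert and 18.4% of those were
decision influenced — within sampling error of the configured 18.1%
cancel probability (dual-class encounters run higher because they can
receive two alerts). The monthly control chart of the influenced rate
uses calendar 2016 as its baseline:

```r
chart <- build_p_chart(monthly_counts(outcomes), c("2016-01-01", "2016-12-01"))
chart <- detect_special_cause(chart)
round(attr(chart, "center"), 3)
#> [1] 0.198
plot(chart)   # filled points mark special-cause evidence
```

The shipped deployment summary counts (a 3.5-year multi-center program,
2016–2019) serve as worked examples for the analytics layer; the rising
influence rate over the number of triggers met is strongly significant:

```r
counts <- alert_summary_counts()
tc <- counts[counts$group == "trigger_count", ]
res <- cochran_armitage_trend(tc$n_encounters, tc$n_influenced)
round(res$z_statistic, 1)
#> [1] 43.2
```

A thin command-line front end over the same functions lives at
`inst/scripts/rxscreen-cli.R` (`simulate` and `analyze` subcommands).

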