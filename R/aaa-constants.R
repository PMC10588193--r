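# package-wide constants (file named so it loads first)

EVENT_TYPES <- c("prescription", "administration", "tox_screen",
                 "overdose", "pain_agreement")

EVENT_COLUMNS <- c("patient_id", "encounter_id", "event_type", "time",
                   "order_id", "drug_code", "drug_class", "strength_mg",
                   "units_per_day", "days_supply", "status",
                   "prescriber_id", "prescriber_type", "specialty",
                   "facility_type", "visit_id", "visit_type",
                   "analyte", "positive", "substance_class")

TRIGGER_NAMES <- c("early_refill", "onsite_admin_2plus", "rx_3plus_30d",
                   "prior_overdose", "positive_tox", "co_prescribed",
                   "extended_release_naive")

RISK_FACTORS <- TRIGGER_NAMES  # the seven prescription-alert triggers

OUTCOME_LEVELS <- c("continued", "cancelled", "none_ordered", "no_alert")
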