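cat6 <- tiny_catalog()

op_order <- function(time, drug_code = "MORPHINE-IR-15", strength_mg = 5,
                     units_per_day = 1, days_supply = 5, encounter_id = "enc",
                     order_id = "new") {
  list(time = time, drug_code = drug_code, strength_mg = strength_mg,
       units_per_day = units_per_day, days_supply = days_supply,
       encounter_id = encounter_id, order_id = order_id)
}

test_that("fraction remaining is linear proration clamped to [0, 1]", {
  expect_equal(fraction_remaining(0, 10, 4), 0.6)
  expect_equal(fraction_remaining(0, 10, 0), 1)
  expect_equal(fraction_remaining(0, 10, 10), 0)
  expect_equal(fraction_remaining(0, 10, 15), 0)
  expect_equal(fraction_remaining(5, 10, 2), 1)  # not yet started
})

test_that("an empty history yields no triggers; class gate is enforced", {
  empty <- one_history(mk_rx(time = 1, drug_code = "X", days_supply = 1)[0, ])
  tr <- evaluate_risk_triggers(empty, op_order(100), cat6)
  expect_equal(tr$trigger_count, 0)
  expect_false(any(unlist(tr[, rxscreen:::TRIGGER_NAMES])))
  expect_error(evaluate_risk_triggers(empty, list(time = 1, drug_class = "other")),
               "opioid/benzodiazepine")
  expect_null(screen_order(empty, list(time = 1, drug_code = "NALOXONE-NASAL-4"),
                           cat6))
})

test_that("early refill needs an active same-class order above the threshold", {
  h <- one_history(mk_rx(time = 96, drug_code = "MORPHINE-IR-15",
                         days_supply = 10))
  tr <- evaluate_risk_triggers(h, op_order(100), cat6)  # 60% remaining
  expect_true(tr$early_refill)
  # exactly 50% remaining is not an early refill (strict >)
  at_half <- one_history(mk_rx(time = 95, drug_code = "MORPHINE-IR-15",
                               days_supply = 10))
  expect_false(evaluate_risk_triggers(at_half, op_order(100), cat6)$early_refill)
  # other class does not count under the same-class default, but does when
  # configured to any controlled class
  bz <- evaluate_risk_triggers(h, list(time = 100, drug_class = "benzodiazepine"),
                               cat6)
  expect_false(bz$early_refill)
  expect_true(bz$co_prescribed)
  any_cfg <- screen_config(early_refill_same_class = FALSE)
  expect_true(evaluate_risk_triggers(h, list(time = 100,
                                             drug_class = "benzodiazepine"),
                                     cat6, any_cfg)$early_refill)
})

test_that("onsite administrations count distinct ED/UC visits in 30 days", {
  two_visits <- one_history(mk_event(event_type = "administration",
                                     time = c(85, 95), visit_id = c("v1", "v2"),
                                     visit_type = "ed", drug_class = "opioid"))
  expect_true(evaluate_risk_triggers(two_visits, op_order(100),
                                     cat6)$onsite_admin_2plus)
  one_visit <- one_history(mk_event(event_type = "administration",
                                    time = c(85, 95), visit_id = "v1",
                                    visit_type = "ed", drug_class = "opioid"))
  expect_false(evaluate_risk_triggers(one_visit, op_order(100),
                                      cat6)$onsite_admin_2plus)
  # a visit exactly 30 days back is outside the half-open window
  edge <- one_history(mk_event(event_type = "administration",
                               time = c(70, 95), visit_id = c("v1", "v2"),
                               visit_type = "urgent_care", drug_class = "opioid"))
  expect_false(evaluate_risk_triggers(edge, op_order(100),
                                      cat6)$onsite_admin_2plus)
  # opioid-only configuration ignores benzodiazepine administrations
  bz_adm <- one_history(mk_event(event_type = "administration",
                                 time = c(85, 95), visit_id = c("v1", "v2"),
                                 visit_type = "ed",
                                 drug_class = "benzodiazepine"))
  expect_true(evaluate_risk_triggers(bz_adm, op_order(100),
                                     cat6)$onsite_admin_2plus)
  op_only <- screen_config(onsite_classes = "opioid")
  expect_false(evaluate_risk_triggers(bz_adm, op_order(100), cat6,
                                      op_only)$onsite_admin_2plus)
})

test_that("prescription frequency plus toxicology combine additively", {
  ev <- dplyr::bind_rows(
    mk_rx(time = c(75, 80, 85), drug_code = "MORPHINE-IR-15", days_supply = 3,
          order_id = paste0("o", 1:3)),
    mk_event(event_type = "tox_screen", time = 50, analyte = "cocaine",
             positive = TRUE))
  tr <- evaluate_risk_triggers(one_history(ev), op_order(100), cat6)
  expect_true(tr$rx_3plus_30d)
  expect_true(tr$positive_tox)
  expect_equal(tr$trigger_count, 2)
  # cancelled orders never create exposure
  cx <- mk_rx(time = c(75, 80, 85), drug_code = "MORPHINE-IR-15",
              days_supply = 3, status = "cancelled", order_id = paste0("c", 1:3))
  expect_false(evaluate_risk_triggers(one_history(cx), op_order(100),
                                      cat6)$rx_3plus_30d)
  # negative screens and non-qualifying analytes do not trigger
  neg <- mk_event(event_type = "tox_screen", time = c(50, 60),
                  analyte = c("cocaine", "other"), positive = c(FALSE, TRUE))
  expect_false(evaluate_risk_triggers(one_history(neg), op_order(100),
                                      cat6)$positive_tox)
  # a finite lookback excludes old screens
  old_tox <- one_history(mk_event(event_type = "tox_screen", time = 50,
                                  analyte = "cocaine", positive = TRUE))
  lim <- screen_config(tox_lookback_days = 30)
  expect_false(evaluate_risk_triggers(old_tox, op_order(100), cat6,
                                      lim)$positive_tox)
})

test_that("an extended-release order for a naive patient triggers on its own", {
  empty <- one_history(mk_rx(time = 1, drug_code = "X", days_supply = 1)[0, ])
  tr <- evaluate_risk_triggers(empty, op_order(100, "MORPHINE-ER-30",
                                               strength_mg = 30), cat6)
  expect_true(tr$extended_release_naive)
  expect_equal(tr$trigger_count, 1)
  exposed <- one_history(mk_rx(time = 90, drug_code = "MORPHINE-IR-15",
                               days_supply = 30))
  expect_false(evaluate_risk_triggers(exposed, op_order(100, "MORPHINE-ER-30",
                                                        strength_mg = 30),
                                      cat6)$extended_release_naive)
})

test_that("the 90-day alert needs 90 continuous opioid days and an opioid order", {
  at90 <- one_history(mk_rx(time = c(10, 55), drug_code = "MORPHINE-IR-15",
                            days_supply = 45, order_id = c("a", "b")))
  expect_true(evaluate_90day(at90, op_order(100), cat6))
  at89 <- one_history(mk_rx(time = c(11, 55), drug_code = "MORPHINE-IR-15",
                            days_supply = c(44, 45), order_id = c("a", "b")))
  expect_false(evaluate_90day(at89, op_order(100), cat6))
  expect_false(evaluate_90day(at90, list(time = 100,
                                         drug_class = "benzodiazepine"), cat6))
})

test_that("the naloxone alert uses strict MME > 50, overdose, co-prescribing and suppression", {
  empty <- one_history(mk_rx(time = 1, drug_code = "X", days_supply = 1)[0, ])
  # combined daily MME exactly 50 does not qualify
  at50 <- op_order(100, "OXYCODONE-10", strength_mg = 10,
                   units_per_day = 10 / 3)  # 10 * (10/3) * 1.5 = 50
  expect_false(evaluate_naloxone(empty, at50, cat6))
  over <- op_order(100, "OXYCODONE-10", strength_mg = 10, units_per_day = 4)
  expect_true(evaluate_naloxone(empty, over, cat6))
  # active concurrent opioids are summed under the default
  conc <- one_history(mk_rx(time = 95, drug_code = "MORPHINE-IR-15",
                            strength_mg = 30, units_per_day = 1,
                            days_supply = 30))
  low_new <- op_order(100, "OXYCODONE-10", strength_mg = 10, units_per_day = 2)
  expect_true(evaluate_naloxone(conc, low_new, cat6))  # 30 + 30 > 50
  solo_cfg <- screen_config(naloxone_combined_mme = FALSE)
  expect_false(evaluate_naloxone(conc, low_new, cat6, solo_cfg))
  od <- one_history(mk_event(event_type = "overdose", time = 10,
                             substance_class = "opioid"))
  expect_true(evaluate_naloxone(od, op_order(100), cat6))
  # an active naloxone prescription suppresses the alert unless disabled
  ev <- dplyr::bind_rows(
    mk_event(event_type = "overdose", time = 10, substance_class = "opioid"),
    mk_rx(time = 98, drug_code = "NALOXONE-NASAL-4", days_supply = 30,
          order_id = "nx"))
  covered <- one_history(ev)
  expect_false(evaluate_naloxone(covered, op_order(100), cat6))
  no_sup <- screen_config(naloxone_suppression = FALSE)
  expect_true(evaluate_naloxone(covered, op_order(100), cat6, no_sup))
})

test_that("screen_order aggregates the three alert pathways independently", {
  one_factor <- one_history(mk_event(event_type = "overdose", time = 10,
                                     substance_class = "opioid"))
  d <- screen_order(one_factor, op_order(100), cat6)
  expect_true(d$prescription_alert)
  expect_equal(d$trigger_count, 1)
  expect_true(d$naloxone_alert)  # overdose history is also high-risk
  # 90-day plus high-risk on one order sets both flags simultaneously
  both <- one_history(mk_rx(time = c(10, 55), drug_code = "MORPHINE-IR-15",
                            strength_mg = 30, days_supply = 45,
                            order_id = c("a", "b"))[, ])
  d2 <- screen_order(both, op_order(100, "OXYCODONE-10", strength_mg = 10,
                                    units_per_day = 4), cat6)
  expect_true(d2$ninety_day_alert)
  expect_true(d2$naloxone_alert)
  expect_true(d2$early_refill %in% c(TRUE, FALSE))  # decision carries flags
})

test_that("screening is pure in the history before the order time", {
  ev <- random_history_events(77)
  h1 <- one_history(ev)
  future <- dplyr::bind_rows(ev, mk_event(event_type = "overdose", time = 399,
                                          substance_class = "opioid"))
  h2 <- one_history(future)
  o <- op_order(300)
  expect_equal(screen_order(h1, o, cat6)[, rxscreen:::TRIGGER_NAMES],
               screen_order(h2, o, cat6)[, rxscreen:::TRIGGER_NAMES])
})

test_that("adding a qualifying event never unsets a count-based trigger", {
  set.seed(21)
  for (i in 1:25) {
    ev <- random_history_events(400 + i)
    h <- one_history(ev)
    o <- op_order(sample(100:300, 1))
    before <- evaluate_risk_triggers(h, o, cat6)
    extra <- dplyr::bind_rows(
      ev,
      mk_rx(time = o$time - sample(1:25, 1), drug_code = "MORPHINE-IR-15",
            days_supply = 2, order_id = "extra"),
      mk_event(event_type = "overdose", time = o$time - 50,
               substance_class = "opioid"))
    after <- evaluate_risk_triggers(one_history(extra), o, cat6)
    for (tr in c("onsite_admin_2plus", "rx_3plus_30d", "prior_overdose",
                 "positive_tox")) {
      expect_true(after[[tr]] >= before[[tr]])
    }
  }
})

test_that("trigger_count equals the sum of independent single-trigger oracles", {
  n_checked <- 0
  for (seed in 1:600) {
    ev <- random_history_events(1000 + seed)
    if (!nrow(ev)) next
    h <- one_history(ev)
    set.seed(2000 + seed)
    code <- sample(c("MORPHINE-IR-15", "DIAZEPAM-5", "MORPHINE-ER-30"), 1)
    o <- list(time = sample(50:400, 1), drug_code = code,
              strength_mg = 10, units_per_day = 1, days_supply = 5)
    tr <- evaluate_risk_triggers(h, o, cat6)
    oo <- o
    oo$drug_class <- classify_drug(cat6, code)
    oo$extended_release <- code == "MORPHINE-ER-30"
    want <- oracle_triggers(ev, cat6, oo)
    expect_equal(unlist(tr[, rxscreen:::TRIGGER_NAMES]), want,
                 info = paste("seed", seed))
    expect_equal(tr$trigger_count, sum(want))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 500)
})

test_that("the cohort screener agrees with per-order screening", {
  cfg <- simulation_config(n_patients = 120, n_encounters_mean = 2,
                           seed = 99)
  coh <- generate_cohort(cfg)
  cat <- default_drug_catalog()
  dec <- screen_cohort(coh$events, cat)
  hist <- ingest_events(coh$events, cat)
  rxs <- coh$events[coh$events$event_type == "prescription", ]
  for (i in seq_len(nrow(dec))) {
    row <- dec[i, ]
    src <- rxs[rxs$order_id == row$order_id, ]
    o <- list(time = src$time, drug_code = src$drug_code,
              strength_mg = src$strength_mg, units_per_day = src$units_per_day,
              days_supply = src$days_supply, order_id = src$order_id,
              encounter_id = src$encounter_id)
    single <- screen_order(hist[[src$patient_id]], o, cat)
    cols <- c(rxscreen:::TRIGGER_NAMES, "trigger_count", "prescription_alert",
              "ninety_day_alert", "naloxone_alert")
    expect_equal(as.list(row[, cols]), as.list(single[, cols]),
                 info = row$order_id)
  }
})

test_that("screening config files round-trip through yaml", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("refill_threshold: 0.4", "rx_window_days: 21",
               "tox_lookback_days: unbounded",
               "onsite_classes: [opioid]"), tmp)
  cfg <- read_screen_config(tmp)
  expect_equal(cfg$refill_threshold, 0.4)
  expect_equal(cfg$rx_window_days, 21)
  expect_true(is.infinite(cfg$tox_lookback_days))
  expect_equal(cfg$onsite_classes, "opioid")
  writeLines("not_a_window: 3", tmp)
  expect_error(read_screen_config(tmp), "unknown")
})
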