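# fixtures built in code + independent brute-force oracles

tiny_catalog <- function() {
  drug_catalog(data.frame(
    drug_code = c("MORPHINE-IR-15", "OXYCODONE-10", "MORPHINE-ER-30",
                  "DIAZEPAM-5", "LORAZEPAM-1", "NALOXONE-NASAL-4"),
    name = c("morphine", "oxycodone", "morphine ER", "diazepam",
             "lorazepam", "naloxone"),
    drug_class = c("opioid", "opioid", "opioid", "benzodiazepine",
                   "benzodiazepine", "naloxone"),
    mme_factor = c(1, 1.5, 1, NA, NA, NA),
    extended_release = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)))
}

# build an event tibble from compact per-type argument lists
mk_rx <- function(patient_id = "p1", encounter_id = "e1", time, drug_code,
                  days_supply, status = "completed", strength_mg = 5,
                  units_per_day = 1, order_id = NULL) {
  n <- length(time)
  tibble::tibble(patient_id = patient_id, encounter_id = encounter_id,
                 event_type = "prescription", time = time,
                 drug_code = drug_code, days_supply = days_supply,
                 status = status, strength_mg = strength_mg,
                 units_per_day = units_per_day,
                 order_id = order_id %||% paste0("o", seq_len(n)))
}

mk_event <- function(patient_id = "p1", event_type, time, ...) {
  tibble::tibble(patient_id = patient_id, encounter_id = NA_character_,
                 event_type = event_type, time = time, ...)
}

one_history <- function(events, catalog = tiny_catalog()) {
  if (nrow(events) == 0) return(empty_history())
  ingest_events(events, catalog)[[1]]
}

empty_history <- function(patient_id = "p1") {
  blank <- as.data.frame(rxscreen:::validate_events(
    mk_rx(time = 1, drug_code = "X", days_supply = 1)))[0, ]
  rxscreen:::new_patient_history(patient_id, blank, blank, blank, blank, blank)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random one-patient event set on integer days 0..400
random_history_events <- function(seed) {
  set.seed(seed)
  n_rx <- sample(0:8, 1)
  ev <- list()
  if (n_rx > 0) {
    ev <- c(ev, list(mk_rx(
      time = sample(0:400, n_rx, replace = TRUE),
      drug_code = sample(c("MORPHINE-IR-15", "OXYCODONE-10", "MORPHINE-ER-30",
                           "DIAZEPAM-5", "NALOXONE-NASAL-4"), n_rx, TRUE),
      days_supply = sample(1:60, n_rx, TRUE),
      status = sample(c("completed", "completed", "cancelled"), n_rx, TRUE),
      strength_mg = sample(c(5, 10, 30), n_rx, TRUE),
      units_per_day = sample(1:3, n_rx, TRUE),
      order_id = paste0("r", seq_len(n_rx)))))
  }
  n_ad <- sample(0:4, 1)
  if (n_ad > 0) {
    ev <- c(ev, list(mk_event(event_type = "administration",
                              time = sample(0:400, n_ad, TRUE),
                              visit_id = paste0("v", sample(1:3, n_ad, TRUE)),
                              visit_type = sample(c("ed", "urgent_care", "other"),
                                                  n_ad, TRUE),
                              drug_class = sample(c("opioid", "benzodiazepine"),
                                                  n_ad, TRUE))))
  }
  n_tx <- sample(0:3, 1)
  if (n_tx > 0) {
    ev <- c(ev, list(mk_event(event_type = "tox_screen",
                              time = sample(0:400, n_tx, TRUE),
                              analyte = sample(c("cocaine", "marijuana",
                                                 "blood_alcohol", "other"),
                                               n_tx, TRUE),
                              positive = sample(c(TRUE, FALSE), n_tx, TRUE))))
  }
  if (sample(c(TRUE, FALSE), 1)) {
    ev <- c(ev, list(mk_event(event_type = "overdose",
                              time = sample(0:400, 1),
                              substance_class = "opioid")))
  }
  if (sample(c(TRUE, FALSE), 1)) {
    ev <- c(ev, list(mk_event(event_type = "pain_agreement",
                              time = sample(0:400, 1))))
  }
  if (!length(ev)) return(mk_rx(time = 1, drug_code = "MORPHINE-IR-15",
                                days_supply = 1)[0, ])
  dplyr::bind_rows(ev)
}

# oracle: linear scan for events_in_window (both window ends exclusive:
# age strictly positive and strictly under w days)
brute_window <- function(df, t, w) {
  keep <- vapply(df$time, function(ti) (t - ti) > 0 && (t - ti) < w, logical(1))
  df[keep, , drop = FALSE]
}

# oracle: day-by-day coverage bitmap for continuous_opioid_days (integer
# day inputs); gaps of <= tol uncovered days are bridged
bitmap_continuous_days <- function(orders, t, tol) {
  op <- orders[orders$status == "completed" & orders$drug_class == "opioid" &
                 orders$time <= t, , drop = FALSE]
  if (nrow(op) == 0) return(0)
  days <- sort(unique(unlist(Map(function(s, d) seq(s, s + d - 1), op$time,
                                 op$days_supply))))
  runs <- split(days, cumsum(c(1, diff(days) > tol + 1)))
  run <- runs[[length(runs)]]
  last_day <- run[length(run)]
  if (t - (last_day + 1) > tol || run[1] > t) {
    # the last bridged run does not reach t; no earlier run can either
    return(0)
  }
  t - run[1]
}

# independent single-trigger oracles (simple loops, default config);
# validate_events() only normalizes the column schema
oracle_triggers <- function(events, catalog, order) {
  events <- rxscreen:::validate_events(events)
  t <- order$time
  rx <- events[events$event_type == "prescription", , drop = FALSE]
  rx$cls <- classify_drug(catalog, rx$drug_code)
  comp <- rx[rx$status == "completed" & rx$time < t, , drop = FALSE]
  early <- FALSE
  for (i in seq_len(nrow(comp))) {
    if (comp$cls[i] == order$drug_class &&
        comp$time[i] + comp$days_supply[i] > t &&
        (1 - (t - comp$time[i]) / comp$days_supply[i]) > 0.5) early <- TRUE
  }
  ad <- events[events$event_type == "administration", , drop = FALSE]
  vis <- character(0)
  for (i in seq_len(nrow(ad))) {
    if (ad$time[i] > t - 30 && ad$time[i] < t &&
        ad$visit_type[i] %in% c("ed", "urgent_care") &&
        ad$drug_class[i] %in% c("opioid", "benzodiazepine")) {
      vis <- union(vis, ad$visit_id[i])
    }
  }
  n_rx30 <- 0
  for (i in seq_len(nrow(comp))) {
    if (comp$time[i] > t - 30 && comp$cls[i] %in% c("opioid", "benzodiazepine")) {
      n_rx30 <- n_rx30 + 1
    }
  }
  od <- events[events$event_type == "overdose", , drop = FALSE]
  tx <- events[events$event_type == "tox_screen", , drop = FALSE]
  tox <- FALSE
  for (i in seq_len(nrow(tx))) {
    if (tx$time[i] < t && isTRUE(tx$positive[i]) &&
        tx$analyte[i] %in% c("blood_alcohol", "cocaine", "marijuana")) tox <- TRUE
  }
  opp <- if (order$drug_class == "opioid") "benzodiazepine" else "opioid"
  co <- FALSE
  for (i in seq_len(nrow(comp))) {
    if (comp$cls[i] == opp && comp$time[i] + comp$days_supply[i] > t) co <- TRUE
  }
  er <- FALSE
  if (order$drug_class == "opioid" && isTRUE(order$extended_release)) {
    exposed <- FALSE
    for (i in seq_len(nrow(comp))) {
      if (comp$cls[i] == "opioid" && comp$time[i] + comp$days_supply[i] > t - 45) {
        exposed <- TRUE
      }
    }
    for (i in seq_len(nrow(ad))) {
      if (ad$drug_class[i] == "opioid" && ad$time[i] > t - 45 && ad$time[i] < t) {
        exposed <- TRUE
      }
    }
    er <- !exposed
  }
  c(early_refill = early, onsite_admin_2plus = length(vis) >= 2,
    rx_3plus_30d = n_rx30 >= 3, prior_overdose = any(od$time < t),
    positive_tox = tox, co_prescribed = co, extended_release_naive = er)
}
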