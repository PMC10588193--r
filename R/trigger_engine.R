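# The trigger engine: screens each opioid/benzodiazepine order against the
# risk triggers and the three guideline alerts, emitting an AlertDecision.

#' Screening configuration
#'
#' All tunable windows and thresholds of the trigger engine, with the
#' defaults used throughout the package. Every value is configuration;
#' none is hard-coded in the engine.
#'
#' @param refill_threshold fraction of days supply remaining above which a
#'   still-active prior order counts as an "early refill". Default 0.5.
#' @param admin_window_days,min_admin_visits window and visit count for the
#'   repeated on-site administration trigger (default: 2+ distinct ED or
#'   urgent-care visits with on-site administration in the prior 30 days).
#' @param rx_window_days,min_rx_count window and count for the prescription
#'   frequency trigger (default: 3+ completed opioid/benzodiazepine orders
#'   in the prior 30 days).
#' @param naive_lookback_days lookback defining "opioid-naive". Default 45.
#' @param gap_tolerance_days gap merged when measuring continuous opioid
#'   therapy. Default 7.
#' @param ninety_day_threshold continuous-therapy days at which the pain
#'   agreement alert fires. Default 90.
#' @param mme_threshold daily MME above which (strictly) the naloxone
#'   alert's dose condition is met. Default 50.
#' @param tox_lookback_days lookback for positive toxicology screens;
#'   `Inf` (the default) means any prior screen in the record.
#' @param tox_analytes analytes that qualify for the toxicology trigger.
#' @param onsite_classes drug classes counted by the on-site
#'   administration trigger. Default both controlled classes.
#' @param early_refill_same_class compare the new order against prior
#'   orders of the same drug class only (default) or any controlled class.
#' @param naloxone_combined_mme sum the new order's daily MME with active
#'   concurrent opioid orders (default, the clinically conservative
#'   reading) or use the new order alone.
#' @param naloxone_suppression suppress the naloxone alert when an active
#'   naloxone prescription already exists. Default TRUE.
#' @param follow_up_horizon_days window after a 90-day or naloxone alert in
#'   which a pain agreement / naloxone prescription counts as a response.
#'   Default 30.
#' @return a `screen_config` list.
#' @export
screen_config <- function(refill_threshold = 0.5,
                          admin_window_days = 30, min_admin_visits = 2,
                          rx_window_days = 30, min_rx_count = 3,
                          naive_lookback_days = 45,
                          gap_tolerance_days = 7,
                          ninety_day_threshold = 90,
                          mme_threshold = 50,
                          tox_lookback_days = Inf,
                          tox_analytes = c("blood_alcohol", "cocaine", "marijuana"),
                          onsite_classes = c("opioid", "benzodiazepine"),
                          early_refill_same_class = TRUE,
                          naloxone_combined_mme = TRUE,
                          naloxone_suppression = TRUE,
                          follow_up_horizon_days = 30) {
  cfg <- list(refill_threshold = refill_threshold,
              admin_window_days = admin_window_days,
              min_admin_visits = min_admin_visits,
              rx_window_days = rx_window_days,
              min_rx_count = min_rx_count,
              naive_lookback_days = naive_lookback_days,
              gap_tolerance_days = gap_tolerance_days,
              ninety_day_threshold = ninety_day_threshold,
              mme_threshold = mme_threshold,
              tox_lookback_days = tox_lookback_days,
              tox_analytes = tox_analytes,
              onsite_classes = onsite_classes,
              early_refill_same_class = isTRUE(early_refill_same_class),
              naloxone_combined_mme = isTRUE(naloxone_combined_mme),
              naloxone_suppression = isTRUE(naloxone_suppression),
              follow_up_horizon_days = follow_up_horizon_days)
  stopifnot(cfg$refill_threshold >= 0, cfg$refill_threshold <= 1,
            cfg$admin_window_days >= 1, cfg$rx_window_days >= 1,
            cfg$naive_lookback_days >= 1, cfg$gap_tolerance_days >= 0,
            cfg$mme_threshold >= 0, cfg$follow_up_horizon_days >= 1)
  structure(cfg, class = "screen_config")
}

#' Read a screening configuration from a YAML file
#'
#' Keys mirror the arguments of [screen_config()]; `tox_lookback_days:
#' unbounded` maps to `Inf`. Unknown keys are an error.
#'
#' @param path path to a YAML file.
#' @return a `screen_config`.
#' @export
read_screen_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(screen_config)))
  if (length(unknown)) {
    stop("unknown screening config keys: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(vals$tox_lookback_days) &&
      identical(vals$tox_lookback_days, "unbounded")) {
    vals$tox_lookback_days <- Inf
  }
  do.call(screen_config, vals)
}

#' Fraction of a prescription's days supply remaining
#'
#' Linear proration: `max(0, 1 - elapsed_days / days_supply)` clamped to
#' `[0, 1]`; a query before the order's start returns 1 (not yet started).
#'
#' @param order_time order start (numeric day, `Date` or ISO string).
#' @param days_supply supply length in days (>= 1).
#' @param t query time.
#' @return numeric in `[0, 1]`, vectorized over orders.
#' @export
fraction_remaining <- function(order_time, days_supply, t) {
  stopifnot(all(days_supply >= 1))
  elapsed <- day_number(t) - day_number(order_time)
  pmin(1, pmax(0, 1 - elapsed / days_supply))
}

# normalize an order argument (one-row data frame or list) and derive
# class / ER flag / daily MME from the catalog where needed
as_order <- function(order, catalog = NULL) {
  o <- as.list(order)
  if (is.null(o$time)) o$time <- o$order_time
  if (is.null(o$time)) stop("order must carry a 'time' (or 'order_time') field")
  o$time <- day_number(o$time)
  if (!is.null(catalog) && !is.null(o$drug_code)) {
    o$drug_class <- classify_drug(catalog, o$drug_code)
    er <- catalog$extended_release[match(o$drug_code, catalog$drug_code)]
    o$extended_release <- isTRUE(er)
  }
  if (is.null(o$drug_class)) stop("order must carry 'drug_class' or a catalog 'drug_code'")
  o$extended_release <- isTRUE(o$extended_release)
  o
}

# restrict a history to events strictly before t: screening is a pure
# function of the history restricted to times < order_time
restrict_history <- function(history, t) {
  cut1 <- function(df) df[df$time < t, , drop = FALSE]
  new_patient_history(history$patient_id,
                      prescriptions = cut1(history$prescriptions),
                      administrations = cut1(history$administrations),
                      tox_screens = cut1(history$tox_screens),
                      overdoses = cut1(history$overdoses),
                      pain_agreements = cut1(history$pain_agreements))
}

#' Evaluate the prescription-alert risk triggers for one order
#'
#' Evaluates the seven risk triggers against the patient history restricted
#' to events strictly before the order time:
#' * `early_refill`: an active completed prior order of the same class with
#'   more than `refill_threshold` of its supply remaining;
#' * `onsite_admin_2plus`: at least `min_admin_visits` distinct ED/urgent
#'   care visits with qualifying on-site administration in the prior
#'   `admin_window_days`;
#' * `rx_3plus_30d`: at least `min_rx_count` completed controlled orders in
#'   the prior `rx_window_days`;
#' * `prior_overdose`: any prior overdose presentation (lifetime);
#' * `positive_tox`: a positive qualifying toxicology screen within
#'   `tox_lookback_days`;
#' * `co_prescribed`: an opioid ordered over an active benzodiazepine or
#'   vice versa;
#' * `extended_release_naive`: an extended-release opioid ordered for an
#'   opioid-naive patient.
#'
#' @param history a `patient_history`.
#' @param order a one-row data frame or list with at least `time` and
#'   `drug_class` (class must be `"opioid"` or `"benzodiazepine"`), plus
#'   `extended_release` or a catalog `drug_code`.
#' @param catalog optional [drug_catalog()] used to derive class/ER flags.
#' @param config a [screen_config()].
#' @return one-row tibble with the seven logical flags and `trigger_count`.
#' @export
evaluate_risk_triggers <- function(history, order, catalog = NULL,
                                   config = screen_config()) {
  o <- as_order(order, catalog)
  if (!o$drug_class %in% c("opioid", "benzodiazepine")) {
    stop("risk triggers are defined only for opioid/benzodiazepine orders")
  }
  t <- o$time
  h <- restrict_history(history, t)
  p <- h$prescriptions
  comp <- p[p$status == "completed", , drop = FALSE]

  same_class <- if (config$early_refill_same_class) {
    comp$drug_class == o$drug_class
  } else {
    comp$drug_class %in% c("opioid", "benzodiazepine")
  }
  fr <- if (nrow(comp)) fraction_remaining(comp$time, comp$days_supply, t) else numeric(0)
  active <- comp$time + comp$days_supply > t
  early_refill <- any(same_class & active & fr > config$refill_threshold)

  a <- h$administrations
  in_w <- a$time > t - config$admin_window_days &
    a$visit_type %in% c("ed", "urgent_care") &
    a$drug_class %in% config$onsite_classes
  onsite_admin_2plus <- length(unique(a$visit_id[in_w])) >= config$min_admin_visits

  rx_3plus_30d <- sum(comp$time > t - config$rx_window_days &
                        comp$drug_class %in% c("opioid", "benzodiazepine")) >=
    config$min_rx_count

  prior_overdose <- nrow(h$overdoses) > 0

  tx <- h$tox_screens
  lb <- config$tox_lookback_days
  positive_tox <- any(tx$positive & tx$analyte %in% config$tox_analytes &
                        (is.infinite(lb) | tx$time > t - lb))

  opposite <- if (o$drug_class == "opioid") "benzodiazepine" else "opioid"
  co_prescribed <- any(comp$drug_class == opposite &
                         comp$time + comp$days_supply > t)

  extended_release_naive <- o$drug_class == "opioid" && o$extended_release &&
    is_opioid_naive(history, t, config$naive_lookback_days)

  flags <- c(early_refill = early_refill,
             onsite_admin_2plus = onsite_admin_2plus,
             rx_3plus_30d = rx_3plus_30d,
             prior_overdose = prior_overdose,
             positive_tox = positive_tox,
             co_prescribed = co_prescribed,
             extended_release_naive = extended_release_naive)
  tibble::as_tibble(c(as.list(flags), list(trigger_count = sum(flags))))
}

#' Does the 90-day continuous-therapy alert fire for this order?
#'
#' TRUE iff the order is an opioid and the patient's continuous opioid
#' therapy (gaps up to `gap_tolerance_days` bridged) has reached
#' `ninety_day_threshold` days at the order time. This alert suggests
#' initiating a pain agreement and regular urine drug screens.
#'
#' @inheritParams evaluate_risk_triggers
#' @return logical scalar.
#' @export
evaluate_90day <- function(history, order, catalog = NULL,
                           config = screen_config()) {
  o <- as_order(order, catalog)
  if (o$drug_class != "opioid") return(FALSE)
  h <- restrict_history(history, o$time)
  continuous_opioid_days(h, o$time, config$gap_tolerance_days) >=
    config$ninety_day_threshold
}

#' Does the naloxone co-prescribing alert fire for this order?
#'
#' The alert suggests prescribing naloxone for patients at high overdose
#' risk: co-prescribed opioids and benzodiazepines, daily MME strictly
#' above `mme_threshold`, or a history of overdose. With
#' `naloxone_combined_mme` (the default) the dose condition sums the new
#' order's daily MME with active concurrent opioid orders. By default the
#' alert is suppressed when an active naloxone prescription already exists
#' (`naloxone_suppression = FALSE` disables the rule).
#'
#' @inheritParams evaluate_risk_triggers
#' @param catalog a [drug_catalog()] (required: MME factors live there).
#' @return logical scalar.
#' @export
evaluate_naloxone <- function(history, order, catalog,
                              config = screen_config()) {
  o <- as_order(order, catalog)
  if (!o$drug_class %in% c("opioid", "benzodiazepine")) {
    stop("naloxone alert is defined only for opioid/benzodiazepine orders")
  }
  t <- o$time
  h <- restrict_history(history, t)
  comp <- h$prescriptions[h$prescriptions$status == "completed", , drop = FALSE]
  active <- comp$time + comp$days_supply > t

  opposite <- if (o$drug_class == "opioid") "benzodiazepine" else "opioid"
  co <- any(comp$drug_class == opposite & active)

  own <- if (!is.null(o$drug_code) && !is.null(o$strength_mg)) {
    daily_mme(catalog, data.frame(drug_code = o$drug_code,
                                  strength_mg = o$strength_mg,
                                  units_per_day = o$units_per_day,
                                  days_supply = o$days_supply %||% 1))$daily_mme
  } else 0
  conc <- 0
  if (config$naloxone_combined_mme) {
    act_op <- comp[active & comp$drug_class == "opioid", , drop = FALSE]
    if (nrow(act_op)) {
      conc <- sum(daily_mme(catalog, act_op)$daily_mme)
    }
  }
  high_mme <- (own + conc) > config$mme_threshold

  overdose <- nrow(h$overdoses) > 0

  at_risk <- co || high_mme || overdose
  if (at_risk && config$naloxone_suppression) {
    has_naloxone <- any(comp$drug_class == "naloxone" & active)
    if (has_naloxone) return(FALSE)
  }
  at_risk
}

#' Screen one order
#'
#' Aggregates the three evaluations into an alert decision. The
#' prescription alert fires iff at least one risk trigger is set; the
#' 90-day and naloxone alerts fire independently of it and of each other.
#' Non-controlled orders (class `other`/`naloxone`) pass through with no
#' decision (`NULL`).
#'
#' @inheritParams evaluate_naloxone
#' @return a one-row tibble (the alert decision) with the trigger flags,
#'   `trigger_count`, `prescription_alert`, `ninety_day_alert` and
#'   `naloxone_alert`, or `NULL` for non-controlled orders.
#' @examples
#' h <- ingest_events(tibble::tibble(
#'   patient_id = "p1", encounter_id = "e0", event_type = "overdose",
#'   time = "2016-01-01"))[["p1"]]
#' screen_order(h, list(time = "2016-06-01", drug_class = "opioid"),
#'              default_drug_catalog())
#' @export
screen_order <- function(history, order, catalog, config = screen_config()) {
  o <- as_order(order, catalog)
  if (!o$drug_class %in% c("opioid", "benzodiazepine")) return(NULL)
  triggers <- evaluate_risk_triggers(history, o, NULL, config)
  decision <- tibble::tibble(
    order_id = o$order_id %||% NA_character_,
    patient_id = history$patient_id,
    encounter_id = o$encounter_id %||% NA_character_,
    time = o$time,
    drug_class = o$drug_class)
  decision <- dplyr::bind_cols(decision, triggers)
  decision$prescription_alert <- decision$trigger_count >= 1
  decision$ninety_day_alert <- evaluate_90day(history, o, NULL, config)
  decision$naloxone_alert <- evaluate_naloxone(history, o, catalog, config)
  decision
}
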