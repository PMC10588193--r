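# Synthetic EHR event generator.
#
# Risk factors are PLANTED: each trigger's defining history is constructed
# directly (e.g. for early refill, a recent completed order with > 50% of
# its supply unelapsed at the index order time), so configured prevalences
# are interpretable as the exact per-encounter firing probabilities.
# Per-patient encounters are spaced >= min_gap_days apart; with plants
# reaching at most 95 days back and index supplies <= 30 days, no event
# planted for one encounter can satisfy a trigger window of another, and
# triggers never arise organically. Lifetime-lookback factors (overdose
# history, positive toxicology) are planted at PATIENT level before the
# first encounter, so every encounter of a flagged patient fires them.

#' Calibrated per-trigger prevalences
#'
#' Finds per-encounter planting probabilities proportional to `weights`
#' such that the implied prescription-alert rate (one minus the product of
#' the per-trigger miss probabilities, accounting for the co-prescribing
#' overlap induced by early-refill plants in dual-class encounters) equals
#' `target_alert_rate`. Default weights follow the relative encounter
#' volume of the seven triggers in a large multi-year CDS deployment.
#'
#' @param target_alert_rate the marginal probability that an encounter
#'   fires at least one risk trigger. Default 0.235.
#' @param weights named nonnegative weights over the seven triggers.
#' @param p_both probability that an encounter carries both an opioid and
#'   a benzodiazepine order.
#' @return named numeric vector of marginal per-encounter prevalences.
#' @export
calibrate_prevalences <- function(target_alert_rate = 0.235,
                                  weights = c(early_refill = 229250,
                                              positive_tox = 148968,
                                              rx_3plus_30d = 126568,
                                              onsite_admin_2plus = 34794,
                                              prior_overdose = 25210,
                                              co_prescribed = 148103,
                                              extended_release_naive = 4142),
                                  p_both = 0.028) {
  stopifnot(setequal(names(weights), RISK_FACTORS), all(weights >= 0),
            target_alert_rate > 0, target_alert_rate < 1)
  w <- weights[RISK_FACTORS] / sum(weights)
  alert_rate <- function(lam) {
    p <- lam * w
    q <- p[["early_refill"]] * p_both * (1 - p[["extended_release_naive"]])
    pco <- (p[["co_prescribed"]] - q) / (1 - q)
    1 - prod(1 - p[setdiff(RISK_FACTORS, "co_prescribed")]) * (1 - pco)
  }
  lam <- uniroot(function(l) alert_rate(l) - target_alert_rate,
                 c(1e-9, 0.95 / max(w)), tol = 1e-12)$root
  lam * w
}

#' Simulation configuration
#'
#' Conditions for the synthetic cohort. Defaults emulate the deployment
#' the analytics layer is designed around: encounters spread over
#' 2016-01 to 2019-07, drug mix 75.6% opioid / 21.6% benzodiazepine /
#' 2.8% both, risk-factor prevalences calibrated so the prescription-alert
#' rate is 23.5%, and a flat cancel-given-alert probability of 18.1%.
#'
#' @param n_patients number of patients.
#' @param n_encounters_mean mean prescribing encounters per patient (>= 1;
#'   1 plus a Poisson draw, later encounters past the calendar end are
#'   dropped).
#' @param prescription_probability probability an encounter includes a
#'   controlled prescription (encounters without one emit no events).
#' @param drug_mix named probabilities over `opioid`, `benzodiazepine`,
#'   `both`.
#' @param risk_prevalences named per-trigger marginal probabilities; when
#'   `NULL` they are derived with [calibrate_prevalences()] from
#'   `target_alert_rate`.
#' @param target_alert_rate see [calibrate_prevalences()].
#' @param ninety_day_prevalence probability that an opioid-prescribing
#'   encounter sits at >= 90 days of continuous therapy (planted as a
#'   chain of prior supplies).
#' @param high_mme_prevalence probability that an opioid-prescribing
#'   encounter's index order exceeds 50 daily MME.
#' @param cancel_intercept,cancel_slope log-odds intercept and
#'   per-trigger-count slope of the cancel probability.
#' @param reorder_probability probability that a cancelled initial order is
#'   followed by a completed controlled prescription in the encounter.
#' @param pain_agreement_probability,naloxone_rx_probability follow-up
#'   probabilities after 90-day / naloxone alerts.
#' @param start,end calendar range of encounter times.
#' @param min_gap_days,gap_mean_days per-patient encounter spacing:
#'   `min_gap_days` plus an exponential with mean `gap_mean_days`. The
#'   default 100-day floor isolates encounters from each other's planted
#'   histories (see the methods vignette).
#' @param strata_mix list of named probability vectors for `specialty`,
#'   `facility_type`, `prescriber_type`.
#' @param step_change `NULL`, or `list(month =, cancel_intercept =)`: from
#'   that calendar month on, responses use the new intercept (used to
#'   exercise special-cause detection).
#' @param seed integer RNG seed; the same seed reproduces the stream
#'   byte-for-byte.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 2000,
                              n_encounters_mean = 2.2,
                              prescription_probability = 1,
                              drug_mix = c(opioid = 0.756,
                                           benzodiazepine = 0.216,
                                           both = 0.028),
                              risk_prevalences = NULL,
                              target_alert_rate = 0.235,
                              ninety_day_prevalence = 0.119,
                              high_mme_prevalence = 0.106,
                              cancel_intercept = qlogis(0.181),
                              cancel_slope = 0,
                              reorder_probability = 0.62,
                              pain_agreement_probability = 0.031,
                              naloxone_rx_probability = 0.023,
                              start = "2016-01-01", end = "2019-07-31",
                              min_gap_days = 100, gap_mean_days = 120,
                              strata_mix = default_strata_mix(),
                              step_change = NULL,
                              seed = 1L) {
  check_prob_vec <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 0.01) {
      stop(what, " must be probabilities summing to 1")
    }
    p / sum(p)
  }
  drug_mix <- check_prob_vec(drug_mix[c("opioid", "benzodiazepine", "both")],
                             "drug_mix")
  strata_mix <- lapply(strata_mix, function(p) check_prob_vec(p, "strata_mix"))
  if (is.null(risk_prevalences)) {
    risk_prevalences <- calibrate_prevalences(target_alert_rate,
                                              p_both = drug_mix[["both"]])
  }
  stopifnot(setequal(names(risk_prevalences), RISK_FACTORS))
  risk_prevalences <- risk_prevalences[RISK_FACTORS]
  probs <- c(risk_prevalences, prescription_probability,
             ninety_day_prevalence, high_mme_prevalence,
             reorder_probability, pain_agreement_probability,
             naloxone_rx_probability)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  stopifnot(n_patients >= 1, n_encounters_mean >= 1,
            min_gap_days >= 0, gap_mean_days > 0)
  structure(list(n_patients = as.integer(n_patients),
                 n_encounters_mean = n_encounters_mean,
                 prescription_probability = prescription_probability,
                 drug_mix = drug_mix,
                 risk_prevalences = risk_prevalences,
                 target_alert_rate = target_alert_rate,
                 ninety_day_prevalence = ninety_day_prevalence,
                 high_mme_prevalence = high_mme_prevalence,
                 cancel_intercept = cancel_intercept,
                 cancel_slope = cancel_slope,
                 reorder_probability = reorder_probability,
                 pain_agreement_probability = pain_agreement_probability,
                 naloxone_rx_probability = naloxone_rx_probability,
                 start = start, end = end,
                 min_gap_days = min_gap_days, gap_mean_days = gap_mean_days,
                 strata_mix = strata_mix,
                 step_change = step_change,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_strata_mix <- function() {
  list(specialty = c(primary_care = 0.425, emergency = 0.202, pain = 0.131,
                     surgical_specialty = 0.119, unknown = 0.043,
                     medical_specialty = 0.037, cancer = 0.024,
                     behavioral_health = 0.019, long_term_care = 0.0004),
       facility_type = c(outpatient = 0.684, ed_urgent_care = 0.228,
                         inpatient = 0.077, other = 0.011),
       prescriber_type = c(physician = 0.655, physician_assistant = 0.189,
                           nurse_practitioner = 0.146, other = 0.010))
}

# blank canonical event table of n rows
blank_events <- function(n) {
  df <- data.frame(matrix(NA, n, length(EVENT_COLUMNS)))
  names(df) <- EVENT_COLUMNS
  for (col in EVENT_COLUMNS) {
    df[[col]] <- if (col %in% c("time", "strength_mg", "units_per_day",
                                "days_supply")) NA_real_
    else if (col == "positive") NA else NA_character_
  }
  df
}

rx_rows <- function(patient_id, encounter_id, time, drug_code, strength_mg,
                    units_per_day, days_supply, status = "completed",
                    prescriber_type = NA, specialty = NA, facility_type = NA) {
  n <- length(time)
  df <- blank_events(n)
  df$patient_id <- patient_id
  df$encounter_id <- encounter_id
  df$event_type <- "prescription"
  df$time <- time
  df$drug_code <- drug_code
  df$strength_mg <- strength_mg
  df$units_per_day <- units_per_day
  df$days_supply <- days_supply
  df$status <- status
  df$prescriber_id <- paste0("dr-", substr(patient_id, 2, 6))
  df$prescriber_type <- as.character(prescriber_type)
  df$specialty <- as.character(specialty)
  df$facility_type <- as.character(facility_type)
  df
}

#' Generate a synthetic cohort
#'
#' Builds a reproducible longitudinal event stream (the [ingest_events()]
#' schema) together with ground-truth labels of the factors planted for
#' each encounter. Ground truth is emitted alongside the stream and never
#' leaks into the event schema.
#'
#' @param config a [simulation_config()].
#' @return a `simulated_cohort` list: `events` (event tibble),
#'   `ground_truth` (one row per prescribing encounter: planted factors,
#'   drug mix label, strata), `patients` (patient-level plants), and
#'   `config`.
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  start <- day_number(config$start)
  end <- day_number(config$end)
  stopifnot(end > start)

  n_pat <- config$n_patients
  patient_id <- sprintf("P%06d", seq_len(n_pat))
  k <- 1L + rpois(n_pat, max(0, config$n_encounters_mean - 1))

  pat_ix <- rep(seq_len(n_pat), k)
  first <- floor(runif(n_pat, start, end + 1))
  enc_rank <- sequence(k)
  gap <- floor(config$min_gap_days +
                 rexp(length(pat_ix), 1 / config$gap_mean_days))
  gap[enc_rank == 1] <- 0
  offset <- stats::ave(gap, pat_ix, FUN = cumsum)
  t <- first[pat_ix] + offset
  keep <- t <= end & rbinom(length(t), 1, config$prescription_probability) == 1
  pat_ix <- pat_ix[keep]; t <- t[keep]

  n_enc <- length(t)
  if (n_enc == 0) stop("no encounters generated; increase n_patients or the range")
  encounter_id <- sprintf("E%07d", seq_len(n_enc))
  pid <- patient_id[pat_ix]

  mix <- sample(names(config$drug_mix), n_enc, replace = TRUE,
                prob = config$drug_mix)
  strat <- lapply(config$strata_mix, function(p) {
    sample(names(p), n_enc, replace = TRUE, prob = p)
  })

  # --- plants ---------------------------------------------------------
  p <- config$risk_prevalences
  bern <- function(prob) rbinom(n_enc, 1, prob) == 1
  er <- bern(p[["extended_release_naive"]])
  early <- bern(p[["early_refill"]]) & !er        # an active opioid would break naivety
  onsite <- bern(p[["onsite_admin_2plus"]])
  rx3 <- bern(p[["rx_3plus_30d"]])
  mix[er & mix == "benzodiazepine"] <- "opioid"   # ER plant needs an opioid order
  has_op <- mix %in% c("opioid", "both")
  ninety <- bern(config$ninety_day_prevalence) & has_op & !er
  high_mme <- bern(config$high_mme_prevalence) & has_op
  # co-prescribing: an early-refill plant in a dual-class encounter already
  # induces it; compensate the sampling probability so the marginal is exact
  q <- p[["early_refill"]] * config$drug_mix[["both"]] *
    (1 - p[["extended_release_naive"]])
  p_co_adj <- max(0, (p[["co_prescribed"]] - q) / (1 - q))
  co_sampled <- bern(p_co_adj)
  co <- co_sampled | (early & mix == "both")

  # patient-level (lifetime-lookback) factors
  od_pat <- rbinom(n_pat, 1, p[["prior_overdose"]]) == 1
  tox_pat <- rbinom(n_pat, 1, p[["positive_tox"]]) == 1
  overdose <- od_pat[pat_ix]
  positive_tox <- tox_pat[pat_ix]

  # --- index orders ---------------------------------------------------
  op_ix <- which(has_op)
  op_code <- ifelse(er[op_ix], "MORPHINE-ER-30",
                    ifelse(high_mme[op_ix], "OXYCODONE-10", "HYDROCODONE-5"))
  op_strength <- ifelse(er[op_ix], 30, ifelse(high_mme[op_ix], 10, 5))
  op_units <- ifelse(er[op_ix], ifelse(high_mme[op_ix], 2, 1),
                     ifelse(high_mme[op_ix], 4, 3))
  op_supply <- sample(c(3, 5, 7, 10, 14), length(op_ix), replace = TRUE,
                      prob = c(0.15, 0.2, 0.25, 0.2, 0.2))
  bz_ix <- which(mix %in% c("benzodiazepine", "both"))
  bz_supply <- sample(c(10, 14, 30), length(bz_ix), replace = TRUE,
                      prob = c(0.35, 0.35, 0.3))

  ev <- list(
    rx_rows(pid[op_ix], encounter_id[op_ix], t[op_ix], op_code,
            op_strength, op_units, op_supply,
            prescriber_type = strat$prescriber_type[op_ix],
            specialty = strat$specialty[op_ix],
            facility_type = strat$facility_type[op_ix]),
    rx_rows(pid[bz_ix], encounter_id[bz_ix], t[bz_ix], "LORAZEPAM-1",
            1, 2, bz_supply,
            prescriber_type = strat$prescriber_type[bz_ix],
            specialty = strat$specialty[bz_ix],
            facility_type = strat$facility_type[bz_ix]))

  # --- planted histories ---------------------------------------------
  hist_enc <- function(ix, tag) paste0(encounter_id[ix], "-h", tag)
  e_ix <- which(early)
  if (length(e_ix)) {
    e_op <- has_op[e_ix]
    ev <- c(ev, list(rx_rows(pid[e_ix], hist_enc(e_ix, "er"), t[e_ix] - 2,
                             ifelse(e_op, "HYDROCODONE-5", "LORAZEPAM-1"),
                             ifelse(e_op, 5, 1), 1, 10)))
  }
  r_ix <- which(rx3)
  if (length(r_ix)) {
    r_bz <- !has_op[r_ix] | er[r_ix]   # benzo orders keep ER plants naive
    code <- ifelse(r_bz, "LORAZEPAM-1", "HYDROCODONE-5")
    strength <- ifelse(r_bz, 1, 5)
    for (off in c(25, 20, 15)) {
      ev <- c(ev, list(rx_rows(pid[r_ix], hist_enc(r_ix, paste0("rx", off)),
                               t[r_ix] - off, code, strength, 1, 5)))
    }
  }
  c_ix <- which(co_sampled)
  if (length(c_ix)) {
    c_op <- !has_op[c_ix]              # plant the class opposite to the index
    ev <- c(ev, list(rx_rows(pid[c_ix], hist_enc(c_ix, "co"), t[c_ix] - 20,
                             ifelse(c_op, "HYDROCODONE-5", "LORAZEPAM-1"),
                             ifelse(c_op, 5, 1), 1, 30)))
  }
  n_ix <- which(ninety)
  if (length(n_ix)) {
    for (off in c(95, 65, 35)) {
      ev <- c(ev, list(rx_rows(pid[n_ix], hist_enc(n_ix, paste0("ct", off)),
                               t[n_ix] - off, "HYDROCODONE-5", 5, 1, 30)))
    }
  }
  o_ix <- which(onsite)
  if (length(o_ix)) {
    adm_class <- ifelse(er[o_ix], "benzodiazepine", "opioid")
    for (off in c(5, 15)) {
      df <- blank_events(length(o_ix))
      df$patient_id <- pid[o_ix]
      df$encounter_id <- hist_enc(o_ix, paste0("ad", off))
      df$event_type <- "administration"
      df$time <- t[o_ix] - off
      df$visit_id <- paste0(encounter_id[o_ix], "-v", off)
      df$visit_type <- "ed"
      df$drug_class <- adm_class
      ev <- c(ev, list(df))
    }
  }
  first_t <- tapply(t, pat_ix, min)
  od_pids <- which(od_pat & seq_len(n_pat) %in% pat_ix)
  if (length(od_pids)) {
    df <- blank_events(length(od_pids))
    df$patient_id <- patient_id[od_pids]
    df$event_type <- "overdose"
    df$time <- first_t[as.character(od_pids)] - 180
    df$substance_class <- "opioid"
    ev <- c(ev, list(df))
  }
  tx_pids <- which(tox_pat & seq_len(n_pat) %in% pat_ix)
  if (length(tx_pids)) {
    df <- blank_events(length(tx_pids))
    df$patient_id <- patient_id[tx_pids]
    df$event_type <- "tox_screen"
    df$time <- first_t[as.character(tx_pids)] - 120
    df$analyte <- "cocaine"
    df$positive <- TRUE
    ev <- c(ev, list(df))
  }

  events <- dplyr::bind_rows(ev)
  events <- events[order(events$patient_id, events$time), ]
  events$order_id <- ifelse(events$event_type == "prescription",
                            sprintf("O%07d", seq_len(nrow(events))),
                            NA_character_)
  events <- validate_events(events)

  ground_truth <- tibble::tibble(
    encounter_id = encounter_id, patient_id = pid, time = t,
    drug_mix = mix,
    planted_early_refill = early,
    planted_onsite_admin_2plus = onsite,
    planted_rx_3plus_30d = rx3,
    planted_prior_overdose = overdose,
    planted_positive_tox = positive_tox,
    planted_co_prescribed = co,
    planted_extended_release_naive = er,
    planted_ninety_day = ninety,
    planted_high_mme = high_mme,
    specialty = strat$specialty,
    facility_type = strat$facility_type,
    prescriber_type = strat$prescriber_type)

  structure(list(events = tibble::as_tibble(events),
                 ground_truth = ground_truth,
                 patients = tibble::tibble(
                   patient_id = patient_id,
                   n_encounters = as.integer(tabulate(pat_ix, n_pat)),
                   planted_prior_overdose = od_pat,
                   planted_positive_tox = tox_pat),
                 config = config),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("<simulated_cohort> ", nrow(x$ground_truth), " prescribing encounters, ",
      nrow(x$patients), " patients, ", nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' Sample prescriber responses to fired alerts
#'
#' For every decision whose prescription alert fired, draws cancel with
#' probability `plogis(cancel_intercept + cancel_slope * trigger_count)`
#' (the step-change intercept applies from its configured month on), and
#' for cancels draws whether a replacement controlled prescription
#' completed (`reordered`, probability `reorder_probability`).
#'
#' @param cohort a `simulated_cohort` (supplies the behavioral config when
#'   `config` is missing).
#' @param decisions decisions from [screen_cohort()] run on the cohort.
#' @param config a [simulation_config()]; defaults to the cohort's.
#' @param seed RNG seed; defaults to the config seed + 1.
#' @return tibble with `order_id`, `encounter_id`, `time`, `trigger_count`,
#'   `p_cancel` (the latent propensity), `response`, `reordered`,
#'   `response_time`.
#' @export
sample_responses <- function(cohort, decisions, config = NULL, seed = NULL) {
  config <- config %||% cohort$config
  set.seed(seed %||% (config$seed + 1L))
  d <- decisions[decisions$prescription_alert, , drop = FALSE]
  icpt <- rep(config$cancel_intercept, nrow(d))
  if (!is.null(config$step_change)) {
    after <- d$time >= day_number(config$step_change$month)
    icpt[after] <- config$step_change$cancel_intercept
  }
  p_cancel <- plogis(icpt + config$cancel_slope * d$trigger_count)
  cancel <- rbinom(nrow(d), 1, p_cancel) == 1
  reordered <- cancel & rbinom(nrow(d), 1, config$reorder_probability) == 1
  tibble::tibble(order_id = d$order_id,
                 encounter_id = d$encounter_id,
                 time = d$time,
                 trigger_count = d$trigger_count,
                 p_cancel = p_cancel,
                 response = ifelse(cancel, "cancel", "continue"),
                 reordered = reordered,
                 response_time = d$time)
}

#' Sample follow-up events after 90-day and naloxone alerts
#'
#' Draws, per fired 90-day alert, a pain-agreement initiation (probability
#' `pain_agreement_probability`) and, per fired naloxone alert, a completed
#' naloxone prescription (probability `naloxone_rx_probability`), each at a
#' uniform offset inside the follow-up horizon. Returns event rows to
#' append to the cohort's stream.
#'
#' @inheritParams sample_responses
#' @param horizon_days follow-up window, default 30.
#' @return an event tibble (possibly empty).
#' @export
sample_follow_ups <- function(cohort, decisions, config = NULL, seed = NULL,
                              horizon_days = 30) {
  config <- config %||% cohort$config
  set.seed(seed %||% (config$seed + 2L))
  ev <- list()
  nd <- decisions[decisions$ninety_day_alert, , drop = FALSE]
  if (nrow(nd)) {
    hit <- rbinom(nrow(nd), 1, config$pain_agreement_probability) == 1
    if (any(hit)) {
      df <- blank_events(sum(hit))
      df$patient_id <- nd$patient_id[hit]
      df$encounter_id <- paste0(nd$encounter_id[hit], "-fu")
      df$event_type <- "pain_agreement"
      df$time <- nd$time[hit] + sample(0:(horizon_days - 1), sum(hit), TRUE)
      ev <- c(ev, list(df))
    }
  }
  nx <- decisions[decisions$naloxone_alert, , drop = FALSE]
  if (nrow(nx)) {
    hit <- rbinom(nrow(nx), 1, config$naloxone_rx_probability) == 1
    if (any(hit)) {
      ev <- c(ev, list(rx_rows(nx$patient_id[hit],
                               paste0(nx$encounter_id[hit], "-fu"),
                               nx$time[hit] + sample(0:(horizon_days - 1),
                                                     sum(hit), TRUE),
                               "NALOXONE-NASAL-4", 4, 1, 1)))
    }
  }
  if (!length(ev)) return(tibble::as_tibble(blank_events(0)))
  out <- dplyr::bind_rows(ev)
  out$order_id <- ifelse(out$event_type == "prescription",
                         sprintf("F%07d", seq_len(nrow(out))), NA_character_)
  tibble::as_tibble(validate_events(out))
}

#' Write a simulated cohort to disk
#'
#' Writes `events.csv` (the [ingest_events()] schema, ISO timestamps) and
#' `ground_truth.csv` to a directory.
#'
#' @param cohort a `simulated_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_events(cohort$events, file.path(dir, "events.csv"))
  gt <- cohort$ground_truth
  gt$time <- format_event_time(gt$time)
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}
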