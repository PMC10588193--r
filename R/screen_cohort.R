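# Cohort-level screening. Logic is identical to screen_order() (a property
# test asserts equality on random cohorts); this path works on per-patient
# column vectors so that hundreds of thousands of orders screen in seconds.

#' Screen every controlled order in an event stream
#'
#' Applies [screen_order()]'s logic to every completed or cancelled
#' opioid/benzodiazepine prescription order in the stream, each screened
#' against the patient's history restricted to events strictly before the
#' order time (alerts fire at medication selection, before the order
#' exists). Orders of other classes are passed through unscreened (no
#' decision row).
#'
#' @param events an event tibble (see [ingest_events()]) or a file path.
#' @param catalog a [drug_catalog()].
#' @param config a [screen_config()].
#' @return a tibble with one row per screened order: identifiers, order
#'   time, drug class, strata columns, the seven trigger flags,
#'   `trigger_count`, `prescription_alert`, `ninety_day_alert`,
#'   `naloxone_alert` and `daily_mme`.
#' @export
screen_cohort <- function(events, catalog, config = screen_config()) {
  if (is.character(events) && length(events) == 1) events <- read_events(events)
  events <- validate_events(events)
  events <- events[order(events$patient_id, events$time), ]

  rx <- events$event_type == "prescription"
  events$drug_class[rx] <- classify_drug(catalog, events$drug_code[rx])
  er_flag <- rep(FALSE, nrow(events))
  er_flag[rx] <- catalog$extended_release[match(events$drug_code[rx],
                                                catalog$drug_code)] %in% TRUE
  dmme <- rep(0, nrow(events))
  dmme[rx] <- daily_mme(catalog, events[rx, ])$daily_mme

  # plain vectors: the per-patient loop must not touch the tibble
  v_type <- events$event_type
  v_time <- events$time
  v_class <- events$drug_class
  v_supply <- events$days_supply
  v_completed <- !is.na(events$status) & events$status == "completed"
  v_visit <- events$visit_id
  v_visit_ok <- events$visit_type %in% c("ed", "urgent_care")
  v_tox_ok <- events$positive %in% TRUE &
    events$analyte %in% config$tox_analytes

  idx_by_patient <- split(seq_len(nrow(events)), events$patient_id)
  controlled <- c("opioid", "benzodiazepine")
  n_pat <- length(idx_by_patient)
  acc_idx <- vector("list", n_pat)
  acc_flags <- vector("list", n_pat)
  acc_ninety <- vector("list", n_pat)
  acc_nalox <- vector("list", n_pat)

  for (k in seq_len(n_pat)) {
    ii <- idx_by_patient[[k]]
    typ <- v_type[ii]

    is_rx <- typ == "prescription"
    rx_t <- v_time[ii][is_rx]
    rx_class <- v_class[ii][is_rx]
    rx_supply <- v_supply[ii][is_rx]
    rx_comp <- v_completed[ii][is_rx]
    rx_er <- er_flag[ii][is_rx]
    rx_mme <- dmme[ii][is_rx]
    rx_end <- rx_t + rx_supply
    rx_ctrl <- rx_class %in% controlled
    rx_op <- rx_class == "opioid"
    rx_bz <- rx_class == "benzodiazepine"
    rx_nx <- rx_class == "naloxone"

    is_ad <- typ == "administration"
    ad_t <- v_time[ii][is_ad]
    ad_ok <- v_visit_ok[ii][is_ad] & v_class[ii][is_ad] %in% config$onsite_classes
    ad_visit <- v_visit[ii][is_ad]
    ad_op <- v_class[ii][is_ad] == "opioid"

    is_tx <- typ == "tox_screen"
    tx_t <- v_time[ii][is_tx]
    tx_ok <- v_tox_ok[ii][is_tx]

    od_t <- v_time[ii][typ == "overdose"]

    rx_pos <- which(is_rx)       # positions within this patient's events
    screen_idx <- which(rx_ctrl) # positions within the rx vectors
    if (!length(screen_idx)) next
    n_s <- length(screen_idx)
    flags <- matrix(FALSE, n_s, 7, dimnames = list(NULL, TRIGGER_NAMES))
    ninety <- logical(n_s)
    nalox <- logical(n_s)

    for (j in seq_len(n_s)) {
      s <- screen_idx[j]
      t <- rx_t[s]
      is_op <- rx_op[s]
      prior <- rx_comp & rx_t < t          # completed, strictly prior
      act <- prior & rx_end > t            # still active at t

      same <- if (config$early_refill_same_class) {
        if (is_op) rx_op else rx_bz
      } else rx_ctrl
      fr <- 1 - (t - rx_t) / rx_supply
      flags[j, 1L] <- any(act & same & fr > config$refill_threshold)

      if (length(ad_t)) {
        in_w <- ad_ok & ad_t > t - config$admin_window_days & ad_t < t
        flags[j, 2L] <- length(unique(ad_visit[in_w])) >= config$min_admin_visits
      }

      flags[j, 3L] <- sum(prior & rx_ctrl & rx_t > t - config$rx_window_days) >=
        config$min_rx_count

      flags[j, 4L] <- any(od_t < t)

      if (length(tx_t)) {
        lb <- config$tox_lookback_days
        flags[j, 5L] <- any(tx_ok & tx_t < t & (is.infinite(lb) | tx_t > t - lb))
      }

      co <- any(act & (if (is_op) rx_bz else rx_op))
      flags[j, 6L] <- co

      if (is_op && rx_er[s]) {
        lbn <- config$naive_lookback_days
        exposed <- any(prior & rx_op & rx_end > t - lbn) ||
          (length(ad_t) && any(ad_op & ad_t > t - lbn & ad_t < t))
        flags[j, 7L] <- !exposed
      }

      if (is_op) {
        cov <- prior & rx_op
        if (any(cov)) {
          run <- merge_coverage_run(rx_t[cov], rx_end[cov], t,
                                    config$gap_tolerance_days)
          ninety[j] <- !is.null(run) &&
            (t - run[["start"]]) >= config$ninety_day_threshold
        }
      }

      conc <- if (config$naloxone_combined_mme) sum(rx_mme[act & rx_op]) else 0
      at_risk <- co || flags[j, 4L] || (rx_mme[s] + conc) > config$mme_threshold
      if (at_risk && config$naloxone_suppression && any(act & rx_nx)) {
        at_risk <- FALSE
      }
      nalox[j] <- at_risk
    }

    acc_idx[[k]] <- ii[rx_pos[screen_idx]]
    acc_flags[[k]] <- flags
    acc_ninety[[k]] <- ninety
    acc_nalox[[k]] <- nalox
  }

  sl <- unlist(acc_idx)
  if (is.null(sl) || !length(sl)) return(tibble::tibble())
  flags <- do.call(rbind, acc_flags)
  decisions <- tibble::tibble(
    order_id = events$order_id[sl],
    patient_id = events$patient_id[sl],
    encounter_id = events$encounter_id[sl],
    time = events$time[sl],
    drug_class = events$drug_class[sl],
    days_supply = events$days_supply[sl],
    daily_mme = dmme[sl],
    prescriber_type = events$prescriber_type[sl],
    specialty = events$specialty[sl],
    facility_type = events$facility_type[sl],
    tibble::as_tibble(flags),
    trigger_count = rowSums(flags),
    prescription_alert = rowSums(flags) >= 1,
    ninety_day_alert = unlist(acc_ninety),
    naloxone_alert = unlist(acc_nalox))
  decisions[order(decisions$time, decisions$order_id), ]
}
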