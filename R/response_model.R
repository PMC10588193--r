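# Prescriber responses to alerts and the encounter outcome taxonomy.
#
# The encounter is the unit of analysis. "Decision influenced" means the
# prescriber clicked cancel at least once during the encounter; influenced
# encounters partition into "cancelled" (a controlled prescription was
# still completed during the encounter) and "none_ordered" (none was).
# These two are mutually exclusive and exhaustive subsets of influenced.

#' Classify one encounter from its alert responses
#'
#' @param responses a data frame of the encounter's alert responses with a
#'   `response` column (`"continue"` / `"cancel"`), possibly empty (no
#'   alert fired).
#' @param completed_orders a data frame of the encounter's completed
#'   opioid/benzodiazepine orders (only a `drug_class` column is needed);
#'   orders of other classes are ignored.
#' @return one-row tibble with `had_alert`, `outcome` (one of `continued`,
#'   `cancelled`, `none_ordered`, `no_alert`) and `decision_influenced`.
#'   `decision_influenced` is TRUE iff the outcome is `cancelled` or
#'   `none_ordered`.
#' @examples
#' classify_encounter(data.frame(response = c("continue", "cancel")),
#'                    data.frame(drug_class = "opioid"))
#' @export
classify_encounter <- function(responses, completed_orders) {
  responses <- as.data.frame(responses)
  if (nrow(responses) && !all(responses$response %in% c("continue", "cancel"))) {
    stop("responses must be 'continue' or 'cancel'")
  }
  completed_orders <- as.data.frame(completed_orders)
  has_ctrl <- nrow(completed_orders) > 0 &&
    any(completed_orders$drug_class %in% c("opioid", "benzodiazepine"))
  had_alert <- nrow(responses) > 0
  outcome <- if (!had_alert) {
    "no_alert"
  } else if (!any(responses$response == "cancel")) {
    "continued"
  } else if (has_ctrl) {
    "cancelled"
  } else {
    "none_ordered"
  }
  tibble::tibble(had_alert = had_alert,
                 outcome = factor(outcome, levels = OUTCOME_LEVELS),
                 decision_influenced = outcome %in% c("cancelled", "none_ordered"))
}

#' Classify every encounter of a screened cohort
#'
#' Collapses order-level alert decisions and prescriber responses into one
#' outcome per encounter. A completed controlled order exists in an
#' encounter when a non-alerted controlled order completed, an alerted
#' order received "continue", or a cancelled order was replaced
#' (`reordered`).
#'
#' @param decisions order-level decisions from [screen_cohort()].
#' @param responses a data frame with `order_id`, `response`
#'   (`"continue"`/`"cancel"`) and optionally `reordered` (logical; did a
#'   replacement controlled prescription complete after a cancel). Every
#'   `order_id` must reference a decision whose prescription alert fired.
#' @return a tibble with one row per encounter: `encounter_id`,
#'   `patient_id`, `time` (first order), `month`, `had_alert`, `outcome`,
#'   `decision_influenced`, encounter drug class (`opioid`,
#'   `benzodiazepine` or `both`), `trigger_count` (maximum over alerted
#'   orders), per-trigger any-flags, `ninety_day_alert`, `naloxone_alert`
#'   and the prescriber/specialty/facility strata of the first order.
#' @export
classify_encounters <- function(decisions, responses) {
  stopifnot(nrow(decisions) > 0)
  responses <- tibble::as_tibble(responses)
  if (!"reordered" %in% names(responses)) responses$reordered <- FALSE
  responses$reordered[is.na(responses$reordered)] <- FALSE

  alerted_ids <- decisions$order_id[decisions$prescription_alert]
  stray <- setdiff(responses$order_id, alerted_ids)
  if (length(stray)) {
    stop("responses without a fired prescription alert: ",
         paste(utils::head(stray, 5), collapse = ", "))
  }
  missing_resp <- setdiff(alerted_ids, responses$order_id)
  if (length(missing_resp)) {
    stop("fired prescription alerts without a response: ",
         paste(utils::head(missing_resp, 5), collapse = ", "))
  }

  d <- dplyr::left_join(decisions,
                        responses[, c("order_id", "response", "reordered")],
                        by = "order_id")
  d$response[!d$prescription_alert] <- NA_character_

  # an order leaves a completed controlled prescription behind when it was
  # never alerted (completes as written), was continued, or was reordered
  d$leaves_completed <- !d$prescription_alert |
    (d$response %in% "continue") | (d$reordered %in% TRUE)

  out <- dplyr::summarise(
    dplyr::group_by(d, .data$encounter_id),
    patient_id = .data$patient_id[1],
    time = min(.data$time),
    had_alert = any(.data$prescription_alert),
    any_cancel = any(.data$response %in% "cancel"),
    has_completed = any(.data$leaves_completed),
    drug_class = if (dplyr::n_distinct(.data$drug_class) > 1) "both"
                 else .data$drug_class[1],
    trigger_count = max(.data$trigger_count),
    early_refill = any(.data$early_refill),
    onsite_admin_2plus = any(.data$onsite_admin_2plus),
    rx_3plus_30d = any(.data$rx_3plus_30d),
    prior_overdose = any(.data$prior_overdose),
    positive_tox = any(.data$positive_tox),
    co_prescribed = any(.data$co_prescribed),
    extended_release_naive = any(.data$extended_release_naive),
    ninety_day_alert = any(.data$ninety_day_alert),
    naloxone_alert = any(.data$naloxone_alert),
    prescriber_type = .data$prescriber_type[1],
    specialty = .data$specialty[1],
    facility_type = .data$facility_type[1],
    .groups = "drop")

  out$outcome <- factor(
    ifelse(!out$had_alert, "no_alert",
           ifelse(!out$any_cancel, "continued",
                  ifelse(out$has_completed, "cancelled", "none_ordered"))),
    levels = OUTCOME_LEVELS)
  out$decision_influenced <- out$outcome %in% c("cancelled", "none_ordered")
  out$month <- month_floor(out$time)
  out$any_cancel <- NULL
  out$has_completed <- NULL
  out
}

#' Follow-up response to a 90-day or naloxone alert
#'
#' For a 90-day alert: did a pain agreement get initiated within the
#' horizon? For a naloxone alert: did a completed naloxone prescription
#' occur within it? The window is `[alert_time, alert_time + horizon)`;
#' events before the alert never count.
#'
#' @param history a `patient_history`.
#' @param alert_kind `"ninety_day"` or `"naloxone"`.
#' @param alert_time time the alert fired.
#' @param horizon_days positive window length, default 30 days.
#' @return logical scalar.
#' @export
follow_up_response <- function(history, alert_kind = c("ninety_day", "naloxone"),
                               alert_time, horizon_days = 30) {
  alert_kind <- match.arg(alert_kind)
  stopifnot(horizon_days >= 1)
  t <- day_number(alert_time)
  if (alert_kind == "ninety_day") {
    pa <- history$pain_agreements
    any(pa$time >= t & pa$time < t + horizon_days)
  } else {
    p <- history$prescriptions
    any(p$status == "completed" & p$drug_class == "naloxone" &
          p$time >= t & p$time < t + horizon_days)
  }
}
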