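# Typed longitudinal EHR event store and windowed temporal queries.
#
# Internal time scale: numeric days since 1970-01-01 (timezone-naive,
# fractional days allowed). Files carry ISO-8601 strings. All temporal
# windows are half-open [t - w, t): an event at the instant of the screened
# order does not count toward its own triggers.

# coerce an event table to the canonical column set / types, with row-level
# diagnostics for malformed input
validate_events <- function(events) {
  events <- tibble::as_tibble(events)
  for (col in c("patient_id", "event_type", "time")) {
    if (!col %in% names(events)) stop("event stream is missing column '", col, "'")
  }
  bad_type <- !events$event_type %in% EVENT_TYPES
  if (any(bad_type)) {
    stop("unknown event_type in rows ",
         paste(utils::head(which(bad_type), 5), collapse = ", "),
         ": ", paste(unique(events$event_type[bad_type]), collapse = ", "))
  }
  t <- parse_event_time(events$time)
  if (anyNA(t)) {
    stop("unparseable timestamps in rows ",
         paste(utils::head(which(is.na(t)), 5), collapse = ", "))
  }
  events$time <- t
  for (col in setdiff(EVENT_COLUMNS, names(events))) {
    events[[col]] <- if (col %in% c("strength_mg", "units_per_day", "days_supply")) {
      NA_real_
    } else if (col == "positive") NA else NA_character_
  }
  rx <- events$event_type == "prescription"
  if (any(rx)) {
    ds <- events$days_supply[rx]
    if (anyNA(ds) || any(ds < 1)) {
      stop("prescription rows must have days_supply >= 1 (rows ",
           paste(utils::head(which(rx)[is.na(ds) | ds < 1], 5), collapse = ", "), ")")
    }
    st <- events$status[rx]
    if (any(!st %in% c("completed", "cancelled"))) {
      stop("prescription status must be 'completed' or 'cancelled'")
    }
    if (anyNA(events$order_id[rx])) {
      events$order_id[rx][is.na(events$order_id[rx])] <-
        sprintf("ord%06d", which(rx)[is.na(events$order_id[rx])])
    }
  }
  if (is.character(events$positive)) {
    events$positive <- tolower(events$positive) %in% c("true", "t", "1", "yes")
  }
  events[, EVENT_COLUMNS]
}

#' Read / write an event stream
#'
#' Event files are CSV or JSON-lines, one event per row, with common
#' columns `patient_id`, `encounter_id`, `event_type`, `time` (ISO-8601)
#' plus type-specific columns (see [ingest_events()]). Format is inferred
#' from the extension (`.jsonl`/`.json` vs anything else = CSV) unless
#' given.
#'
#' @param path file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `read_events()`: a validated event tibble with numeric-day
#'   times; `write_events()`: the path, invisibly.
#' @export
read_events <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  df <- if (format == "jsonl") {
    jsonlite::stream_in(file(path), verbose = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  }
  validate_events(df)
}

#' @rdname read_events
#' @param events a validated event tibble.
#' @export
write_events <- function(events, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  out <- as.data.frame(events)
  out$time <- format_event_time(out$time)
  if (format == "jsonl") {
    jsonlite::stream_out(out, file(path), verbose = FALSE)
  } else {
    utils::write.csv(out, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

new_patient_history <- function(patient_id, prescriptions, administrations,
                                tox_screens, overdoses, pain_agreements) {
  structure(list(patient_id = patient_id,
                 prescriptions = prescriptions,
                 administrations = administrations,
                 tox_screens = tox_screens,
                 overdoses = overdoses,
                 pain_agreements = pain_agreements),
            class = "patient_history")
}

#' Build per-patient histories from an event stream
#'
#' Splits a longitudinal event table into one `patient_history` per
#' patient, with each event type sorted ascending by time. Queries on a
#' history never mutate it, and query results are independent of the
#' original insertion order.
#'
#' @param events an event tibble (as from [read_events()] or
#'   [generate_cohort()]), or a file path.
#' @param catalog optional [drug_catalog()]; when given, prescription
#'   `drug_class` and `extended_release` are (re)derived from the catalog.
#' @return a named list of `patient_history` objects, class `history_set`.
#' @examples
#' ev <- tibble::tibble(patient_id = c("p1", "p1", "p2"),
#'                      encounter_id = c("e1", "e2", "e3"),
#'                      event_type = c("prescription", "overdose", "prescription"),
#'                      time = c("2016-01-10", "2016-03-01", "2016-02-01"),
#'                      drug_code = c("HYDROCODONE-5", NA, "DIAZEPAM-5"),
#'                      days_supply = c(5, NA, 10),
#'                      status = c("completed", NA, "completed"),
#'                      strength_mg = c(5, NA, 5), units_per_day = c(3, NA, 2))
#' h <- ingest_events(ev, default_drug_catalog())
#' length(h)
#' @export
ingest_events <- function(events, catalog = NULL) {
  if (is.character(events) && length(events) == 1) events <- read_events(events)
  events <- validate_events(events)
  events <- events[order(events$time), ]
  if (!is.null(catalog)) {
    rx <- events$event_type == "prescription"
    events$drug_class[rx] <- classify_drug(catalog, events$drug_code[rx])
    er <- catalog$extended_release[match(events$drug_code[rx], catalog$drug_code)]
    er[is.na(er)] <- FALSE
    events$extended_release <- NA
    events$extended_release[rx] <- er
  } else if (!"extended_release" %in% names(events)) {
    events$extended_release <- NA
  }
  split_type <- function(df, type) {
    as.data.frame(df[df$event_type == type, , drop = FALSE])
  }
  out <- lapply(split(events, events$patient_id), function(df) {
    new_patient_history(df$patient_id[[1]],
                        prescriptions = split_type(df, "prescription"),
                        administrations = split_type(df, "administration"),
                        tox_screens = split_type(df, "tox_screen"),
                        overdoses = split_type(df, "overdose"),
                        pain_agreements = split_type(df, "pain_agreement"))
  })
  structure(out, class = "history_set")
}

#' @export
print.patient_history <- function(x, ...) {
  cat("<patient_history ", x$patient_id, "> ",
      nrow(x$prescriptions), " rx, ",
      nrow(x$administrations), " admin, ",
      nrow(x$tox_screens), " tox, ",
      nrow(x$overdoses), " overdose, ",
      nrow(x$pain_agreements), " agreement\n", sep = "")
  invisible(x)
}

#' Events of one kind in a trailing window
#'
#' Returns all events of the requested kind strictly inside the trailing
#' window: events whose age at `t` is positive and strictly less than
#' `window_days`. An event exactly `window_days` before `t` is excluded,
#' and so is an event at exactly `t` (it cannot count toward triggers
#' evaluated at `t`).
#'
#' @param history a `patient_history`.
#' @param kind one of `"prescription"`, `"administration"`, `"tox_screen"`,
#'   `"overdose"`, `"pain_agreement"`.
#' @param t query time (numeric day, `Date`, or ISO string).
#' @param window_days positive window length in days.
#' @return the matching event rows (data frame).
#' @export
events_in_window <- function(history, kind = EVENT_TYPES, t, window_days) {
  kind <- match.arg(kind)
  stopifnot(window_days >= 1)
  t <- day_number(t)
  slot <- switch(kind, prescription = "prescriptions",
                 administration = "administrations",
                 tox_screen = "tox_screens", overdose = "overdoses",
                 pain_agreement = "pain_agreements")
  df <- history[[slot]]
  df[df$time > t - window_days & df$time < t, , drop = FALSE]
}

#' Prescriptions active at a time point
#'
#' A completed order is active at `t` when
#' `order_time <= t < order_time + days_supply` (half-open end: a 10-day
#' supply started 10 days ago is no longer active). Cancelled orders are
#' never active.
#'
#' @inheritParams events_in_window
#' @param class_filter optional character vector of drug classes to keep.
#' @return the active prescription rows (data frame).
#' @export
active_prescriptions <- function(history, t, class_filter = NULL) {
  t <- day_number(t)
  p <- history$prescriptions
  keep <- p$status == "completed" & p$time <= t & t < p$time + p$days_supply
  if (!is.null(class_filter)) keep <- keep & p$drug_class %in% class_filter
  p[keep, , drop = FALSE]
}

# interval-merge core shared by continuous_opioid_days() and the cohort
# screener: merges coverage intervals whose gaps are <= tol and returns the
# run qualifying at t (start <= t, end >= t - tol), or NULL
merge_coverage_run <- function(start, end, t, tol) {
  if (!length(start)) return(NULL)
  o <- order(start)
  s <- start[o]; e <- end[o]
  ce <- cummax(e)
  brk <- which(s[-1] - ce[-length(s)] > tol)  # indices where a new run starts - 1
  run_first <- c(1, brk + 1)
  run_last <- c(brk, length(s))
  rs <- s[run_first]
  re <- ce[run_last]
  qual <- rs <= t & re >= t - tol
  if (!any(qual)) return(NULL)
  i <- max(which(qual))  # runs are disjoint and ordered: last = largest end
  c(start = rs[i], end = re[i])
}

#' Days of continuous opioid therapy ending at a time point
#'
#' Length in days of the maximal run of opioid coverage reaching `t`.
#' Coverage intervals from completed opioid prescriptions
#' (`[order_time, order_time + days_supply)`) separated by at most
#' `gap_tolerance_days` are merged; the run qualifies when it starts at or
#' before `t` and its coverage ends no more than `gap_tolerance_days`
#' before `t`. The returned length is `t - run_start` (bridged gaps count
#' as therapy days); 0 when no coverage reaches `t`.
#'
#' @inheritParams events_in_window
#' @param gap_tolerance_days nonnegative integer; gaps up to this many days
#'   do not interrupt "continuous" therapy. Default 7.
#' @return nonnegative number of days.
#' @export
continuous_opioid_days <- function(history, t, gap_tolerance_days = 7) {
  stopifnot(gap_tolerance_days >= 0)
  t <- day_number(t)
  p <- history$prescriptions
  keep <- p$status == "completed" & p$drug_class == "opioid" & p$time <= t
  if (!any(keep)) return(0)
  run <- merge_coverage_run(p$time[keep], p$time[keep] + p$days_supply[keep],
                            t, gap_tolerance_days)
  if (is.null(run)) return(0)
  unname(t - run["start"])
}

#' Is the patient opioid-naive at a time point?
#'
#' TRUE iff no completed opioid prescription's coverage overlaps the
#' trailing lookback window before `t` and no opioid administration occurs
#' in it. The lookback is configuration: "naive" has no universal clinical
#' definition.
#'
#' @inheritParams events_in_window
#' @param lookback_days positive lookback window, default 45 days.
#' @return logical scalar.
#' @export
is_opioid_naive <- function(history, t, lookback_days = 45) {
  stopifnot(lookback_days >= 1)
  t <- day_number(t)
  p <- history$prescriptions
  rx_exposed <- any(p$status == "completed" & p$drug_class == "opioid" &
                      p$time < t & p$time + p$days_supply > t - lookback_days)
  a <- history$administrations
  adm_exposed <- any(a$drug_class == "opioid" &
                       a$time > t - lookback_days & a$time < t)
  !(rx_exposed || adm_exposed)
}
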