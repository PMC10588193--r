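#' Drug catalog
#'
#' A drug catalog maps opaque drug codes to a regulatory class, a morphine
#' milligram equivalent (MME) conversion factor (opioids only) and an
#' extended-release flag. The catalog is configuration, not fact: MME
#' conversion tables differ between reference versions, so the engine never
#' hard-codes factors. [default_drug_catalog()] ships standard published
#' factors (morphine 1, hydrocodone 1, oxycodone 1.5, hydromorphone 4,
#' codeine 0.15, tramadol 0.1, ...) and is fully user-replaceable.
#'
#' @param entries a data frame with columns `drug_code`, `name`,
#'   `drug_class` (one of `"opioid"`, `"benzodiazepine"`, `"naloxone"`,
#'   `"other"`), `mme_factor` (nonnegative; required for opioids, `NA`
#'   otherwise) and `extended_release` (logical; only meaningful for
#'   opioids).
#' @return a `drug_catalog` tibble.
#' @examples
#' cat <- default_drug_catalog()
#' classify_drug(cat, c("MORPHINE-IR-15", "DIAZEPAM-5", "ATORVASTATIN-20"))
#' @export
drug_catalog <- function(entries) {
  entries <- tibble::as_tibble(entries)
  req <- c("drug_code", "name", "drug_class", "mme_factor", "extended_release")
  missing_cols <- setdiff(req, names(entries))
  if (length(missing_cols)) {
    stop("drug catalog is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  classes <- c("opioid", "benzodiazepine", "naloxone", "other")
  bad <- !entries$drug_class %in% classes
  if (any(bad)) {
    stop("unknown drug_class values: ",
         paste(unique(entries$drug_class[bad]), collapse = ", "))
  }
  if (anyDuplicated(entries$drug_code)) stop("duplicate drug_code entries")
  entries$mme_factor <- as.numeric(entries$mme_factor)
  entries$extended_release <- as.logical(entries$extended_release)
  op <- entries$drug_class == "opioid"
  if (any(op & is.na(entries$mme_factor))) {
    stop("opioid entries without mme_factor: ",
         paste(entries$drug_code[op & is.na(entries$mme_factor)], collapse = ", "))
  }
  if (any(!is.na(entries$mme_factor) & entries$mme_factor < 0)) {
    stop("mme_factor must be nonnegative")
  }
  # the factor is defined only for opioids
  entries$mme_factor[!op] <- NA_real_
  entries$extended_release[is.na(entries$extended_release)] <- FALSE
  entries$extended_release[!op] <- FALSE
  class(entries) <- c("drug_catalog", class(entries))
  entries
}

#' Read a drug catalog from CSV
#'
#' Expects the header `drug_code,name,drug_class,mme_factor,extended_release`;
#' booleans as `true`/`false`; `mme_factor` may be empty for non-opioids.
#'
#' @param path path to a UTF-8 CSV file.
#' @return a `drug_catalog` tibble.
#' @export
read_drug_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(mme_factor = "numeric"))
  df$extended_release <- tolower(trimws(as.character(df$extended_release))) %in%
    c("true", "t", "1", "yes")
  drug_catalog(df)
}

#' @rdname read_drug_catalog
#' @export
default_drug_catalog <- function() {
  read_drug_catalog(system.file("extdata", "default_drug_catalog.csv",
                                package = "rxscreen", mustWork = TRUE))
}

#' Classify drug codes
#'
#' Looks drug codes up in the catalog; codes absent from the catalog are
#' classified `"other"` (and therefore never screened).
#'
#' @param catalog a [drug_catalog()].
#' @param drug_code character vector of drug codes.
#' @return character vector of classes, same length as `drug_code`.
#' @export
classify_drug <- function(catalog, drug_code) {
  stopifnot(inherits(catalog, "drug_catalog"))
  if (nrow(catalog) == 0) stop("drug catalog is empty (configuration error)")
  if (any(!nzchar(drug_code))) stop("empty drug_code")
  idx <- match(drug_code, catalog$drug_code)
  out <- catalog$drug_class[idx]
  out[is.na(idx)] <- "other"
  out
}

#' Morphine milligram equivalents of a prescription order
#'
#' `daily_mme = strength_mg * units_per_day * mme_factor` and
#' `total_mme = daily_mme * days_supply`. Non-opioid orders have MME 0 by
#' definition.
#'
#' @param catalog a [drug_catalog()].
#' @param order a data frame (one row per order) with columns `drug_code`,
#'   `strength_mg`, `units_per_day` and `days_supply`.
#' @return a tibble with columns `daily_mme` and `total_mme`.
#' @examples
#' cat <- default_drug_catalog()
#' daily_mme(cat, data.frame(drug_code = "OXYCODONE-10", strength_mg = 10,
#'                           units_per_day = 3, days_supply = 5))
#' @export
daily_mme <- function(catalog, order) {
  stopifnot(inherits(catalog, "drug_catalog"))
  order <- as.data.frame(order)
  stopifnot(all(c("drug_code", "strength_mg", "units_per_day", "days_supply")
                %in% names(order)))
  if (any(order$strength_mg <= 0) || any(order$units_per_day <= 0)) {
    stop("strength_mg and units_per_day must be positive")
  }
  if (any(order$days_supply < 0)) stop("days_supply must be nonnegative")
  cls <- classify_drug(catalog, order$drug_code)
  factor <- catalog$mme_factor[match(order$drug_code, catalog$drug_code)]
  op <- cls == "opioid"
  if (any(op & is.na(factor))) {
    stop("opioid order with missing MME factor in catalog: ",
         paste(unique(order$drug_code[op & is.na(factor)]), collapse = ", "))
  }
  daily <- ifelse(op, order$strength_mg * order$units_per_day * factor, 0)
  tibble::tibble(daily_mme = daily, total_mme = daily * order$days_supply)
}

#' Daily-MME risk band
#'
#' Partitions nonnegative daily MME into the bands `[0, 50)`, `[50, 90)`
#' and `[90, Inf)` used in descriptive dose summaries. Zero or missing MME
#' records (all non-opioid orders) are excluded from band summaries by the
#' caller.
#'
#' @param daily_mme nonnegative numeric vector.
#' @return factor with levels `under50`, `from50to89`, `atLeast90`.
#' @export
mme_risk_band <- function(daily_mme) {
  if (any(daily_mme < 0, na.rm = TRUE)) stop("daily_mme must be nonnegative")
  cut(daily_mme, breaks = c(0, 50, 90, Inf), right = FALSE,
      labels = c("under50", "from50to89", "atLeast90"))
}
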