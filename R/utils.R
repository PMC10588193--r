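# internal helpers: rounding and timestamp arithmetic

`%||%` <- function(x, y) if (is.null(x)) y else x

# half-up rounding (R's round() is banker's rounding); the small epsilon
# guards against binary representations just below the .5 boundary
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5 + 1e-8) / m
}

#' Reported percentage
#'
#' Converts a count and a denominator into the percentage used in all
#' reported rate tables: computed at full precision, rounded half-up to two
#' decimals and then half-up to one (the convention of report tables
#' exported at two decimals and displayed at one; see the methods
#' vignette).
#'
#' @param x numerator count(s).
#' @param n denominator count(s); must satisfy `x <= n`.
#' @param digits digits displayed, default 1.
#' @return numeric vector of percentages in `[0, 100]`; `NA` where `n == 0`.
#' @examples
#' report_rate(100301, 555626)  # 18.1
#' @export
report_rate <- function(x, n, digits = 1) {
  stopifnot(length(x) == length(n), all(x >= 0), all(n >= 0))
  if (any(x > n)) stop("numerator exceeds denominator")
  out <- rep(NA_real_, length(x))
  ok <- n > 0
  out[ok] <- round_half_up(round_half_up(100 * x[ok] / n[ok], digits + 1), digits)
  out
}

# Internal time scale: numeric days since 1970-01-01 (timezone-naive),
# fractional days allowed. All windows are day-granular.
day_number <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  as.numeric(as.Date(x))
}

# parse ISO-8601 date or datetime strings to numeric days; NA on failure
parse_event_time <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (inherits(x, "Date")) return(as.numeric(x))
  if (inherits(x, "POSIXt")) return(as.numeric(x) / 86400)
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  is_date <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (any(is_date)) {
    d <- as.Date(x[is_date], format = "%Y-%m-%d")
    out[is_date] <- as.numeric(d)
  }
  is_dt <- !is.na(x) & !is_date
  if (any(is_dt)) {
    v <- x[is_dt]
    p <- as.POSIXct(v, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
    miss <- is.na(p)
    if (any(miss)) {
      p[miss] <- as.POSIXct(v[miss], tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
    }
    out[is_dt] <- as.numeric(p) / 86400
  }
  out
}

# numeric days -> ISO string (date when integral, datetime otherwise)
format_event_time <- function(day) {
  out <- character(length(day))
  whole <- !is.na(day) & day == floor(day)
  out[whole] <- format(as.Date(day[whole], origin = "1970-01-01"))
  frac <- !is.na(day) & !whole
  if (any(frac)) {
    out[frac] <- format(as.POSIXct(day[frac] * 86400, origin = "1970-01-01",
                                   tz = "UTC"), "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
  out[is.na(day)] <- NA_character_
  out
}

# first day of the calendar month containing a numeric day
month_floor <- function(day) {
  d <- as.Date(day, origin = "1970-01-01")
  as.Date(format(d, "%Y-%m-01"))
}
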