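# Analytics: stratified decision-influenced rates, categorical tests, and
# Shewhart p-charts with special-cause detection.

#' Stratified decision-influenced rates
#'
#' One cell per stratum value plus an `"all"` cell, among encounters whose
#' alert fired. `rate_percent` uses the reporting convention of
#' [report_rate()] (one decimal); `rate` is the full-precision proportion.
#' Strata with no encounters get `n = 0` and `NA` rates, flagged in
#' `empty`; encounters with a missing stratum value form a `"(missing)"`
#' cell so the cells always partition the `"all"` counts exactly.
#'
#' @param outcomes encounter outcomes from [classify_encounters()] (or any
#'   data frame with logical `decision_influenced` and, optionally,
#'   logical `had_alert` to filter on).
#' @param by optional name of a stratifier column; `NULL` gives the
#'   `"all"` cell only.
#' @return tibble with `stratum`, `n_encounters`, `n_influenced`, `rate`,
#'   `rate_percent`, `empty`.
#' @export
rate_table <- function(outcomes, by = NULL) {
  if ("had_alert" %in% names(outcomes)) {
    outcomes <- outcomes[outcomes$had_alert, , drop = FALSE]
  }
  cell <- function(label, flag) {
    tibble::tibble(stratum = label, n_encounters = sum(flag),
                   n_influenced = sum(outcomes$decision_influenced[flag]))
  }
  cells <- list(cell("all", rep(TRUE, nrow(outcomes))))
  if (!is.null(by)) {
    v <- outcomes[[by]]
    lev <- if (is.factor(v)) levels(v) else sort(unique(as.character(v[!is.na(v)])))
    cells <- c(cells, lapply(lev, function(l) cell(l, !is.na(v) & v == l)))
    if (anyNA(v)) cells <- c(cells, list(cell("(missing)", is.na(v))))
  }
  out <- dplyr::bind_rows(cells)
  out$rate <- ifelse(out$n_encounters > 0,
                     out$n_influenced / out$n_encounters, NA_real_)
  out$rate_percent <- report_rate(out$n_influenced, out$n_encounters)
  out$empty <- out$n_encounters == 0
  out
}

#' Rates from pre-aggregated counts
#'
#' Adds the reported one-decimal percentage to a table of stratum counts
#' (columns `n_encounters`, `n_influenced`), e.g. a published summary
#' table used as a worked example.
#'
#' @param counts data frame with `n_encounters` and `n_influenced`.
#' @return the input with `rate` and `rate_percent` columns appended.
#' @export
rate_table_from_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("n_encounters", "n_influenced") %in% names(counts)))
  if (any(counts$n_influenced > counts$n_encounters)) {
    stop("n_influenced exceeds n_encounters")
  }
  counts$rate <- ifelse(counts$n_encounters > 0,
                        counts$n_influenced / counts$n_encounters, NA_real_)
  counts$rate_percent <- report_rate(counts$n_influenced, counts$n_encounters)
  counts
}

#' Summary counts from a deployed prescribing CDS program
#'
#' Encounter and decision-influenced counts, by trigger, alert and
#' stratum, from a 3.5-year deployment of opioid/benzodiazepine
#' prescription alerts across a large multi-center US health system
#' (2016-01 to 2019-07). Shipped as the package's worked example: all
#' percentages are recomputed from these counts at run time.
#'
#' @return tibble with `group`, `stratum`, `n_encounters`, `n_influenced`.
#'   The numerator's meaning follows the group: for the `screening` row it
#'   is encounters with an alert (out of encounters with a controlled
#'   prescription); for the `ninety_day_alert` / `naloxone_alert` rows it
#'   is pain agreements initiated / naloxone prescribed after the alert;
#'   for all other groups it is encounters where the prescribing decision
#'   was influenced (a cancel click).
#' @export
alert_summary_counts <- function() {
  path <- system.file("extdata", "alert_summary_counts.csv",
                      package = "rxscreen", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Pearson chi-square test on a contingency table
#'
#' Thin wrapper over [stats::chisq.test()] without continuity correction
#' (statistic `sum((O - E)^2 / E)`, df `(r - 1)(c - 1)`, upper-tail p),
#' with an explicit degenerate-table check.
#'
#' @param table a 2-dimensional matrix of counts.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  if (length(dim(table)) != 2 || any(dim(table) < 2)) {
    stop("need a 2-dimensional table with at least 2 rows and columns")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: a marginal total is zero")
  }
  ht <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Cochran-Armitage test for trend in proportions
#'
#' Signed trend statistic over k ordered groups:
#' `z = sum(s_i (x_i - n_i p)) / sqrt(p (1 - p) (sum n_i s_i^2 - (sum n_i s_i)^2 / N))`
#' with pooled proportion `p`. `z` is invariant under affine
#' transformations of the scores and flips sign under score reversal;
#' `z^2` equals the chi-square trend component (and
#' [stats::prop.trend.test()]'s statistic). Degenerate tables (all
#' successes or all failures) return `z = 0`, `p = 1`.
#'
#' @param n group sizes (ordered).
#' @param x successes per group.
#' @param scores numeric scores, default `1:k`.
#' @param alternative `"two.sided"` (default), `"increasing"` or
#'   `"decreasing"`.
#' @return list with `z_statistic`, `p_value`, `scores`, `direction`.
#' @examples
#' cochran_armitage_trend(c(100, 100, 100), c(10, 20, 30))
#' @export
cochran_armitage_trend <- function(n, x, scores = seq_along(n),
                                   alternative = c("two.sided", "increasing",
                                                   "decreasing")) {
  alternative <- match.arg(alternative)
  stopifnot(length(n) >= 2, length(x) == length(n),
            length(scores) == length(n), all(x >= 0), all(x <= n))
  N <- sum(n)
  pbar <- sum(x) / N
  if (pbar == 0 || pbar == 1) {
    return(list(z_statistic = 0, p_value = 1, scores = scores,
                direction = "none"))
  }
  num <- sum(scores * (x - n * pbar))
  den <- sqrt(pbar * (1 - pbar) * (sum(n * scores^2) - sum(n * scores)^2 / N))
  z <- num / den
  p <- switch(alternative,
              two.sided = 2 * pnorm(-abs(z)),
              increasing = pnorm(z, lower.tail = FALSE),
              decreasing = pnorm(z))
  list(z_statistic = z, p_value = p, scores = scores,
       direction = if (z > 0) "increasing" else if (z < 0) "decreasing" else "none")
}

#' Monthly alert / influenced counts
#'
#' Aggregates alerted encounter outcomes by calendar month for p-chart
#' construction.
#'
#' @param outcomes encounter outcomes from [classify_encounters()].
#' @return tibble with `month` (Date, first of month), `n` (alerted
#'   encounters) and `x` (decision influenced).
#' @export
monthly_counts <- function(outcomes) {
  o <- outcomes[outcomes$had_alert, , drop = FALSE]
  m <- if ("month" %in% names(o)) o$month else month_floor(o$time)
  agg <- dplyr::summarise(dplyr::group_by(tibble::tibble(
    month = m, infl = o$decision_influenced), .data$month),
    n = dplyr::n(), x = sum(.data$infl), .groups = "drop")
  dplyr::arrange(agg, .data$month)
}

#' Build a Shewhart p-chart
#'
#' Center line `pbar = sum(x)/sum(n)` pooled over the BASELINE periods
#' only (post-baseline data never move the center); per-period sigma
#' `sqrt(pbar (1 - pbar) / n_i)`; control/zone limits at `pbar +/- k
#' sigma_i` for k = 1, 2, 3, truncated to `[0, 1]`.
#'
#' @param monthly tibble of ordered periods with columns `month`, `n`,
#'   `x` (see [monthly_counts()]).
#' @param baseline length-2 vector (Date or string) giving the inclusive
#'   first/last baseline month, e.g. `c("2016-01-01", "2016-12-01")`.
#' @return a `p_chart` tibble with per-period `p`, `center`, `sigma`,
#'   `lcl_1`..`lcl_3`, `ucl_1`..`ucl_3` and `in_baseline`.
#' @export
build_p_chart <- function(monthly, baseline) {
  monthly <- tibble::as_tibble(monthly)
  stopifnot(all(c("month", "n", "x") %in% names(monthly)),
            all(monthly$x <= monthly$n), length(baseline) == 2)
  monthly <- dplyr::arrange(monthly, .data$month)
  b0 <- as.Date(baseline[1]); b1 <- as.Date(baseline[2])
  in_base <- monthly$month >= b0 & monthly$month <= b1
  if (!any(in_base) || sum(monthly$n[in_base]) == 0) {
    stop("empty baseline: no periods with n > 0 in the baseline range")
  }
  pbar <- sum(monthly$x[in_base]) / sum(monthly$n[in_base])
  sigma <- sqrt(pbar * (1 - pbar) / monthly$n)
  chart <- monthly
  chart$p <- ifelse(chart$n > 0, chart$x / chart$n, NA_real_)
  chart$center <- pbar
  chart$sigma <- sigma
  for (k in 1:3) {
    chart[[paste0("lcl_", k)]] <- pmax(0, pbar - k * sigma)
    chart[[paste0("ucl_", k)]] <- pmin(1, pbar + k * sigma)
  }
  chart$in_baseline <- in_base
  structure(chart, class = c("p_chart", class(chart)),
            center = pbar, baseline = c(b0, b1))
}

#' Special-cause rule set
#'
#' The standard Shewhart/IHI rules, individually toggleable with exposed
#' run-length parameters:
#' 1. a point beyond 3 sigma;
#' 2. `shift_run` (default 8) consecutive points on one side of the
#'    center line (points exactly on the center break the run);
#' 3. `trend_run` (default 6) consecutive strictly increasing or
#'    decreasing points;
#' 4. 2 of 3 consecutive points beyond 2 sigma on the same side;
#' 5. `inner_run` (default 15) consecutive points within 1 sigma of the
#'    center.
#'
#' @param beyond_3sigma,shift,trend,two_of_three_2sigma,inner toggles.
#' @param shift_run,trend_run,inner_run run-length parameters.
#' @return an `spc_rules` list.
#' @export
spc_rules <- function(beyond_3sigma = TRUE, shift = TRUE, trend = TRUE,
                      two_of_three_2sigma = TRUE, inner = TRUE,
                      shift_run = 8, trend_run = 6, inner_run = 15) {
  structure(list(beyond_3sigma = beyond_3sigma, shift = shift, trend = trend,
                 two_of_three_2sigma = two_of_three_2sigma, inner = inner,
                 shift_run = shift_run, trend_run = trend_run,
                 inner_run = inner_run),
            class = "spc_rules")
}

# flag every point belonging to a qualifying run of TRUEs of length >= len
flag_runs <- function(ok, len) {
  r <- rle(ok)
  hit <- r$values & r$lengths >= len
  rep(hit, r$lengths)
}

#' Detect special-cause variation on a p-chart
#'
#' Applies the [spc_rules()] rule set per period and adds one logical
#' column per rule plus `special_cause` (any rule). Rules flag every point
#' participating in the qualifying pattern.
#'
#' @param chart a [build_p_chart()] result.
#' @param rules an [spc_rules()] rule set.
#' @return the chart with rule columns appended.
#' @export
detect_special_cause <- function(chart, rules = spc_rules()) {
  stopifnot(inherits(chart, "p_chart"))
  p <- chart$p
  ctr <- chart$center
  sg <- chart$sigma
  n <- length(p)
  side <- sign(p - ctr)   # 0 exactly on the center line

  r1 <- rules$beyond_3sigma & !is.na(p) & abs(p - ctr) > 3 * sg

  r2 <- rep(FALSE, n)
  if (rules$shift) {
    r2 <- (flag_runs(!is.na(side) & side > 0, rules$shift_run) |
             flag_runs(!is.na(side) & side < 0, rules$shift_run))
  }

  r3 <- rep(FALSE, n)
  if (rules$trend && n >= rules$trend_run) {
    d <- sign(diff(p))
    up <- c(FALSE, !is.na(d) & d > 0)   # point i continues an increase
    dn <- c(FALSE, !is.na(d) & d < 0)
    # a run of (trend_run - 1) consecutive moves spans trend_run points
    run_up <- flag_runs(up, rules$trend_run - 1)
    run_dn <- flag_runs(dn, rules$trend_run - 1)
    # include the point that started each flagged run
    r3 <- run_up | run_dn | c(run_up[-1] & up[-1], FALSE) |
      c(run_dn[-1] & dn[-1], FALSE)
  }

  r4 <- rep(FALSE, n)
  if (rules$two_of_three_2sigma) {
    hi <- !is.na(p) & p - ctr > 2 * sg
    lo <- !is.na(p) & ctr - p > 2 * sg
    for (i in seq_len(n)) {
      win <- i:min(n, i + 2)
      if (length(win) == 3) {
        if (sum(hi[win]) >= 2) r4[win][hi[win]] <- TRUE
        if (sum(lo[win]) >= 2) r4[win][lo[win]] <- TRUE
      }
    }
  }

  r5 <- rep(FALSE, n)
  if (rules$inner) {
    r5 <- flag_runs(!is.na(p) & abs(p - ctr) < sg, rules$inner_run)
  }

  chart$beyond_3sigma <- r1
  chart$shift_run <- r2
  chart$trend_run <- r3
  chart$two_of_three_2sigma <- r4
  chart$inner_run <- r5
  chart$special_cause <- r1 | r2 | r3 | r4 | r5
  chart
}

#' Plot a p-chart
#'
#' Monthly proportion with the baseline center line and 1/2/3-sigma zone
#' limits; points showing special-cause evidence are filled.
#'
#' @param x a `p_chart` (special-cause columns are computed with default
#'   rules if absent).
#' @param ... ignored.
#' @return a ggplot object.
#' @export
plot.p_chart <- function(x, ...) {
  if (!"special_cause" %in% names(x)) x <- detect_special_cause(x)
  df <- as.data.frame(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$month, y = .data$p)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lcl_3, ymax = .data$ucl_3),
                         fill = "grey92") +
    ggplot2::geom_line(ggplot2::aes(y = .data$center), linetype = "solid",
                       colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ucl_3), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$lcl_3), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ucl_2), linetype = "dotted") +
    ggplot2::geom_line(ggplot2::aes(y = .data$lcl_2), linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(fill = .data$special_cause),
                        shape = 21, size = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white", `TRUE` = "black"),
                               name = "special cause") +
    ggplot2::labs(x = NULL, y = "proportion influenced") +
    ggplot2::theme_minimal()
}
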