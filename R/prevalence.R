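#' Binarize the mentally-unhealthy-days item
#'
#' The core survey item asks on how many of the past 30 days the respondent's
#' mental health was not good.  Responses of `cutoff` or more days (default
#' 15, i.e. the 15-30 vs 0-14 split) are coded 1, fewer days 0.  Special
#' codes follow the BRFSS dialect: 88 means "none" (0 days, coded 0), while
#' 77 (don't know) and 99 (refused) are missing (`NA`).
#'
#' @param days integer vector of responses in `0:30` or codes 77/88/99;
#'   `NA` passes through as missing.
#' @param cutoff integer in `1:30`; days `>= cutoff` count as cases.
#' @return an integer vector of 0/1/`NA`.
#' @export
#' @examples
#' binarize_days(c(15, 14, 30, 0, 88, 77, 99))
binarize_days <- function(days, cutoff = 15L) {
  stopifnot(length(cutoff) == 1L, cutoff >= 1L, cutoff <= 30L)
  legal <- is.na(days) | (days %in% c(0:30, 77L, 88L, 99L))
  if (!all(legal)) {
    bad <- which(!legal)
    stop("illegal days value(s) ", paste(days[utils::head(bad, 5L)], collapse = ", "),
         " at record(s) ", paste(utils::head(bad, 5L), collapse = ", "))
  }
  out <- rep(NA_integer_, length(days))
  out[!is.na(days) & days %in% 0:30] <-
    as.integer(days[!is.na(days) & days %in% 0:30] >= cutoff)
  out[!is.na(days) & days == 88L] <- 0L  # 88 = zero days
  out
}

validate_records <- function(records) {
  req <- c("ment14d_days", "weight", "interview_date")
  missing <- setdiff(req, names(records))
  if (length(missing)) {
    stop("microdata lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(records$weight) | records$weight <= 0)) {
    bad <- which(!is.finite(records$weight) | records$weight <= 0)
    stop("non-positive weight at record(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  invisible(records)
}

#' Survey-weighted weekly prevalence
#'
#' Aggregates respondent-level records to a weekly prevalence series: for
#' every week on the grid, \eqn{z_t = 100 \sum_i w_i y_i / \sum_i w_i} over
#' complete cases (records whose binarized outcome is missing are dropped,
#' complete-case handling).  Weeks without complete cases are `NA` with a
#' zero effective denominator.
#'
#' @param records tibble with columns `ment14d_days`, `weight`,
#'   `interview_date` (plus stratification attributes).
#' @param cutoff passed to [binarize_days()].
#' @param start_date first day of week 1; defaults to the ISO Monday of the
#'   earliest interview.
#' @param n_weeks grid length; defaults to the span of the interview dates.
#' @param stratum label stored on the result (metadata only).
#' @return a `weekly_series` with `prevalence_pct` and `n_effective` (sum of
#'   weights of complete cases per week).
#' @export
weighted_weekly_prevalence <- function(records, cutoff = 15L,
                                       start_date = NULL, n_weeks = NULL,
                                       stratum = "total") {
  if (NROW(records) == 0L) stop("no records (empty stratum?)")
  validate_records(records)
  dates <- as.Date(records$interview_date)
  if (is.null(start_date)) start_date <- min(dates)
  start_date <- iso_week_start(start_date)
  wk <- week_index(dates, start_date)
  if (is.null(n_weeks)) n_weeks <- max(wk)
  if (any(wk < 1L | wk > n_weeks)) {
    stop("interview dates fall outside the weekly grid (weeks ",
         min(wk), "..", max(wk), " vs 1..", n_weeks, ")")
  }
  y <- binarize_days(records$ment14d_days, cutoff)
  keep <- !is.na(y)  # complete cases
  num <- rep(0, n_weeks)
  den <- rep(0, n_weeks)
  if (any(keep)) {
    num <- num + as.numeric(
      tapply(records$weight[keep] * y[keep], factor(wk[keep], levels = seq_len(n_weeks)),
             sum, default = 0))
    den <- den + as.numeric(
      tapply(records$weight[keep], factor(wk[keep], levels = seq_len(n_weeks)),
             sum, default = 0))
  }
  z <- ifelse(den > 0, 100 * num / den, NA_real_)
  new_weekly_series(z, start_date = start_date, n_effective = den,
                    stratum = stratum)
}

#' Stratification groupings
#'
#' The standard groupings used for stratified models: age 18-64 / 65+;
#' sex female/male; race/ethnicity Hispanic / NH White / NH Black / NH other;
#' household income <25k / 25-50k / >=50k / refused; physical-health days
#' 0-13 / 14-30; raising children yes/no/refused.  Unknown levels are routed
#' to an explicit `"unclassified"` bucket, never dropped.
#'
#' @return named list mapping variable name to its expected levels.
#' @export
strata_definitions <- function() {
  list(
    age_group = c("18-64", "65+"),
    sex = c("female", "male"),
    race_ethnicity = c("hispanic", "nh_white", "nh_black", "nh_other"),
    income_band = c("<25k", "25-50k", ">=50k", "refused"),
    phys_days_band = c("0-13", "14-30"),
    raising_children = c("yes", "no", "refused")
  )
}

#' Stratified weekly prevalence series
#'
#' Splits the records by each stratification variable and computes one
#' weighted weekly series per level (plus the `"total"` series), all on a
#' common weekly grid.  `phys_days` (0-30) is banded into 0-13 / 14-30.
#'
#' @inheritParams weighted_weekly_prevalence
#' @param vars stratification variables (subset of
#'   `names(strata_definitions())`).
#' @return named list of `weekly_series`; names are `"total"` and
#'   `"<var>:<level>"`.
#' @export
stratify_prevalence <- function(records, cutoff = 15L, start_date = NULL,
                                n_weeks = NULL,
                                vars = names(strata_definitions())) {
  if (NROW(records) == 0L) stop("no records (empty stratum?)")
  validate_records(records)
  defs <- strata_definitions()[vars]
  if ("phys_days_band" %in% vars && !"phys_days_band" %in% names(records)) {
    if (!"phys_days" %in% names(records)) {
      stop("records lack phys_days / phys_days_band")
    }
    records$phys_days_band <- ifelse(records$phys_days <= 13, "0-13", "14-30")
  }
  dates <- as.Date(records$interview_date)
  if (is.null(start_date)) start_date <- min(dates)
  start_date <- iso_week_start(start_date)
  if (is.null(n_weeks)) n_weeks <- max(week_index(dates, start_date))

  out <- list(total = weighted_weekly_prevalence(
    records, cutoff, start_date, n_weeks, stratum = "total"))
  for (v in names(defs)) {
    if (!v %in% names(records)) stop("records lack stratification column ", v)
    lev <- as.character(records[[v]])
    lev[!lev %in% defs[[v]]] <- "unclassified"
    for (l in unique(c(defs[[v]], intersect("unclassified", lev)))) {
      key <- paste0(v, ":", l)
      sub <- records[lev == l, , drop = FALSE]
      out[[key]] <- if (NROW(sub) == 0L) {
        new_weekly_series(rep(NA_real_, n_weeks), start_date,
                          n_effective = rep(0, n_weeks), stratum = key)
      } else {
        weighted_weekly_prevalence(sub, cutoff, start_date, n_weeks,
                                   stratum = key)
      }
    }
  }
  out
}
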