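#' Weekly calendar utilities and the default interruption calendar
#'
#' The analysis is anchored on a gap-free weekly grid whose weeks start on
#' Mondays (ISO-8601 convention).  The default study window runs from ISO week
#' 2019-W01 (Monday 2018-12-31) through 2023-W08, i.e. 217 weeks.
#'
#' @name calendar
NULL

#' Monday of the ISO week containing a date
#'
#' @param date a `Date` vector.
#' @return a `Date` vector of the same length, each the Monday of its ISO week.
#' @export
#' @examples
#' iso_week_start(as.Date("2020-12-11"))  # Monday 2020-12-07
iso_week_start <- function(date) {
  date <- as.Date(date)
  # POSIXlt wday: 0 = Sunday ... 6 = Saturday; ISO weeks start Monday
  wday <- as.POSIXlt(date)$wday
  date - ((wday + 6L) %% 7L)
}

#' Build the weekly grid of a study window
#'
#' @param start_date date of (any day in) week 1; snapped to its ISO Monday.
#' @param n_weeks number of weeks.
#' @return a `Date` vector of `n_weeks` Mondays.
#' @export
week_starts <- function(start_date = as.Date("2018-12-31"), n_weeks = 217L) {
  stopifnot(n_weeks >= 1L)
  iso_week_start(start_date) + 7L * (seq_len(n_weeks) - 1L)
}

#' Week index of a date on a weekly grid
#'
#' @param date a `Date` vector.
#' @param start_date first day of week 1 (snapped to its ISO Monday).
#' @return integer week indices; dates before week 1 give indices < 1 and
#'   dates after the grid give indices > `n_weeks` (callers decide how to
#'   handle out-of-range weeks).
#' @export
week_index <- function(date, start_date = as.Date("2018-12-31")) {
  start <- iso_week_start(start_date)
  as.integer(floor(as.numeric(as.Date(date) - start) / 7)) + 1L
}

#' Default interruption calendar
#'
#' The 11 dated interruptions used throughout: 8 phases of the US COVID-19
#' vaccine rollout (ids 3-6 and 8-11) and 3 pandemic-related events
#' (ids 1, 2 and 7), January 10, 2020 through June 18, 2022.
#'
#' @return a tibble with columns `id`, `date`, `label`, `category`
#'   (`"vaccine_rollout"` or `"pandemic_event"`).
#' @export
#' @examples
#' default_calendar()
default_calendar <- function() {
  tibble::tibble(
    id = 1:11,
    date = as.Date(c(
      "2020-01-10", "2020-03-13", "2020-12-11", "2021-03-02", "2021-04-19",
      "2021-05-10", "2021-07-30", "2021-09-22", "2021-10-29", "2021-11-21",
      "2022-06-18"
    )),
    label = c(
      "Identification of SARS-CoV-2",
      "National emergency declaration",
      "Phase 1: healthcare workers and at-risk groups",
      "Prioritization for educational/childcare workers",
      "Phase 2: all individuals aged 16+",
      "Authorization for adolescents aged 12-15",
      "CDC guidance concerning Delta variant",
      "First booster for at-risk populations",
      "Authorization for children aged 5-11",
      "Booster for all US adults",
      "Authorization for children aged 6 months to 5 years"
    ),
    category = c(
      "pandemic_event", "pandemic_event", "vaccine_rollout", "vaccine_rollout",
      "vaccine_rollout", "vaccine_rollout", "pandemic_event", "vaccine_rollout",
      "vaccine_rollout", "vaccine_rollout", "vaccine_rollout"
    )
  )
}

validate_calendar <- function(events) {
  req <- c("id", "date", "label", "category")
  missing <- setdiff(req, names(events))
  if (length(missing)) {
    stop("interruption calendar lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(events$id)) stop("interruption ids must be unique")
  bad <- setdiff(unique(events$category), c("vaccine_rollout", "pandemic_event"))
  if (length(bad)) {
    stop("unknown interruption category: ", paste(bad, collapse = ", "))
  }
  events$date <- as.Date(events$date)
  events[order(events$date, events$id), , drop = FALSE]
}

#' Lagged onset week of an interruption
#'
#' Intervention indicators start a fixed number of weeks after the event
#' itself, so that an outcome asking about the preceding 30 days has had time
#' to respond; the default lag is 4 weeks (1 month).
#'
#' @param event_date the interruption date.
#' @param start_date first day of week 1 of the series.
#' @param lag_weeks non-negative integer lag (default 4).
#' @return integer week index of the lagged onset.
#' @export
lagged_onset <- function(event_date, start_date = as.Date("2018-12-31"),
                         lag_weeks = 4L) {
  stopifnot(lag_weeks >= 0L)
  week_index(event_date, start_date) + as.integer(lag_weeks)
}

#' Build the lagged multi-intervention design matrix
#'
#' Encodes each interruption as a binary indicator column on the weekly grid,
#' beginning `lag_weeks` after the week containing the event date:
#'
#' * `vaccine_rollout` events form one chronological sequence of mutually
#'   exclusive, contiguous *segments*: each phase's column is 1 from its
#'   lagged onset up to (but excluding) the lagged onset of the next rollout
#'   phase; the final phase extends to the end of the series.
#' * `pandemic_event` columns are permanent *steps* (1 from lagged onset to
#'   the end) by default; `pandemic_coding = "pulse"` limits them to the onset
#'   week, and `"segment"` chains them like rollout phases.
#'
#' Events whose lagged onset falls after the series end yield an all-zero
#' column with a warning.  Events dated before week 1 are active from week 1.
#'
#' @param events interruption calendar (see [default_calendar()]).
#' @param n_weeks number of weeks in the series.
#' @param start_date first day of week 1.
#' @param lag_weeks lag in whole weeks between event and indicator onset.
#' @param pandemic_coding `"step"` (default), `"pulse"`, or `"segment"`.
#' @return an `its_design`: an `n_weeks` x `nrow(events)` 0/1 matrix with
#'   columns `event_<id>`, carrying attributes `events`, `onsets`,
#'   `lag_weeks`, `start_date` and `coding`.
#' @export
#' @examples
#' D <- build_design_matrix(default_calendar(), n_weeks = 217)
#' colSums(D)
build_design_matrix <- function(events = default_calendar(), n_weeks = 217L,
                                start_date = as.Date("2018-12-31"),
                                lag_weeks = 4L,
                                pandemic_coding = c("step", "pulse", "segment")) {
  pandemic_coding <- match.arg(pandemic_coding)
  events <- validate_calendar(events)
  stopifnot(n_weeks >= 1L)
  n_weeks <- as.integer(n_weeks)

  onsets <- lagged_onset(events$date, start_date, lag_weeks)
  X <- matrix(0L, nrow = n_weeks, ncol = nrow(events))
  if (nrow(events)) colnames(X) <- paste0("event_", events$id)

  fill_segments <- function(idx) {
    # chronological chain: each column ends where the next one starts
    if (anyDuplicated(events$date[idx])) {
      stop("duplicate dates among segment-coded events: segmentation undefined")
    }
    ons <- onsets[idx]
    ends <- c(ons[-1] - 1L, n_weeks)
    for (j in seq_along(idx)) {
      if (ons[j] > n_weeks) {
        warning("event ", events$id[idx[j]], " (", events$label[idx[j]],
                "): lagged onset beyond series end; column is all zero",
                call. = FALSE)
        next
      }
      s <- max(ons[j], 1L); e <- min(ends[j], n_weeks)
      if (e >= s) X[s:e, idx[j]] <<- 1L
    }
  }

  roll <- which(events$category == "vaccine_rollout")
  if (length(roll)) fill_segments(roll)

  pand <- which(events$category == "pandemic_event")
  if (length(pand)) {
    if (pandemic_coding == "segment") {
      fill_segments(pand)
    } else {
      for (j in pand) {
        if (onsets[j] > n_weeks) {
          warning("event ", events$id[j], " (", events$label[j],
                  "): lagged onset beyond series end; column is all zero",
                  call. = FALSE)
          next
        }
        end <- if (pandemic_coding == "pulse") onsets[j] else n_weeks
        s <- max(onsets[j], 1L); e <- min(end, n_weeks)
        if (e >= s) X[s:e, j] <- 1L
      }
    }
  }

  structure(X,
            events = events, onsets = onsets, lag_weeks = as.integer(lag_weeks),
            start_date = iso_week_start(start_date), coding = pandemic_coding,
            class = c("its_design", "matrix", "array"))
}

#' @export
print.its_design <- function(x, ...) {
  ev <- attr(x, "events")
  cat("<its_design> ", nrow(x), " weeks x ", ncol(x), " interruption columns\n",
      "  lag: ", attr(x, "lag_weeks"), " weeks; week 1 starts ",
      format(attr(x, "start_date")), "\n", sep = "")
  on <- attr(x, "onsets")
  for (j in seq_len(ncol(x))) {
    cat(sprintf("  %-9s %-15s onset week %3d  active %d weeks\n",
                colnames(x)[j], ev$category[j], on[j], sum(x[, j])))
  }
  invisible(x)
}

#' Export a design matrix as a data frame
#'
#' @param design an `its_design` matrix.
#' @return a tibble with `week`, `week_start_date` and one column per event.
#' @export
design_as_tibble <- function(design) {
  stopifnot(inherits(design, "its_design"))
  ws <- week_starts(attr(design, "start_date"), nrow(design))
  dplyr::bind_cols(
    tibble::tibble(week = seq_len(nrow(design)), week_start_date = ws),
    tibble::as_tibble(unclass(design)[seq_len(nrow(design)), , drop = FALSE])
  )
}
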