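#' Simulation scenarios for weekly prevalence series
#'
#' A `scenario` fixes every ingredient of the generating model
#' \deqn{z_t = baseline + drift \cdot t + \sum_k \delta_k I_k(t) + u_t,}
#' where \eqn{I_k(t)} is the lagged intervention design of
#' [build_design_matrix()] and \eqn{u_t} is ARMA(1,1) noise, optionally
#' integrated once (`d = 1`) to mimic an ARIMA(0,1,1)-type outcome process.
#' Defaults mirror the study conditions the estimators are validated under:
#' 217 weeks from ISO 2019-W01, baseline 12.9 percentage points, weekly drift
#' 0.034 pp, integrated MA(1) noise with \eqn{\theta = 0.5} and
#' \eqn{\sigma_\epsilon = 0.5} pp, and a 4-week intervention lag.
#'
#' @param n_weeks number of weeks (>= 2).
#' @param start_date first day of week 1 (snapped to its ISO Monday).
#' @param baseline prevalence level in percentage points.
#' @param drift weekly trend constant in percentage points per week.
#' @param ma_theta MA(1) coefficient of the noise.
#' @param ar_phi AR(1) coefficient of the noise (|phi| < 1).
#' @param innovation_sd innovation standard deviation (>= 0), percentage points.
#' @param d 0 for stationary ARMA noise, 1 for once-integrated noise.
#' @param effects named numeric vector of step effects in percentage points;
#'   names are event ids of `events` (e.g. `c("4" = -0.93)`).
#' @param lag_weeks intervention lag in whole weeks.
#' @param events interruption calendar (default [default_calendar()]).
#' @param pandemic_coding passed to [build_design_matrix()].
#' @param seed integer RNG seed.
#' @return a `scenario` object (a list).
#' @export
#' @examples
#' sc <- scenario(effects = c("4" = -0.93), seed = 1)
#' z <- simulate_weekly_series(sc)
scenario <- function(n_weeks = 217L, start_date = as.Date("2018-12-31"),
                     baseline = 12.9, drift = 0.034,
                     ma_theta = 0.5, ar_phi = 0, innovation_sd = 0.5, d = 1L,
                     effects = numeric(0), lag_weeks = 4L,
                     events = default_calendar(),
                     pandemic_coding = "step", seed = 1L) {
  stopifnot(n_weeks >= 2L, innovation_sd >= 0, lag_weeks >= 0L, d %in% 0:1,
            abs(ar_phi) < 1)
  events <- validate_calendar(events)
  effects <- unlist(effects)  # accept list input (e.g. from YAML/JSON configs)
  if (is.null(effects)) effects <- numeric(0)
  stopifnot(is.numeric(effects))
  if (length(effects)) {
    if (is.null(names(effects)) || any(!nzchar(names(effects)))) {
      stop("`effects` must be named by event id")
    }
    unknown <- setdiff(names(effects), as.character(events$id))
    if (length(unknown)) {
      stop("effect(s) reference unknown event id(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(list(
    n_weeks = as.integer(n_weeks), start_date = iso_week_start(start_date),
    baseline = baseline, drift = drift, ma_theta = ma_theta, ar_phi = ar_phi,
    innovation_sd = innovation_sd, d = as.integer(d),
    effects = effects, lag_weeks = as.integer(lag_weeks), events = events,
    pandemic_coding = pandemic_coding, seed = as.integer(seed)
  ), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", x$n_weeks, " weeks from ", format(x$start_date),
      "; baseline ", x$baseline, " pp, drift ", x$drift, " pp/week\n",
      "  noise: ARMA(phi=", x$ar_phi, ", theta=", x$ma_theta, "), sd ",
      x$innovation_sd, ", d=", x$d, "; lag ", x$lag_weeks,
      " weeks; seed ", x$seed, "\n", sep = "")
  if (length(x$effects)) {
    cat("  effects (pp): ",
        paste(names(x$effects), unname(x$effects), sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# Simulate ARMA(1,1) noise.  An MA(1) (phi = 0) is exact from the first
# observation; with an AR component a 500-step burn-in brings the process to
# (effective) stationarity so finite-sample moments match
# theoretical_moments().  For d = 1 the stationary ARMA noise is cumulated.
simulate_arma_noise <- function(n, phi, theta, sd, d) {
  if (sd == 0) return(numeric(n))
  burn <- if (phi != 0) 500L else 0L
  m <- n + burn
  eps <- stats::rnorm(m + 1L, 0, sd)
  u <- numeric(m)
  u[1] <- eps[2] + theta * eps[1]
  if (m > 1L) {
    for (t in 2:m) u[t] <- phi * u[t - 1] + eps[t + 1] + theta * eps[t]
  }
  u <- u[(burn + 1L):m]
  if (d == 1L) cumsum(u) else u
}

#' Simulate a weekly prevalence series from a scenario
#'
#' Deterministic given the scenario's seed.  With `innovation_sd = 0` the
#' output equals the deterministic mean function exactly.
#'
#' @param sc a [scenario()].
#' @return a `weekly_series` tibble with columns `week`, `week_start_date`,
#'   `prevalence_pct` and attribute `scenario`.
#' @export
simulate_weekly_series <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  set.seed(sc$seed)
  n <- sc$n_weeks
  X <- build_design_matrix(sc$events, n, sc$start_date, sc$lag_weeks,
                           sc$pandemic_coding)
  delta <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (length(sc$effects)) {
    delta[paste0("event_", names(sc$effects))] <- unname(sc$effects)
  }
  mean_fn <- sc$baseline + sc$drift * seq_len(n) +
    as.numeric(unclass(X)[seq_len(n), , drop = FALSE] %*% delta)
  z <- mean_fn + simulate_arma_noise(n, sc$ar_phi, sc$ma_theta,
                                     sc$innovation_sd, sc$d)
  new_weekly_series(z, start_date = sc$start_date, scenario = sc)
}

new_weekly_series <- function(values, start_date, n_effective = NA_real_,
                              stratum = "total", scenario = NULL) {
  out <- tibble::tibble(
    week = seq_along(values),
    week_start_date = week_starts(start_date, length(values)),
    prevalence_pct = as.numeric(values),
    n_effective = n_effective
  )
  attr(out, "stratum") <- stratum
  attr(out, "start_date") <- iso_week_start(start_date)
  if (!is.null(scenario)) attr(out, "scenario") <- scenario
  class(out) <- c("weekly_series", class(out))
  out
}

#' Theoretical noise moments of a scenario
#'
#' Closed-form mean, variance and lag-1 autocovariance of the stationary
#' ARMA(1,1) noise \eqn{u_t = \phi u_{t-1} + \epsilon_t + \theta
#' \epsilon_{t-1}}: \eqn{\gamma_0 = \sigma^2 (1 + \theta^2 + 2\phi\theta) /
#' (1-\phi^2)} and \eqn{\gamma_1 = \sigma^2 (1+\phi\theta)(\phi+\theta) /
#' (1-\phi^2)}.  Used as the oracle for long-run simulation checks; only
#' defined for `d = 0`.
#'
#' @param sc a [scenario()] with `d = 0`.
#' @return a list with `mean`, `variance`, `lag1_autocov`.
#' @export
theoretical_moments <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  if (sc$d != 0L) {
    stop("theoretical moments are only defined for stationary noise (d = 0)")
  }
  s2 <- sc$innovation_sd^2
  phi <- sc$ar_phi
  theta <- sc$ma_theta
  list(
    mean = 0,
    variance = s2 * (1 + theta^2 + 2 * phi * theta) / (1 - phi^2),
    lag1_autocov = s2 * (1 + phi * theta) * (phi + theta) / (1 - phi^2)
  )
}

#' Microdata simulation scenario
#'
#' Parameters of a synthetic respondent-level survey emulating the microdata
#' the prevalence stage consumes: per-week respondent counts, a log-normal
#' positive weight law, a days-response model whose exceedance probability
#' tracks a target weekly series, a stratum mixture with centred prevalence
#' shifts, and a rate of special missing-data codes.
#'
#' @param respondents_per_week positive integer.
#' @param weight_meanlog,weight_sdlog log-normal weight parameters.
#' @param strata_mix data frame with columns `label`, `share`, `shift`
#'   (percentage-point prevalence shift; shares must sum to 1).  Shifts are
#'   centred so the share-weighted mean shift is 0, preserving the target.
#' @param missing_rate probability in `[0, 1)` that a response is replaced by
#'   a special code (77 don't know / 99 refused).
#' @param zero_share probability that a below-cutoff response is 0 days
#'   (recorded with BRFSS-dialect code 88).
#' @param cutoff days cutoff the exceedance tracks (default 15).
#' @param seed integer RNG seed.
#' @return a `microdata_scenario` object.
#' @export
microdata_scenario <- function(respondents_per_week = 150L,
                               weight_meanlog = 0, weight_sdlog = 0.5,
                               strata_mix = default_strata_mix(),
                               missing_rate = 0.02, zero_share = 0.6,
                               cutoff = 15L, seed = 1L) {
  stopifnot(respondents_per_week >= 1L, missing_rate >= 0, missing_rate < 1,
            zero_share >= 0, zero_share <= 1, cutoff >= 1L, cutoff <= 30L)
  req <- c("label", "share", "shift")
  if (!all(req %in% names(strata_mix))) {
    stop("strata_mix needs columns: ", paste(req, collapse = ", "))
  }
  if (abs(sum(strata_mix$share) - 1) > 1e-8) {
    stop("strata_mix shares must sum to 1 (got ", sum(strata_mix$share), ")")
  }
  strata_mix$shift <- strata_mix$shift -
    sum(strata_mix$share * strata_mix$shift)
  structure(list(
    respondents_per_week = as.integer(respondents_per_week),
    weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog,
    strata_mix = strata_mix, missing_rate = missing_rate,
    zero_share = zero_share, cutoff = as.integer(cutoff),
    seed = as.integer(seed)
  ), class = "microdata_scenario")
}

#' Default race/ethnicity stratum mixture
#'
#' Shares roughly matching the composition of a large US adult telephone
#' survey; shifts default to 0 (no stratum effect).
#'
#' @return a tibble with columns `label`, `share`, `shift`.
#' @export
default_strata_mix <- function() {
  tibble::tibble(
    label = c("hispanic", "nh_white", "nh_black", "nh_other"),
    share = c(0.169, 0.617, 0.119, 0.095),
    shift = c(0, 0, 0, 0)
  )
}

#' Simulate survey microdata reproducing a target weekly series
#'
#' For every week of the target series, draws `respondents_per_week` records
#' with positive log-normal weights, a stratum label, and a 0-30 days
#' response (or special code): the probability that a respondent's days
#' response meets the cutoff equals the target prevalence plus the centred
#' stratum shift, so the expected survey-weighted weekly exceedance equals
#' the target value.  Below-cutoff responses are zero-inflated; zero days are
#' recorded with code 88 (none), and with probability `missing_rate` the
#' response is replaced by 77 (don't know) or 99 (refused).  Auxiliary
#' stratification attributes (age group, sex, income band, physical-health
#' days, raising children) are drawn independently with realistic shares.
#'
#' @param msc a [microdata_scenario()].
#' @param target a `weekly_series` giving the per-week prevalence (pp).
#' @return a tibble of survey records with columns `record_id`,
#'   `interview_date`, `ment14d_days`, `weight`, `age_group`, `sex`,
#'   `race_ethnicity`, `income_band`, `phys_days`, `raising_children`.
#' @export
simulate_microdata <- function(msc, target) {
  stopifnot(inherits(msc, "microdata_scenario"),
            inherits(target, "weekly_series"))
  set.seed(msc$seed)
  n_weeks <- nrow(target)
  m <- msc$respondents_per_week
  n <- n_weeks * m
  week <- rep(target$week, each = m)
  p_base <- rep(target$prevalence_pct, each = m) / 100

  mix <- msc$strata_mix
  stratum_idx <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$share)
  p <- pmin(pmax(p_base + mix$shift[stratum_idx] / 100, 0), 1)

  exceed <- stats::rbinom(n, 1L, p)
  days <- integer(n)
  hi <- exceed == 1L
  days[hi] <- sample(msc$cutoff:30L, sum(hi), replace = TRUE)
  lo <- !hi
  zero <- lo & (stats::runif(n) < msc$zero_share)
  days[zero] <- 88L  # BRFSS dialect: 88 = none (zero days)
  rest <- lo & !zero
  if (msc$cutoff > 1L) {
    days[rest] <- sample(1:(msc$cutoff - 1L), sum(rest), replace = TRUE)
  } else {
    days[rest] <- 88L
  }
  miss <- stats::runif(n) < msc$missing_rate
  days[miss] <- sample(c(77L, 99L), sum(miss), replace = TRUE)

  monday <- attr(target, "start_date") + 7L * (week - 1L)
  tibble::tibble(
    record_id = seq_len(n),
    interview_date = monday + sample(0:6, n, replace = TRUE),
    ment14d_days = days,
    weight = stats::rlnorm(n, msc$weight_meanlog, msc$weight_sdlog),
    age_group = sample(c("18-64", "65+"), n, TRUE, prob = c(0.76, 0.24)),
    sex = sample(c("female", "male"), n, TRUE, prob = c(0.512, 0.488)),
    race_ethnicity = mix$label[stratum_idx],
    income_band = sample(c("<25k", "25-50k", ">=50k", "refused"), n, TRUE,
                         prob = c(0.16, 0.19, 0.44, 0.21)),
    phys_days = sample(0:30, n, TRUE,
                       prob = c(0.6, rep(0.28 / 13, 13), rep(0.12 / 17, 17))),
    raising_children = sample(c("yes", "no", "refused"), n, TRUE,
                              prob = c(0.33, 0.64, 0.03))
  )
}

#' Write a weekly series / microdata table to CSV
#'
#' @param x a `weekly_series` or microdata tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read a weekly prevalence series from CSV
#'
#' Expects columns `week_start_date` and `prevalence_pct` (optionally
#' `n_effective`); the weekly grid must be gap-free.
#'
#' @param path CSV file path.
#' @return a `weekly_series`.
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("week_start_date", "prevalence_pct")
  if (!all(req %in% names(df))) {
    stop("series CSV needs columns: ", paste(req, collapse = ", "))
  }
  ws <- as.Date(df$week_start_date)
  if (nrow(df) > 1 && any(diff(as.numeric(ws)) != 7)) {
    stop("weekly calendar has gaps or is unordered; expected consecutive Mondays")
  }
  new_weekly_series(df$prevalence_pct, start_date = ws[1],
                    n_effective = if ("n_effective" %in% names(df))
                      df$n_effective else NA_real_)
}
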