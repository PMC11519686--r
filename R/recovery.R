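#' Monte-Carlo parameter recovery, coverage and type-I-error study
#'
#' Repeatedly simulates weekly series from a scenario, re-estimates the ITS
#' model on each replicate, and summarises how well the injected truths are
#' recovered: per design column the mean estimate, bias, empirical SD, RMSE,
#' empirical coverage of the nominal 95% confidence intervals, and the
#' 2-tailed p < 0.05 rejection rate (the type-I error when the injected
#' effect is zero).  The trend constant is summarised the same way against
#' the scenario's drift.
#'
#' Replicate r uses seed `scenario$seed + r`, so the whole study is
#' reproducible from one seed.  Replicates whose fit fails are recorded and
#' skipped, never fatal.
#'
#' @param sc a [scenario()]; its `effects` are the injected truths.
#' @param reps number of replicates (>= 2).
#' @param order ARIMA order to fit (defaults to the order implied by the
#'   scenario: `c(0, d, 1)` for MA noise, adding an AR term when
#'   `ar_phi != 0`).
#' @param include_trend,include_mean passed to [fit_its()].
#' @param method passed to [fit_its()].
#' @return a `recovery_study` list with `summary` (a tibble, one row per
#'   coefficient), `n_failed`, `reps`, and the per-replicate `estimates` /
#'   `covered` / `rejected` matrices.
#' @export
#' @examples
#' sc <- scenario(n_weeks = 120, effects = c("4" = -1), seed = 7)
#' rs <- recovery_study(sc, reps = 20)
#' rs$summary
recovery_study <- function(sc, reps = 500L, order = NULL,
                           include_trend = NULL, include_mean = TRUE,
                           method = "CSS-ML") {
  stopifnot(inherits(sc, "scenario"), reps >= 2L)
  if (is.null(order)) {
    order <- c(if (sc$ar_phi != 0) 1L else 0L, sc$d,
               if (sc$ma_theta != 0) 1L else 0L)
  }
  if (is.null(include_trend)) include_trend <- sc$d >= 1L || sc$drift != 0

  X <- build_design_matrix(sc$events, sc$n_weeks, sc$start_date,
                           sc$lag_weeks, sc$pandemic_coding)
  truth <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (length(sc$effects)) {
    truth[paste0("event_", names(sc$effects))] <- unname(sc$effects)
  }
  if (include_trend) truth <- c(trend = sc$drift, truth)
  terms <- names(truth)

  est <- cov <- rej <- matrix(NA_real_, nrow = reps, ncol = length(terms),
                              dimnames = list(NULL, terms))
  n_failed <- 0L
  for (r in seq_len(reps)) {
    sc_r <- sc
    sc_r$seed <- sc$seed + r
    z <- simulate_weekly_series(sc_r)
    f <- tryCatch(
      fit_its(z, X, order = order, include_trend = include_trend,
              include_mean = include_mean, method = method),
      error = function(e) NULL
    )
    if (is.null(f)) {
      n_failed <- n_failed + 1L
      next
    }
    co <- f$coefficients
    idx <- match(terms, co$term)
    est[r, ] <- co$estimate[idx]
    cov[r, ] <- as.numeric(co$ci_lower[idx] <= truth & truth <= co$ci_upper[idx])
    rej[r, ] <- as.numeric(co$p_value[idx] < 0.05)
  }

  ok <- stats::complete.cases(est)
  summarise_term <- function(j) {
    e <- est[ok, j]
    tr <- unname(truth[j])
    tibble::tibble(
      term = terms[j], truth = tr,
      mean_estimate = mean(e), bias = mean(e) - tr,
      sd = stats::sd(e), mc_se = stats::sd(e) / sqrt(length(e)),
      rmse = sqrt(mean((e - tr)^2)),
      coverage = mean(cov[ok, j]), rejection_rate = mean(rej[ok, j])
    )
  }
  summary <- dplyr::bind_rows(lapply(seq_along(terms), summarise_term))
  structure(list(
    summary = summary, reps = as.integer(reps), n_failed = n_failed,
    failure_share = n_failed / reps, order = order,
    estimates = est, covered = cov, rejected = rej, scenario = sc
  ), class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat("<recovery_study> ", x$reps, " replicates, ARIMA(",
      paste(x$order, collapse = ","), "); ", x$n_failed, " failed fit(s)\n",
      sep = "")
  print(as.data.frame(x$summary), digits = 3, row.names = FALSE)
  invisible(x)
}
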