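#' Difference a series
#'
#' @param x numeric vector.
#' @param d non-negative integer order of differencing.
#' @return numeric vector of length `length(x) - d`.
#' @export
#' @examples
#' difference_series(c(1, 3, 6), 1)    # 2 3
#' difference_series(c(1, 3, 6, 10), 2)  # 1 1
difference_series <- function(x, d) {
  stopifnot(d >= 0L, length(x) > d)
  if (d == 0L) return(x)
  diff(x, differences = d)
}

series_values <- function(series) {
  if (inherits(series, "weekly_series")) series$prevalence_pct
  else as.numeric(series)
}

#' Fit a multi-intervention ITS by regression with ARIMA errors
#'
#' Maximum-likelihood fit of
#' \deqn{z_t = c \cdot t + \sum_k \omega_k I_k(t) + \eta_t, \qquad
#'       \eta_t \sim ARIMA(p, d, q),}
#' estimated via [stats::arima()] with the trend and intervention columns as
#' external regressors.  With `d = 1` the linear trend in levels is the
#' constant (drift) of the differenced equation, so the reported trend
#' coefficient is the weekly drift in percentage points per week.  With
#' `d = 0` an intercept is included.  95% confidence intervals are normal
#' approximations (estimate +/- 1.96 SE); p-values are 2-tailed normal.
#' Standard errors carry a finite-sample degrees-of-freedom correction,
#' `sqrt(n_eff / (n_eff - k))` with `k` the number of estimated ARMA and
#' regression coefficients, the analogue of dividing the innovation variance
#' by `n - k` rather than `n`.
#'
#' @param series a `weekly_series` or numeric vector.
#' @param design an `its_design` matrix (or any numeric matrix aligned to the
#'   series); `NULL` fits trend + noise only.
#' @param order ARIMA order `c(p, d, q)` with `p, q <= 3`, `d <= 2`.
#' @param include_trend include the linear trend regressor (slope model)?
#' @param include_mean include an intercept when `d = 0`? (ignored for
#'   `d >= 1`, where differencing removes it.)
#' @param method estimation method for [stats::arima()].
#' @param ljung_box_lags lags for the residual Ljung-Box test.
#' @return an `its_fit` with the coefficient table (`estimate`, `se`,
#'   `ci_lower`, `ci_upper`, `p_value` per term), `order`, `loglik`, `bic`,
#'   `sigma2`, `ljung_box` (Q, df, p), `stationary_r2`, `residuals`, `n`.
#' @export
#' @examples
#' sc <- scenario(effects = c("4" = -0.93), seed = 42)
#' z <- simulate_weekly_series(sc)
#' D <- build_design_matrix(n_weeks = nrow(z))
#' fit <- fit_its(z, D, order = c(0, 1, 1))
#' fit
fit_its <- function(series, design = NULL, order = c(0, 1, 1),
                    include_trend = TRUE, include_mean = TRUE,
                    method = c("CSS-ML", "ML", "CSS"),
                    ljung_box_lags = 18L) {
  method <- match.arg(method)
  stopifnot(length(order) == 3L, all(order >= 0L),
            order[1] <= 3L, order[3] <= 3L, order[2] <= 2L)
  z <- series_values(series)
  if (anyNA(z)) {
    stop("series contains missing weeks; interpolate or restrict the window first")
  }
  n <- length(z)
  xreg <- NULL
  if (include_trend) xreg <- cbind(trend = seq_len(n))
  if (!is.null(design)) {
    X <- unclass(design)[seq_len(NROW(design)), , drop = FALSE]
    storage.mode(X) <- "double"
    if (NROW(X) != n) stop("design matrix and series lengths differ")
    keep <- colSums(abs(X)) > 0
    if (any(!keep)) {
      message("dropping all-zero design column(s): ",
              paste(colnames(X)[!keep], collapse = ", "))
      X <- X[, keep, drop = FALSE]
    }
    xreg <- cbind(xreg, X)
  }
  if (!is.null(xreg)) {
    qrx <- qr(cbind(`(const)` = 1, xreg))
    if (qrx$rank < ncol(xreg) + 1L) {
      dep <- colnames(cbind(`(const)` = 1, xreg))[-seq_len(qrx$rank)]
      stop("collinear design columns: ",
           paste(utils::tail(colnames(xreg), ncol(xreg) + 1L - qrx$rank),
                 collapse = ", "))
    }
  }

  # degenerate corner: a pure-regression model (p = q = d = 0) whose fit is
  # exact has zero innovation variance, where the ARMA likelihood machinery
  # is singular; the least-squares solution *is* the MLE there
  if (order[1] == 0L && order[2] == 0L && order[3] == 0L) {
    M <- if (include_mean) cbind(intercept = rep(1, n), xreg) else xreg
    if (!is.null(M)) {
      beta <- qr.solve(M, z)
      rss <- sum((z - as.numeric(M %*% beta))^2)
      if (rss <= 1e-10 * max(1, sum(z^2))) {
        coefs <- tibble::tibble(
          term = colnames(M), estimate = unname(beta), se = 0,
          ci_lower = unname(beta), ci_upper = unname(beta), p_value = NA_real_)
        res <- z - as.numeric(M %*% beta)
        return(structure(list(
          order = order, coefficients = coefs, loglik = NA_real_,
          bic = NA_real_, aic = NA_real_, sigma2 = rss / n, n = n, n_eff = n,
          n_par = length(beta) + 1L,
          ljung_box = list(statistic = NA_real_, df = NA_integer_,
                           p_value = NA_real_, lags = NA_integer_),
          stationary_r2 = stationary_r2_values(res, z, 0L), residuals = res,
          include_trend = include_trend, method = "exact", arima = NULL
        ), class = "its_fit"))
      }
    }
  }

  fit <- tryCatch(
    stats::arima(z, order = order, xreg = xreg,
                 include.mean = (order[2] == 0L && include_mean),
                 method = method,
                 optim.control = list(maxit = 500, reltol = 1e-8)),
    error = function(e) stop("ARIMA estimation failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (!is.null(fit$code) && fit$code != 0) {
    stop("ARIMA optimizer did not converge (optim code ", fit$code, ")")
  }

  est <- fit$coef
  vc <- fit$var.coef
  se <- rep(NA_real_, length(est))
  if (length(est)) {
    se[match(rownames(vc), names(est))] <- sqrt(pmax(diag(vc), 0))
  }
  # finite-sample correction: the ML innovation variance divides by n_eff,
  # the unbiased analogue by n_eff - k; inflate SEs accordingly (k = all
  # estimated ARMA + regression coefficients)
  n_eff <- n - order[2]
  if (n_eff > length(est) + 1L) {
    se <- se * sqrt(n_eff / (n_eff - length(est)))
  }
  zstat <- est / se
  coefs <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    ci_lower = unname(est - 1.96 * se),
    ci_upper = unname(est + 1.96 * se),
    p_value = unname(2 * stats::pnorm(-abs(zstat)))
  )

  # ARMA terms + regression terms (trend, intercept, interventions) are all
  # in est; + 1 for the innovation variance
  k <- length(est) + 1L
  bic <- -2 * fit$loglik + k * log(n_eff)

  res <- as.numeric(stats::residuals(fit))
  m <- max(1L, min(ljung_box_lags, length(res) - 1L))
  lb <- tryCatch(
    ljung_box_q(res, max_lag = m, fitdf = order[1] + order[3]),
    error = function(e) list(statistic = NA_real_, df = NA_integer_,
                             p_value = NA_real_, lags = m)
  )
  sr2 <- stationary_r2_values(res, z, order[2])

  structure(list(
    order = order, coefficients = coefs, loglik = fit$loglik, bic = bic,
    aic = fit$aic, sigma2 = fit$sigma2, n = n, n_eff = n_eff, n_par = k,
    ljung_box = lb, stationary_r2 = sr2, residuals = res,
    include_trend = include_trend, method = method, arima = fit
  ), class = "its_fit")
}

#' @export
print.its_fit <- function(x, digits = 3, ...) {
  cat("<its_fit> ARIMA(", paste(x$order, collapse = ","), ") with ",
      nrow(x$coefficients), " coefficient(s), n = ", x$n, "\n", sep = "")
  cat(sprintf("  BIC %.2f | Ljung-Box Q(%d) %.2f (p = %.3f) | Stationary R2 %.2f\n",
              x$bic, x$ljung_box$lags,
              x$ljung_box$statistic, x$ljung_box$p_value, x$stationary_r2))
  df <- as.data.frame(x$coefficients)
  df$` ` <- ifelse(!is.na(df$p_value) & df$p_value < 0.05, "*", "")
  print(format(df, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Ljung-Box portmanteau test
#'
#' \eqn{Q = n(n+2) \sum_{k=1}^{m} \hat\rho_k^2 / (n-k)}, referred to a
#' chi-square with `m - fitdf` degrees of freedom (floored at 1), where
#' `fitdf` is the number of fitted ARMA parameters.  A non-significant Q
#' indicates residuals compatible with white noise.
#'
#' @param residuals numeric residual vector.
#' @param max_lag number of autocorrelation lags `m`.
#' @param fitdf degrees of freedom consumed by the fitted ARMA terms.
#' @return list with `statistic`, `df`, `p_value`, `lags`.
#' @export
ljung_box_q <- function(residuals, max_lag = 18L, fitdf = 0L) {
  n <- length(residuals)
  stopifnot(max_lag >= 1L, n > max_lag)
  if (stats::sd(residuals) == 0) {
    stop("residuals are constant: autocorrelation undefined")
  }
  rho <- as.numeric(stats::acf(residuals, lag.max = max_lag,
                               plot = FALSE, demean = TRUE)$acf)[-1]
  q <- n * (n + 2) * sum(rho^2 / (n - seq_len(max_lag)))
  df <- max(max_lag - fitdf, 1L)
  list(statistic = q, df = df,
       p_value = stats::pchisq(q, df, lower.tail = FALSE),
       lags = as.integer(max_lag))
}

#' Bayesian information criterion of an ITS fit
#'
#' \eqn{BIC = -2 \log L + k \log(n_{eff})} with `k` counting the ARMA terms,
#' trend/intercept, intervention coefficients and the innovation variance,
#' and `n_eff = n - d`.
#'
#' @param fit an `its_fit`, or a log-likelihood value.
#' @param k,n parameter count and effective sample size (required when `fit`
#'   is a bare log-likelihood).
#' @return the BIC value.
#' @export
#' @examples
#' information_criteria(-100, k = 3, n = 100)  # 200 + 3 log(100)
information_criteria <- function(fit, k = NULL, n = NULL) {
  if (inherits(fit, "its_fit")) {
    return(-2 * fit$loglik + fit$n_par * log(fit$n_eff))
  }
  stopifnot(is.numeric(fit), !is.null(k), !is.null(n))
  -2 * fit + k * log(n)
}

stationary_r2_values <- function(residuals, z, d) {
  dz <- difference_series(z, d)
  denom <- sum((dz - mean(dz))^2)
  if (denom == 0) stop("differenced series has zero variance")
  res <- utils::tail(residuals, length(dz))
  1 - sum(res^2) / denom
}

#' Stationary R-squared
#'
#' Proportion of the variance of the d-differenced series explained by the
#' model relative to its mean: \eqn{R^2_s = 1 - \sum \hat e_t^2 /
#' \sum (\Delta^d z_t - \overline{\Delta^d z})^2}.  At most 1; negative when
#' the model does worse than the mean of the differenced series.
#'
#' @param fit an `its_fit`.
#' @param series the series the fit was estimated on (optional; residual and
#'   order information is taken from the fit).
#' @return the Stationary R-squared.
#' @export
stationary_r2 <- function(fit, series = NULL) {
  stopifnot(inherits(fit, "its_fit"))
  fit$stationary_r2
}

#' Residual ACF and PACF with 95% bands
#'
#' Sample autocorrelations and partial autocorrelations (Durbin-Levinson, as
#' computed by [stats::pacf()]) with the usual white-noise bands
#' \eqn{\pm 1.96/\sqrt{n}}.
#'
#' @param x numeric series (typically residuals).
#' @param max_lag maximum lag.
#' @return tibble with `lag`, `acf`, `pacf`, and attribute `band`.
#' @export
acf_pacf <- function(x, max_lag = 18L) {
  n <- length(x)
  stopifnot(n > max_lag, max_lag >= 1L)
  if (stats::sd(x) == 0) stop("zero-variance input: autocorrelation undefined")
  a <- as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE)$acf)[-1]
  p <- as.numeric(stats::pacf(x, lag.max = max_lag, plot = FALSE)$acf)
  out <- tibble::tibble(lag = seq_len(max_lag), acf = a, pacf = p)
  attr(out, "band") <- 1.96 / sqrt(n)
  out
}

#' Select an ARIMA order by BIC among diagnostically adequate fits
#'
#' Fits every candidate order and returns the converged candidate with the
#' lowest BIC among those whose residual Ljung-Box test is non-significant
#' (p > 0.05).  If no candidate passes Ljung-Box, the overall minimum-BIC
#' candidate is returned with a warning.  Ties in BIC break toward the
#' smaller `p + q`.
#'
#' @inheritParams fit_its
#' @param grid list of `c(p, d, q)` candidate orders.
#' @return the selected `its_fit`, with a `candidates` attribute holding the
#'   per-order table (order, converged, BIC, Ljung-Box p).
#' @export
select_order <- function(series, design = NULL,
                         grid = list(c(0, 1, 1), c(1, 0, 0), c(0, 0, 1),
                                     c(1, 0, 1), c(1, 1, 1), c(0, 0, 0)),
                         include_trend = TRUE, ...) {
  stopifnot(length(grid) >= 1L)
  fits <- vector("list", length(grid))
  tab <- tibble::tibble(
    p = vapply(grid, `[`, 0, 1), d = vapply(grid, `[`, 0, 2),
    q = vapply(grid, `[`, 0, 3),
    converged = FALSE, bic = NA_real_, ljung_box_p = NA_real_
  )
  for (i in seq_along(grid)) {
    f <- tryCatch(fit_its(series, design, order = grid[[i]],
                          include_trend = include_trend, ...),
                  error = function(e) NULL)
    fits[[i]] <- f
    if (!is.null(f)) {
      tab$converged[i] <- TRUE
      tab$bic[i] <- f$bic
      tab$ljung_box_p[i] <- f$ljung_box$p_value
    }
  }
  if (!any(tab$converged)) stop("no candidate order converged")
  ok <- which(tab$converged & !is.na(tab$ljung_box_p) & tab$ljung_box_p > 0.05)
  flagged <- FALSE
  if (!length(ok)) {
    warning("no candidate passes the Ljung-Box test; returning minimum-BIC fit")
    ok <- which(tab$converged)
    flagged <- TRUE
  }
  ord <- ok[order(tab$bic[ok], tab$p[ok] + tab$q[ok])]
  best <- fits[[ord[1]]]
  attr(best, "candidates") <- tab
  attr(best, "ljung_box_flagged") <- flagged
  best
}
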