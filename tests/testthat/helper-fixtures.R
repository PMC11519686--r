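# Shared fixture builders; everything is generated in code, no stored data.

# Two-event calendar with a known geometry: one pandemic step, two rollout
# phases (the second supersedes the first).
toy_calendar <- function() {
  tibble::tibble(
    id = 1:3,
    date = as.Date(c("2019-02-04", "2019-03-11", "2019-05-20")),
    label = c("shock", "phase A", "phase B"),
    category = c("pandemic_event", "vaccine_rollout", "vaccine_rollout")
  )
}

# One-week microdata table with explicit outcomes and weights.
toy_records <- function(days, weights, date = as.Date("2019-01-01")) {
  tibble::tibble(
    record_id = seq_along(days),
    interview_date = rep(date, length(days)),
    ment14d_days = days,
    weight = weights
  )
}

# Independent brute-force autocorrelation (same convention as stats::acf:
# denominator n, mean-corrected).
brute_acf <- function(x, max_lag) {
  n <- length(x)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  vapply(seq_len(max_lag), function(k) {
    sum(xc[(k + 1):n] * xc[1:(n - k)]) / denom
  }, 0)
}

# Durbin-Levinson partial autocorrelations from brute-force ACF.
brute_pacf <- function(x, max_lag) {
  rho <- brute_acf(x, max_lag)
  pacf_out <- numeric(max_lag)
  phi_prev <- numeric(0)
  for (k in seq_len(max_lag)) {
    if (k == 1) {
      phi_k <- rho[1]
    } else {
      num <- rho[k] - sum(phi_prev * rho[(k - 1):1])
      den <- 1 - sum(phi_prev * rho[1:(k - 1)])
      phi_k <- num / den
    }
    pacf_out[k] <- phi_k
    phi_prev <- if (k == 1) phi_k else c(phi_prev - phi_k * rev(phi_prev), phi_k)
  }
  pacf_out
}

# Brute-force Ljung-Box Q from its definition.
brute_ljung_box <- function(x, m) {
  n <- length(x)
  rho <- brute_acf(x, m)
  n * (n + 2) * sum(rho^2 / (n - seq_len(m)))
}
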