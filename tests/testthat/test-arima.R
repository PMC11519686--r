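test_that("differencing follows its definition", {
  expect_equal(difference_series(c(1, 3, 6), 1), c(2, 3))
  expect_equal(difference_series(c(1, 3, 6, 10), 2), c(1, 1))
  x <- rnorm(5)
  expect_equal(difference_series(x, 0), x)
  expect_error(difference_series(c(1, 2), 2))
})

test_that("a noise-free step is recovered exactly by the degenerate model", {
  z <- c(rep(5, 13), rep(7, 17))
  X <- cbind(step = as.numeric(seq_len(30) >= 14))
  f <- suppressWarnings(fit_its(z, X, order = c(0, 0, 0),
                                include_trend = FALSE))
  co <- setNames(f$coefficients$estimate, f$coefficients$term)
  expect_equal(unname(co["intercept"]), 5, tolerance = 1e-8)
  expect_equal(unname(co["step"]), 2, tolerance = 1e-8)
})

test_that("order (0,0,0) equals the closed-form least-squares solution", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 40
    X <- cbind(a = rnorm(n), b = as.numeric(seq_len(n) >= 20))
    y <- 1 + 0.03 * seq_len(n) + 0.5 * X[, "a"] - 1.1 * X[, "b"] + rnorm(n)
    f <- fit_its(y, X, order = c(0, 0, 0), include_trend = TRUE)
    ols <- coef(lm(y ~ seq_len(n) + X))
    co <- setNames(f$coefficients$estimate, f$coefficients$term)
    expect_equal(unname(co["intercept"]), unname(ols[1]), tolerance = 1e-8)
    expect_equal(unname(co["trend"]), unname(ols[2]), tolerance = 1e-8)
    expect_equal(unname(co["a"]), unname(ols[3]), tolerance = 1e-8)
    expect_equal(unname(co["b"]), unname(ols[4]), tolerance = 1e-8)
  }
})

test_that("fit_its surfaces degenerate designs and missing weeks", {
  z <- rnorm(30)
  X <- cbind(a = rep(1, 30), b = rep(1, 30))
  expect_error(fit_its(z, X, order = c(0, 0, 0)), "collinear")
  z[5] <- NA
  expect_error(fit_its(z, NULL, order = c(0, 0, 0)), "missing weeks")
})

test_that("Ljung-Box Q matches the brute-force definition", {
  # alternating residuals: rho1 = -0.875, Q = 8.75
  x <- rep(c(1, -1), 4)
  lb <- ljung_box_q(x, max_lag = 1)
  expect_equal(lb$statistic, 8.75, tolerance = 1e-12)
  expect_equal(lb$df, 1L)
  set.seed(3)
  for (rep in 1:10) {
    x <- rnorm(60)
    m <- sample(3:12, 1)
    lb <- ljung_box_q(x, max_lag = m, fitdf = 2)
    expect_equal(lb$statistic, brute_ljung_box(x, m), tolerance = 1e-8)
    expect_equal(lb$df, max(m - 2, 1))
    expect_equal(lb$p_value, pchisq(lb$statistic, lb$df, lower.tail = FALSE))
  }
  expect_error(ljung_box_q(rep(1, 20), 3), "constant")
})

test_that("Ljung-Box p-values are calibrated under white noise", {
  set.seed(99)
  p <- replicate(400, ljung_box_q(rnorm(120), max_lag = 10)$p_value)
  # rejection at 5% close to nominal (binomial 3-SE band)
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("information criteria follow the BIC formula", {
  expect_equal(information_criteria(0, k = 0, n = 10), 0)
  expect_equal(information_criteria(-100, k = 3, n = 100),
               200 + 3 * log(100))
  expect_lt(information_criteria(-50, k = 2, n = 80),
            information_criteria(-50, k = 3, n = 80))
})

test_that("fit diagnostics agree with independent recomputation", {
  set.seed(21)
  sc <- scenario(n_weeks = 120, events = toy_calendar(),
                 effects = c("2" = -1), seed = 31)
  z <- simulate_weekly_series(sc)
  D <- build_design_matrix(toy_calendar(), 120)
  f <- fit_its(z, D, order = c(0, 1, 1))
  # BIC from first principles: every estimated coefficient + sigma2
  expect_equal(f$bic,
               -2 * f$loglik + (nrow(f$coefficients) + 1) * log(f$n - 1),
               tolerance = 1e-8)
  # Ljung-Box against the brute-force oracle
  expect_equal(f$ljung_box$statistic, brute_ljung_box(f$residuals, 18),
               tolerance = 1e-8)
  # Stationary R2 against direct evaluation of both sums
  dz <- diff(z$prevalence_pct)
  res <- tail(f$residuals, length(dz))
  expect_equal(f$stationary_r2, 1 - sum(res^2) / sum((dz - mean(dz))^2),
               tolerance = 1e-8)
  # perfect fit / mean-only baselines
  expect_equal(stationary_r2(f), f$stationary_r2)
})

test_that("stationary R2 is 1 for a perfect fit and 0 for the mean model", {
  z <- rnorm(50)
  expect_equal(itsprev:::stationary_r2_values(rep(0, 50), z, 0), 1)
  expect_equal(itsprev:::stationary_r2_values(z - mean(z), z, 0), 0)
})

test_that("ACF/PACF match brute-force and closed-form references", {
  set.seed(8)
  x <- rnorm(300)
  ap <- acf_pacf(x, max_lag = 12)
  expect_equal(ap$acf, brute_acf(x, 12), tolerance = 1e-8)
  expect_equal(ap$pacf, brute_pacf(x, 12), tolerance = 1e-6)
  expect_equal(ap$acf[1], ap$pacf[1], tolerance = 1e-10)
  expect_equal(attr(ap, "band"), 1.96 / sqrt(300))
  # AR(1) autocorrelation decays as phi^k
  sc <- scenario(n_weeks = 20000, baseline = 0, drift = 0, d = 0,
                 ar_phi = 0.6, ma_theta = 0, innovation_sd = 1,
                 events = toy_calendar()[0, ], seed = 17)
  z <- simulate_weekly_series(sc)$prevalence_pct
  a <- acf_pacf(z, max_lag = 5)$acf
  expect_equal(a, 0.6^(1:5), tolerance = 0.03)
  expect_error(acf_pacf(rep(2, 50), 5), "zero-variance")
})

test_that("scale equivariance: scaling the series scales all coefficients", {
  sc <- scenario(n_weeks = 120, events = toy_calendar(), effects = c("2" = -1),
                 seed = 5)
  z <- simulate_weekly_series(sc)
  D <- build_design_matrix(toy_calendar(), 120)
  f1 <- fit_its(z, D, order = c(0, 1, 1))
  z2 <- z; z2$prevalence_pct <- 10 * z$prevalence_pct
  f2 <- fit_its(z2, D, order = c(0, 1, 1))
  reg <- setdiff(f1$coefficients$term, c("ma1", "ar1"))
  co1 <- setNames(f1$coefficients$estimate, f1$coefficients$term)[reg]
  co2 <- setNames(f2$coefficients$estimate, f2$coefficients$term)[reg]
  expect_equal(unname(co2), unname(10 * co1), tolerance = 1e-3)
})

test_that("order selection prefers the generating order and breaks ties", {
  # single-candidate grid returns that order
  z <- simulate_weekly_series(scenario(n_weeks = 100,
                                       events = toy_calendar()[0, ], seed = 2))
  f <- select_order(z, NULL, grid = list(c(0, 1, 1)))
  expect_equal(f$order, c(0, 1, 1))
  # ARIMA(0,1,1) data: (0,1,1) beats white-noise-in-levels and AR(1) usually
  wins <- 0L
  for (r in 1:25) {
    sc <- scenario(n_weeks = 217, events = toy_calendar()[0, ], seed = 300 + r)
    z <- simulate_weekly_series(sc)
    sel <- suppressWarnings(
      select_order(z, NULL, grid = list(c(0, 0, 0), c(0, 1, 1), c(1, 0, 0))))
    if (identical(sel$order, c(0, 1, 1))) wins <- wins + 1L
  }
  expect_gt(wins, 12L)
})

test_that("recovery harness summarises bias, coverage and rejection", {
  sc <- scenario(n_weeks = 120, events = toy_calendar(), effects = c("2" = -2),
                 innovation_sd = 0.5, seed = 100)
  rs <- recovery_study(sc, reps = 30)
  expect_equal(rs$reps, 30L)
  expect_equal(rs$n_failed, 0L)
  s <- rs$summary[rs$summary$term == "event_2", ]
  expect_equal(s$truth, -2)
  expect_lt(abs(s$bias), 4 * s$mc_se)
  expect_true(s$coverage > 0.8)
  # a huge effect relative to noise is detected in every replicate (power ~ 1)
  sc2 <- scenario(n_weeks = 120, events = toy_calendar(),
                  effects = c("2" = -8), innovation_sd = 0.3, seed = 200)
  rs2 <- recovery_study(sc2, reps = 15)
  expect_equal(rs2$summary$rejection_rate[rs2$summary$term == "event_2"], 1)
})
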