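test_that("softplus is exact, overflow-safe and near-identity for large x", {
  expect_equal(softplus(0), log(2))
  expect_equal(softplus(50), 50, tolerance = 1e-12)
  expect_equal(softplus(-20), 2.0611536e-9, tolerance = 1e-8)
  x <- seq(-40, 40, by = 0.5)
  expect_true(all(softplus(x) > 0))
  expect_true(all(diff(softplus(x)) > 0))
  expect_true(all(abs(softplus(x) - pmax(x, 0)) <= log(2) + 1e-12))
})

test_that("the Gaussian NLL evaluates exactly and is minimised correctly", {
  expect_equal(gaussian_nll(0, 0, 1), 0.5 * log(2 * pi))
  expect_equal(gaussian_nll(3.7, 3.7, sqrt(1 / (2 * pi))), 0)
  expect_error(gaussian_nll(0, 0, 0), "strictly positive")
  # over sigma^2, the loss is minimised at (y - mu)^2
  y <- 1.3; mu <- 0.4
  f <- function(s2) gaussian_nll(y, mu, sqrt(s2))
  opt <- optimize(f, c(1e-4, 10))$minimum
  expect_equal(opt, (y - mu)^2, tolerance = 1e-4)
  # finite-difference gradients match analytic ones
  for (pars in list(c(0.5, 0.2, 0.8), c(-1, 1, 2), c(3, 2.5, 0.3))) {
    y <- pars[1]; mu <- pars[2]; sig <- pars[3]
    h <- 1e-6
    d_mu <- (gaussian_nll(y, mu + h, sig) - gaussian_nll(y, mu - h, sig)) / (2 * h)
    d_sig <- (gaussian_nll(y, mu, sig + h) - gaussian_nll(y, mu, sig - h)) / (2 * h)
    expect_equal(d_mu, -(y - mu) / sig^2, tolerance = 1e-5)
    expect_equal(d_sig, 1 / sig - (y - mu)^2 / sig^3, tolerance = 1e-5)
  }
})

test_that("rmse follows its definition", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_error(rmse(1:3, 1:2), "lengths differ")
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(rmse(x, y)^2, mean((x - y)^2))
})

test_that("window construction counts, aligns and splits chronologically", {
  z <- simulate_weekly_series(scenario(n_weeks = 217, seed = 1))
  D <- build_design_matrix(n_weeks = 217)
  ds <- make_windows(z, D, lstm_config(window = 12))
  expect_equal(dim(ds$x), c(205, 12, 12))   # 217 - 12 samples, 1 + 11 features
  expect_equal(length(ds$y), 205)
  # boundary: n = w + 1 gives exactly one sample
  z13 <- suppressWarnings(simulate_weekly_series(scenario(n_weeks = 13, seed = 1)))
  expect_error(make_windows(z13, NULL, lstm_config(window = 12)),
               "empty")  # 1 sample cannot be split
  ds1 <- make_windows(z13$prevalence_pct[1:13], NULL,
                      lstm_config(window = 6, train_fraction = 0.7))
  expect_equal(dim(ds1$x)[1], 7)
  # intervention features equal the design rows of the window weeks
  i <- 100
  expect_equal(ds$x[i, , 2:12],
               matrix(as.double(unclass(D)[i:(i + 11), ]), 12, 11,
                      dimnames = NULL),
               ignore_attr = TRUE)
  # no target leakage: the window stops one week before the target
  expect_equal(ds$target_week[i], i + 12)
  # train windows strictly precede test windows
  expect_equal(ds$split_index, floor(0.8 * 205))
  # too-short series fails fast
  expect_error(make_windows(z$prevalence_pct[1:10], NULL, lstm_config()),
               "too short")
})

test_that("backpropagated gradients match finite differences", {
  set.seed(4)
  B <- 5; w <- 4; nf <- 3; H <- 3
  x <- array(rnorm(B * w * nf), c(B, w, nf))
  y <- rnorm(B)
  cfg <- lstm_config(window = w, hidden_units = H, layers = 2, seed = 11)
  params <- itsprev:::lstm_init_params(nf, cfg)
  fw <- itsprev:::lstm_forward(params, x, 1e-6, keep_cache = TRUE)
  bw <- itsprev:::lstm_backward(params, fw, x, y, 1e-6)
  loss_at <- function(p) {
    f <- itsprev:::lstm_forward(p, x, 1e-6)
    mean(gaussian_nll(y, f$mu, sqrt(f$sigma2)))
  }
  eps <- 1e-6
  # spot-check a deterministic sample of coordinates in every block
  for (l in 1:2) {
    for (nmj in c("Wx", "Wh", "b")) {
      v <- params$layers[[l]][[nmj]]
      g <- bw$grads$layers[[l]][[nmj]]
      for (j in unique(pmin(length(v), c(1, 4, length(v))))) {
        p1 <- params; p1$layers[[l]][[nmj]][j] <- v[j] + eps
        p2 <- params; p2$layers[[l]][[nmj]][j] <- v[j] - eps
        num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
        expect_equal(num, g[j], tolerance = 1e-5)
      }
    }
  }
  for (nmj in c("Wmu", "Ws")) {
    for (j in seq_len(H)) {
      p1 <- params; p1[[nmj]][j] <- params[[nmj]][j] + eps
      p2 <- params; p2[[nmj]][j] <- params[[nmj]][j] - eps
      num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
      expect_equal(num, bw$grads[[nmj]][j], tolerance = 1e-5)
    }
  }
  for (nmj in c("bmu", "bs")) {
    p1 <- params; p1[[nmj]] <- params[[nmj]] + eps
    p2 <- params; p2[[nmj]] <- params[[nmj]] - eps
    num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
    expect_equal(num, bw$grads[[nmj]], tolerance = 1e-5)
  }
})

test_that("training is deterministic and learns a constant series", {
  z <- rep(8, 60)
  ds <- make_windows(z, NULL, lstm_config(window = 6, hidden_units = 8,
                                          epochs = 10, seed = 21))
  fit1 <- train_lstm(ds)
  fit2 <- train_lstm(ds)
  expect_identical(fit1$history, fit2$history)
  # constant series standardizes to constant 0; the head must drive MSE to ~0
  expect_lt(tail(fit1$history$train_mse, 1), 1e-3)
  pred <- predict_distribution(fit1)
  expect_true(all(pred$sigma > 0))
  expect_equal(pred$upper - pred$lower, 2 * 1.96 * pred$sigma)
  # sigma shrinks toward its floor across epochs on noiseless data
  expect_lt(tail(fit1$history$train_loss, 1), fit1$history$train_loss[1])
})

test_that("the fitted mean beats the mean predictor on a noise-free trend", {
  sc <- scenario(n_weeks = 120, baseline = 10, drift = 0.05,
                 innovation_sd = 0, events = toy_calendar(),
                 effects = c("2" = -2), seed = 1)
  z <- simulate_weekly_series(sc)
  D <- build_design_matrix(toy_calendar(), 120)
  ds <- make_windows(z, D, lstm_config(seed = 1))
  fit <- train_lstm(ds)
  test_idx <- (ds$split_index + 1):length(ds$y)
  expect_lt(tail(fit$history$test_mse, 1), var(ds$y_raw[test_idx]))
})

test_that("the fitted mean recovers the sign of an injected step", {
  # around a negative step, the post-onset mean of the predicted mu must sit
  # below the pre-onset mean in >= 90% of seeded runs
  hits <- 0L
  for (s in 1:10) {
    sc <- scenario(n_weeks = 120, baseline = 12, drift = 0,
                   innovation_sd = 0.2, d = 0, ma_theta = 0,
                   events = toy_calendar()[2, ], effects = c("2" = -3),
                   seed = 400 + s)
    z <- simulate_weekly_series(sc)
    D <- build_design_matrix(toy_calendar()[2, ], 120)
    ds <- make_windows(z, D, lstm_config(seed = s))
    fit <- train_lstm(ds)
    pred <- predict_distribution(fit)
    post <- pred$week >= 15  # lagged onset of the injected effect
    if (mean(pred$mu[post]) < mean(pred$mu[!post])) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
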