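#' Softplus
#'
#' \eqn{softplus(x) = \log(1 + e^x)}, computed overflow-safely as
#' \eqn{\max(x, 0) + \log(1 + e^{-|x|})}.  Used to keep the variance head of
#' the LSTM strictly positive.
#'
#' @param x numeric vector.
#' @return numeric vector of strictly positive values.
#' @export
#' @examples
#' softplus(0)    # log(2)
#' softplus(50)   # ~50, no overflow
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Gaussian negative log-likelihood
#'
#' \eqn{L(y, \mu, \sigma) = \frac{1}{2}\log(2\pi\sigma^2) +
#' \frac{(y-\mu)^2}{2\sigma^2}}, elementwise over its arguments (recycled);
#' training minimises the mean over samples.
#'
#' @param y observed values.
#' @param mu predicted means.
#' @param sigma predicted standard deviations (> 0).
#' @return numeric vector of per-sample losses.
#' @export
#' @examples
#' gaussian_nll(0, 0, 1)               # 0.5 * log(2*pi)
#' gaussian_nll(3, 3, sqrt(1 / (2 * pi)))  # 0
gaussian_nll <- function(y, mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  0.5 * log(2 * pi * sigma^2) + (y - mu)^2 / (2 * sigma^2)
}

#' Root mean square error
#'
#' @param predicted,observed equal-length numeric vectors.
#' @return \eqn{\sqrt{mean((predicted - observed)^2)}}.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed lengths differ (",
         length(predicted), " vs ", length(observed), ")")
  }
  if (!length(predicted)) stop("empty input")
  sqrt(mean((predicted - observed)^2))
}

#' LSTM configuration
#'
#' Hyper-parameters of the distributional LSTM ITS model.  Defaults follow
#' the reference recipe: window 12 weeks, learning rate 0.001, 10 epochs,
#' Adam.  Hidden size 32, a single layer, per-sample updates (batch size 1)
#' and a chronological 80/20 train/test split are this package's defaults.
#'
#' @param window input window length w (>= 1 week).
#' @param learning_rate Adam step size (> 0).
#' @param epochs complete passes over the training set (>= 1).
#' @param hidden_units LSTM hidden state size.
#' @param layers number of stacked LSTM layers.
#' @param train_fraction chronological share of samples used for training.
#' @param batch_size samples per gradient update.
#' @param sigma2_floor additive floor on the predicted variance.
#' @param standardize standardize the prevalence feature/targets by
#'   train-split mean/SD (predictions are de-standardized)?
#' @param predict_difference if `TRUE` (default) the mean head predicts the
#'   week-over-week change and the reported mean adds back the last observed
#'   value -- the sequence analogue of first differencing, which lets the
#'   bounded recurrent states track a trending level; `FALSE` predicts the
#'   level directly.
#' @param seed integer RNG seed (initialisation + shuffling).
#' @return an `lstm_config` list.
#' @export
lstm_config <- function(window = 12L, learning_rate = 0.001, epochs = 10L,
                        hidden_units = 32L, layers = 1L,
                        train_fraction = 0.8, batch_size = 1L,
                        sigma2_floor = 1e-6, standardize = TRUE,
                        predict_difference = TRUE, seed = 1L) {
  stopifnot(window >= 1L, learning_rate > 0, epochs >= 1L, hidden_units >= 1L,
            layers >= 1L, train_fraction > 0, train_fraction < 1,
            batch_size >= 1L, sigma2_floor >= 0)
  structure(list(
    window = as.integer(window), learning_rate = learning_rate,
    epochs = as.integer(epochs), hidden_units = as.integer(hidden_units),
    layers = as.integer(layers), train_fraction = train_fraction,
    batch_size = as.integer(batch_size), sigma2_floor = sigma2_floor,
    standardize = isTRUE(standardize),
    predict_difference = isTRUE(predict_difference), seed = as.integer(seed),
    optimizer = "adam"
  ), class = "lstm_config")
}

#' Sliding-window dataset for the LSTM
#'
#' Builds the `n - w` sequence-to-one samples: sample i covers weeks
#' `i .. i+w-1` (features: prevalence plus the binary intervention
#' indicators of those weeks) and predicts week `i+w`.  Samples are split
#' chronologically at `train_fraction`; the prevalence feature and targets
#' are standardized by the mean/SD of the weeks available before the first
#' test target, so no test information leaks into the scaling.
#'
#' @param series a `weekly_series` (or numeric vector).
#' @param design optional `its_design` aligned to the series.
#' @param config an [lstm_config()].
#' @return a `windowed_dataset`: list with array `x` (samples x window x
#'   features), `y` (standardized targets), `y_raw`, `target_week`,
#'   `split_index`, `center`, `scale`, `config`.
#' @export
make_windows <- function(series, design = NULL, config = lstm_config()) {
  z <- series_values(series)
  n <- length(z)
  w <- config$window
  if (n <= w) stop("series of length ", n, " is too short for window ", w,
                   " (need at least ", w + 1L, " weeks)")
  if (anyNA(z)) stop("series contains missing weeks")
  if (!is.null(design)) {
    D <- unclass(design)[seq_len(NROW(design)), , drop = FALSE]
    storage.mode(D) <- "double"
    if (NROW(D) != n) stop("design matrix and series lengths differ")
  } else {
    D <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  n_samp <- n - w
  split_index <- floor(config$train_fraction * n_samp)
  if (split_index < 1L || split_index >= n_samp) {
    stop("train_fraction ", config$train_fraction, " leaves an empty ",
         "train or test partition for ", n_samp, " samples")
  }
  train_weeks <- seq_len(w + split_index)
  if (config$standardize) {
    center <- mean(z[train_weeks])
    scale <- stats::sd(z[train_weeks])
    if (!is.finite(scale) || scale == 0) scale <- 1
  } else {
    center <- 0; scale <- 1
  }
  zs <- (z - center) / scale

  n_feat <- 1L + ncol(D)
  x <- array(0, dim = c(n_samp, w, n_feat))
  for (i in seq_len(n_samp)) {
    x[i, , 1] <- zs[i:(i + w - 1L)]
    if (ncol(D)) x[i, , -1] <- D[i:(i + w - 1L), ]
  }
  structure(list(
    x = x, y = zs[(w + 1L):n], y_raw = z[(w + 1L):n],
    last_obs = zs[w:(n - 1L)],
    target_week = (w + 1L):n, split_index = split_index,
    center = center, scale = scale, n_features = n_feat,
    feature_names = c("prevalence", colnames(D)), config = config,
    start_date = if (inherits(series, "weekly_series"))
      attr(series, "start_date") else NULL
  ), class = "windowed_dataset")
}

# ---- parameter initialisation, forward and backward passes -----------------
# Gate layout in the 4H-wide weight blocks: [input | forget | cell | output].

lstm_init_params <- function(n_features, config) {
  H <- config$hidden_units
  k <- 1 / sqrt(H)
  runifm <- function(r, c) matrix(stats::runif(r * c, -k, k), r, c)
  layers <- vector("list", config$layers)
  f_in <- n_features
  for (l in seq_len(config$layers)) {
    b <- stats::runif(4 * H, -k, k)
    b[(H + 1L):(2L * H)] <- 1  # forget-gate bias 1: remember by default
    layers[[l]] <- list(Wx = runifm(f_in, 4 * H), Wh = runifm(H, 4 * H), b = b)
    f_in <- H
  }
  list(layers = layers,
       Wmu = runifm(H, 1), bmu = 0,
       Ws = runifm(H, 1), bs = 0)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass over a batch.  x: array [B, w, F].  Returns the head outputs
# and (optionally) the full cache needed for backpropagation through time.
lstm_forward <- function(params, x, sigma2_floor, keep_cache = FALSE) {
  B <- dim(x)[1]; w <- dim(x)[2]
  H <- nrow(params$layers[[1]]$Wh)
  L <- length(params$layers)
  cache <- if (keep_cache) vector("list", L) else NULL
  inp <- lapply(seq_len(w), function(t) matrix(x[, t, ], nrow = B))
  for (l in seq_len(L)) {
    p <- params$layers[[l]]
    Hp <- matrix(0, B, H); Cp <- matrix(0, B, H)
    steps <- if (keep_cache) vector("list", w) else NULL
    out <- vector("list", w)
    for (t in seq_len(w)) {
      Z <- inp[[t]] %*% p$Wx + Hp %*% p$Wh +
        matrix(p$b, B, 4 * H, byrow = TRUE)
      i <- sigmoid(Z[, 1:H, drop = FALSE])
      f <- sigmoid(Z[, (H + 1):(2 * H), drop = FALSE])
      g <- tanh(Z[, (2 * H + 1):(3 * H), drop = FALSE])
      o <- sigmoid(Z[, (3 * H + 1):(4 * H), drop = FALSE])
      C <- f * Cp + i * g
      tC <- tanh(C)
      Hn <- o * tC
      if (keep_cache) {
        steps[[t]] <- list(X = inp[[t]], Hp = Hp, Cp = Cp, i = i, f = f,
                           g = g, o = o, C = C, tC = tC)
      }
      out[[t]] <- Hn
      Hp <- Hn; Cp <- C
    }
    if (keep_cache) cache[[l]] <- steps
    inp <- out
  }
  Hfin <- inp[[w]]
  mu <- as.numeric(Hfin %*% params$Wmu) + params$bmu
  s <- as.numeric(Hfin %*% params$Ws) + params$bs
  sigma2 <- softplus(s) + sigma2_floor
  list(mu = mu, s = s, sigma2 = sigma2, Hfin = Hfin, cache = cache)
}

# Backward pass: mean Gaussian NLL over the batch; returns gradients in the
# same structure as the parameters, plus the loss.
lstm_backward <- function(params, fw, x, y, sigma2_floor) {
  B <- dim(x)[1]; w <- dim(x)[2]
  H <- nrow(params$layers[[1]]$Wh)
  L <- length(params$layers)
  mu <- fw$mu; sigma2 <- fw$sigma2
  loss <- mean(0.5 * log(2 * pi * sigma2) + (y - mu)^2 / (2 * sigma2))

  dmu <- -(y - mu) / sigma2 / B
  dsig2 <- (0.5 / sigma2 - (y - mu)^2 / (2 * sigma2^2)) / B
  ds <- dsig2 * sigmoid(fw$s)

  grads <- list(
    layers = lapply(params$layers, function(p)
      list(Wx = p$Wx * 0, Wh = p$Wh * 0, b = p$b * 0)),
    Wmu = params$Wmu * 0, bmu = 0, Ws = params$Ws * 0, bs = 0
  )
  Hfin <- fw$Hfin
  grads$Wmu[] <- crossprod(Hfin, dmu)
  grads$bmu <- sum(dmu)
  grads$Ws[] <- crossprod(Hfin, ds)
  grads$bs <- sum(ds)

  # gradient injected into the top layer's hidden states (final step only)
  dH_inj <- vector("list", w)
  zero <- matrix(0, B, H)
  for (t in seq_len(w)) dH_inj[[t]] <- zero
  dH_inj[[w]] <- dmu %o% as.numeric(params$Wmu) + ds %o% as.numeric(params$Ws)

  for (l in rev(seq_len(L))) {
    p <- params$layers[[l]]
    st <- fw$cache[[l]]
    dX_below <- if (l > 1L) vector("list", w) else NULL
    dH_next <- zero; dC_next <- zero
    for (t in rev(seq_len(w))) {
      sc <- st[[t]]
      dH <- dH_inj[[t]] + dH_next
      dO <- dH * sc$tC
      dC <- dC_next + dH * sc$o * (1 - sc$tC^2)
      dF <- dC * sc$Cp
      dI <- dC * sc$g
      dG <- dC * sc$i
      dC_next <- dC * sc$f
      dZ <- cbind(dI * sc$i * (1 - sc$i),
                  dF * sc$f * (1 - sc$f),
                  dG * (1 - sc$g^2),
                  dO * sc$o * (1 - sc$o))
      grads$layers[[l]]$Wx <- grads$layers[[l]]$Wx + crossprod(sc$X, dZ)
      grads$layers[[l]]$Wh <- grads$layers[[l]]$Wh + crossprod(sc$Hp, dZ)
      grads$layers[[l]]$b <- grads$layers[[l]]$b + colSums(dZ)
      dH_next <- dZ %*% t(p$Wh)
      if (l > 1L) dX_below[[t]] <- dZ %*% t(p$Wx)
    }
    if (l > 1L) dH_inj <- dX_below
  }
  list(grads = grads, loss = loss)
}

# Adam optimiser state and update (standard bias-corrected moments).
adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^state$t)
    vhat <- v / (1 - beta2^state$t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- Map(upd, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = state$t))
}

#' Train the distributional LSTM ITS model
#'
#' A stacked-LSTM network whose final hidden state feeds two parallel linear
#' heads predicting the mean and (through a Softplus, plus a small floor)
#' the variance of the next week's prevalence; trained by Adam on the mean
#' Gaussian negative log-likelihood.  Each epoch is one complete pass over
#' the training samples in a seeded shuffled order, updated in mini-batches
#' of `batch_size`; after every epoch the train/test MSE of the mean
#' prediction (raw prevalence scale) and the mean training NLL are recorded
#' for epoch selection.  Training is deterministic given the config seed.
#'
#' @param dataset a [make_windows()] dataset.
#' @param config an [lstm_config()]; defaults to the dataset's.
#' @return an `lstm_fit`: `params`, `config`, `history` (tibble with
#'   `epoch`, `train_mse`, `test_mse`, `train_loss`), `dataset`.
#' @export
#' @examples
#' z <- simulate_weekly_series(scenario(n_weeks = 60, seed = 3))
#' ds <- make_windows(z, config = lstm_config(epochs = 2, hidden_units = 8))
#' fit <- train_lstm(ds)
#' fit$history
train_lstm <- function(dataset, config = dataset$config) {
  stopifnot(inherits(dataset, "windowed_dataset"))
  set.seed(config$seed)
  n_samp <- dim(dataset$x)[1]
  split <- dataset$split_index
  train_idx <- seq_len(split)
  test_idx <- (split + 1L):n_samp

  params <- lstm_init_params(dataset$n_features, config)
  state <- adam_init(params)
  history <- tibble::tibble(epoch = integer(), train_mse = numeric(),
                            test_mse = numeric(), train_loss = numeric())
  # with difference targets the head learns y_t - z_{t-1}; the reported mean
  # adds the last observed value back, an affine shift that leaves the
  # Gaussian NLL and its gradients unchanged
  offset <- if (config$predict_difference) dataset$last_obs else
    numeric(length(dataset$y))

  mse_of <- function(idx) {
    fw <- lstm_forward(params, dataset$x[idx, , , drop = FALSE],
                       config$sigma2_floor)
    mu_raw <- (fw$mu + offset[idx]) * dataset$scale + dataset$center
    mean((mu_raw - dataset$y_raw[idx])^2)
  }

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(train_idx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    losses <- numeric(length(batches))
    for (b in seq_along(batches)) {
      idx <- batches[[b]]
      xb <- dataset$x[idx, , , drop = FALSE]
      yb <- dataset$y[idx] - offset[idx]
      fw <- lstm_forward(params, xb, config$sigma2_floor, keep_cache = TRUE)
      bw <- lstm_backward(params, fw, xb, yb, config$sigma2_floor)
      if (!is.finite(bw$loss)) {
        stop("training loss is not finite at epoch ", epoch,
             "; try a smaller learning_rate than ", config$learning_rate)
      }
      losses[b] <- bw$loss
      stepped <- adam_step(params, bw$grads, state, config$learning_rate)
      params <- stepped$params
      state <- stepped$state
    }
    history <- dplyr::bind_rows(history, tibble::tibble(
      epoch = epoch, train_mse = mse_of(train_idx), test_mse = mse_of(test_idx),
      train_loss = mean(losses)
    ))
  }
  structure(list(params = params, config = config, history = history,
                 dataset = dataset), class = "lstm_fit")
}

#' @export
print.lstm_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat("<lstm_fit> ", x$config$layers, " layer(s) x ", x$config$hidden_units,
      " units, window ", x$config$window, ", ", x$config$epochs, " epochs\n",
      sep = "")
  cat(sprintf("  final train MSE %.4f | test MSE %.4f | train NLL %.4f\n",
              h$train_mse, h$test_mse, h$train_loss))
  invisible(x)
}

#' Predict the forecast distribution for every predictable week
#'
#' Runs the trained network over all windows and returns, per target week,
#' the de-standardized predicted mean \eqn{\mu_t}, scale \eqn{\sigma_t > 0},
#' and the 95% predictive interval \eqn{\mu_t \pm 1.96\sigma_t}.
#'
#' @param model an `lstm_fit`.
#' @param dataset a [make_windows()] dataset (defaults to the training one).
#' @return a `forecast_distribution` tibble: `week`, `observed`, `mu`,
#'   `sigma`, `lower`, `upper`, `partition` ("train"/"test").
#' @export
predict_distribution <- function(model, dataset = model$dataset) {
  stopifnot(inherits(model, "lstm_fit"), inherits(dataset, "windowed_dataset"))
  fw <- lstm_forward(model$params, dataset$x, model$config$sigma2_floor)
  offset <- if (model$config$predict_difference) dataset$last_obs else 0
  mu <- (fw$mu + offset) * dataset$scale + dataset$center
  sigma <- sqrt(fw$sigma2) * dataset$scale
  out <- tibble::tibble(
    week = dataset$target_week,
    observed = dataset$y_raw,
    mu = mu, sigma = sigma,
    lower = mu - 1.96 * sigma, upper = mu + 1.96 * sigma,
    partition = rep(c("train", "test"),
                    c(dataset$split_index,
                      length(dataset$y) - dataset$split_index))
  )
  class(out) <- c("forecast_distribution", class(out))
  out
}
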