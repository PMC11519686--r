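#' Effects table across fitted models
#'
#' Flattens one or more ITS fits into the standard reporting layout: one row
#' per coefficient per model, carrying the ARIMA order and the model-level
#' diagnostics (Ljung-Box Q, Stationary R-squared), the estimate with its
#' 95% CI rendered as `"estimate (lower to upper)"`, the 2-tailed p-value,
#' and a significance flag at p < 0.05.
#'
#' @param fits a named list of `its_fit` objects (names are model/stratum
#'   labels), or a single `its_fit`.
#' @return an `effects_table` tibble.
#' @export
effects_table <- function(fits) {
  if (inherits(fits, "its_fit")) fits <- list(total = fits)
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "its_fit")))
  if (is.null(names(fits))) names(fits) <- paste0("model_", seq_along(fits))
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    co <- f$coefficients
    tibble::tibble(
      model = nm,
      arima_order = paste(f$order, collapse = ","),
      ljung_box_q = f$ljung_box$statistic,
      stationary_r2 = f$stationary_r2,
      term = co$term,
      estimate = co$estimate,
      ci_lower = co$ci_lower,
      ci_upper = co$ci_upper,
      ci = sprintf("%.2f (%.2f to %.2f)", co$estimate, co$ci_lower, co$ci_upper),
      p_value = co$p_value,
      significant = !is.na(co$p_value) & co$p_value < 0.05
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("effects_table", class(out))
  out
}

#' Plot a weekly series with interruption markers and model overlays
#'
#' The observed series with dotted vertical markers at the (unlagged) event
#' dates labelled by event id, optionally overlaid with an ARIMA fitted mean
#' and/or an LSTM forecast distribution (predicted mean plus 95% band).
#'
#' @param series a `weekly_series`.
#' @param events interruption calendar; `NULL` suppresses markers.
#' @param fit optional `its_fit` whose fitted values (`observed - residual`)
#'   are overlaid.
#' @param forecast optional `forecast_distribution` overlay.
#' @return a ggplot object.
#' @export
plot_series <- function(series, events = default_calendar(), fit = NULL,
                        forecast = NULL) {
  stopifnot(inherits(series, "weekly_series"))
  p <- ggplot2::ggplot(series,
                       ggplot2::aes(x = .data$week_start_date,
                                    y = .data$prevalence_pct)) +
    ggplot2::geom_line(color = "#c23b22") +
    ggplot2::labs(x = NULL, y = "Prevalence (%)") +
    ggplot2::theme_minimal()
  if (!is.null(events)) {
    events <- validate_calendar(events)
    ymax <- max(series$prevalence_pct, na.rm = TRUE)
    p <- p +
      ggplot2::geom_vline(data = events,
                          ggplot2::aes(xintercept = .data$date),
                          linetype = "dotted", color = "black") +
      ggplot2::annotate("text", x = events$date, y = ymax * 1.04,
                        label = events$id, size = 3)
  }
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "its_fit"))
    fitted_df <- tibble::tibble(
      week_start_date = series$week_start_date,
      fitted = series$prevalence_pct - fit$residuals
    )
    p <- p + ggplot2::geom_line(data = fitted_df,
                                ggplot2::aes(y = .data$fitted),
                                color = "#2c5f9e", linetype = "dashed")
  }
  if (!is.null(forecast)) {
    stopifnot(inherits(forecast, "forecast_distribution"))
    fc <- forecast
    fc$week_start_date <- series$week_start_date[fc$week]
    p <- p +
      ggplot2::geom_ribbon(data = fc,
                           ggplot2::aes(x = .data$week_start_date,
                                        ymin = .data$lower, ymax = .data$upper),
                           inherit.aes = FALSE, fill = "grey70", alpha = 0.5) +
      ggplot2::geom_line(data = fc,
                         ggplot2::aes(x = .data$week_start_date, y = .data$mu),
                         inherit.aes = FALSE, color = "#2c5f9e")
  }
  p
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config
}

#' Run the full ITS pipeline from a configuration
#'
#' Executes the stages in order -- input (simulate a series, read a weekly
#' series CSV, or aggregate a microdata CSV), build the lagged intervention
#' design, fit the ARIMA ITS (per stratum when stratifying), optionally fit
#' the LSTM model -- and writes every artifact under `out_dir`: the weekly
#' series and design CSVs, the effects table (CSV + JSON), LSTM predictions
#' and loss curves, figures (PNG), a plain-text log and a run manifest.
#'
#' Config fields (list or YAML/JSON path): `mode` ("simulate" | "series" |
#' "microdata"); `scenario` (arguments to [scenario()], simulate mode);
#' `series_file` / `microdata_file`; `cutoff`; `lag_weeks`;
#' `pandemic_coding`; `order` (ARIMA order, default `c(0,1,1)`); `strata`
#' (stratification variables, microdata mode); `lstm` (arguments to
#' [lstm_config()], or `FALSE` to skip); `seed`; `out_dir`.
#'
#' @param config list or path to a YAML/JSON file.
#' @return invisibly, a list with the series, design, fits, effects table,
#'   LSTM results and output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  mode <- match.arg(cfg$mode, c("simulate", "series", "microdata"))
  out_dir <- cfg$out_dir %||% stop("config needs `out_dir`")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed %||% 1L
  log_lines <- character()
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), paste0(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    say("stage ", name, " started")
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste0("stage ", name, " FAILED: ",
                                     conditionMessage(e))),
                 file.path(out_dir, "pipeline.log"))
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cutoff <- cfg$cutoff %||% 15L
  lag_weeks <- cfg$lag_weeks %||% 4L
  coding <- cfg$pandemic_coding %||% "step"
  order <- as.numeric(cfg$order %||% c(0, 1, 1))

  strata_series <- NULL
  series <- stage("input", {
    switch(mode,
      simulate = {
        sc_args <- cfg$scenario %||% list()
        sc_args$seed <- sc_args$seed %||% seed
        sc_args$lag_weeks <- sc_args$lag_weeks %||% lag_weeks
        sc <- do.call(scenario, sc_args)
        simulate_weekly_series(sc)
      },
      series = read_series_csv(cfg$series_file),
      microdata = {
        rec <- utils::read.csv(cfg$microdata_file, stringsAsFactors = FALSE)
        strata_series <<- stratify_prevalence(rec, cutoff = cutoff,
                                              vars = cfg$strata %||%
                                                names(strata_definitions()))
        strata_series$total
      }
    )
  })
  write_series_csv(series, file.path(out_dir, "weekly_series.csv"))
  say("series: ", nrow(series), " weeks from ",
      format(series$week_start_date[1]))

  design <- stage("design", {
    build_design_matrix(default_calendar(), n_weeks = nrow(series),
                        start_date = attr(series, "start_date"),
                        lag_weeks = lag_weeks, pandemic_coding = coding)
  })
  utils::write.csv(as.data.frame(design_as_tibble(design)),
                   file.path(out_dir, "design_matrix.csv"), row.names = FALSE)

  fits <- stage("fit-arima", {
    to_fit <- if (!is.null(strata_series)) strata_series else
      list(total = series)
    to_fit <- Filter(function(s) !anyNA(s$prevalence_pct), to_fit)
    lapply(to_fit, fit_its, design = design, order = order)
  })
  tab <- effects_table(fits)
  utils::write.csv(as.data.frame(tab), file.path(out_dir, "effects_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.data.frame(tab),
                       file.path(out_dir, "effects_table.json"),
                       auto_unbox = TRUE, digits = NA)
  say("fitted ", length(fits), " ARIMA model(s)")
  if (any(vapply(fits, function(f) f$ljung_box$p_value <= 0.05, TRUE))) {
    say("warning: Ljung-Box significant (p <= 0.05) for model(s): ",
        paste(names(fits)[vapply(fits, function(f)
          f$ljung_box$p_value <= 0.05, TRUE)], collapse = ", "))
  }

  lstm_out <- NULL
  if (!isFALSE(cfg$lstm)) {
    lstm_out <- stage("fit-lstm", {
      largs <- if (is.list(cfg$lstm)) cfg$lstm else list()
      largs$seed <- largs$seed %||% seed
      lc <- do.call(lstm_config, largs)
      ds <- make_windows(series, design, lc)
      fit <- train_lstm(ds)
      pred <- predict_distribution(fit)
      utils::write.csv(as.data.frame(pred),
                       file.path(out_dir, "lstm_predictions.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(fit$history),
                       file.path(out_dir, "lstm_history.csv"),
                       row.names = FALSE)
      list(fit = fit, predictions = pred)
    })
    say("LSTM trained: final test MSE ",
        signif(utils::tail(lstm_out$fit$history$test_mse, 1), 4))
  }

  stage("report", {
    fig <- plot_series(series, fit = fits[["total"]],
                       forecast = lstm_out$predictions)
    ggplot2::ggsave(file.path(out_dir, "series_fit.png"), fig,
                    width = 10, height = 5, dpi = 150)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("itsprev")),
    r_version = R.version.string,
    seed = seed, mode = mode, cutoff = cutoff, lag_weeks = lag_weeks,
    order = order, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg[setdiff(names(cfg), "out_dir")]
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  say("pipeline complete; outputs in ", out_dir)

  invisible(list(series = series, design = design, fits = fits,
                 effects = tab, lstm = lstm_out, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
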