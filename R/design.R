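#' Model specification for the four competing pollutant models
#'
#' * Model `"I"`: single-pollutant — confounders plus one linear pollutant
#'   term (`pollutant` selects which).
#' * Model `"II"`: three linear pollutant terms.
#' * Model `"III"`: Model II plus the three pairwise product terms.
#' * Model `"IV"`: a centered tensor-product smooth of the three pollutants
#'   with one roughness penalty per margin.
#'
#' All models share the confounder block: natural cubic splines of the
#' 14-day moving average of temperature, of same-day humidity and pressure
#' (each `df_met` columns) and of the day index (`df_time` columns),
#' day-of-week dummies (Monday reference) and a holiday indicator.
#' Pollutants enter as moving averages over `pollutant_lag` (default the
#' 3-day window, lags 0-2).
#'
#' @param model one of "I", "II", "III", "IV".
#' @param pollutant for Model I, one of "pm10", "no2", "so2".
#' @param pollutant_lag inclusive lag range for the pollutant moving
#'   average, default `0:2`.
#' @param temperature_lag inclusive lag range for the temperature moving
#'   average, default `0:13` (14-day).
#' @param df_time spline df for the time trend; `NULL` (default) uses
#'   `df_time_per_year` per 365.25 days, the standard convention for
#'   multi-year daily series.
#' @param df_time_per_year trend df per year when `df_time` is `NULL`.
#' @param df_met spline df for each meteorological variable (default 3).
#' @param tensor_dims marginal basis dimensions `(I, K, L)` for Model IV.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(model = c("I", "II", "III", "IV"),
                       pollutant = NULL,
                       pollutant_lag = 0:2,
                       temperature_lag = 0:13,
                       df_time = NULL,
                       df_time_per_year = 7,
                       df_met = 3L,
                       tensor_dims = c(5L, 5L, 5L)) {
  model <- match.arg(model)
  if (model == "I") {
    if (is.null(pollutant)) stop("Model I needs a 'pollutant'")
    pollutant <- match.arg(pollutant, c("pm10", "no2", "so2"))
  }
  stopifnot(length(pollutant_lag) >= 1L, length(temperature_lag) >= 1L,
            df_met >= 1L, is.null(df_time) || df_time >= 1L)
  structure(list(model = model, pollutant = pollutant,
                 pollutant_lag = as.integer(pollutant_lag),
                 temperature_lag = as.integer(temperature_lag),
                 df_time = df_time, df_time_per_year = df_time_per_year,
                 df_met = as.integer(df_met),
                 tensor_dims = as.integer(tensor_dims)),
            class = "model_spec")
}

#' Trailing moving average with strict missingness propagation
#'
#' The value at day `t` is the mean of `x` over days `t - window + 1 ... t`.
#' The first `window - 1` days are missing, and a missing input day makes
#' every average containing it missing (no imputation).
#'
#' @param x numeric series (may contain `NA`).
#' @param window integer window length (>= 1).
#' @return a numeric series of the same length.
#' @export
moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  as.numeric(stats::filter(x, rep(1 / window, window), sides = 1L))
}

#' Confounder block of the model matrix
#'
#' Builds the parametric columns shared by all four models (no intercept;
#' the intercept is added by [build_model()]).
#'
#' @param data a validated daily data.frame.
#' @param spec a [model_spec()].
#' @return a labeled numeric matrix (rows with undefined lagged temperature
#'   are `NA` and are dropped later).
#' @export
build_confounders <- function(data, spec) {
  n <- nrow(data)
  df_time <- if (!is.null(spec$df_time)) as.integer(spec$df_time)
             else max(1L, as.integer(round(spec$df_time_per_year * n / 365.25)))
  temp_ma <- moving_average(data$temp, length(spec$temperature_lag))
  blocks <- list(
    temp = natural_cubic_basis(temp_ma, spec$df_met),
    rh = natural_cubic_basis(data$rh, spec$df_met),
    pressure = natural_cubic_basis(data$pressure, spec$df_met),
    time = natural_cubic_basis(seq_len(n), df_time)
  )
  dow <- data$dow
  if (!is.factor(dow)) dow <- factor(dow, levels = unique(dow))
  dow_mm <- stats::model.matrix(~ dw, data.frame(dw = dow))[, -1L, drop = FALSE]
  colnames(dow_mm) <- sub("^dw", "dow_", colnames(dow_mm))
  blocks$dow <- dow_mm
  blocks$holiday <- matrix(as.numeric(data$holiday), ncol = 1L,
                           dimnames = list(NULL, "holiday"))
  for (b in c("temp", "rh", "pressure", "time"))
    colnames(blocks[[b]]) <- paste0(b, "_", seq_len(ncol(blocks[[b]])))
  do.call(cbind, blocks)
}

#' Build the penalized design for one model
#'
#' Assembles response, intercept, confounders and the pollutant block for
#' the requested model; drops (and records) days undefined because of lag
#' warm-up or missing values; computes the IQR increments and 25th-percentile
#' reference levels of the lagged exposures actually entering the model.
#' For Model IV the marginal bases are built on the retained lagged
#' exposures, the tensor design is centered to sum to zero over the sample,
#' and the three expanded penalties are attached to the smooth block.
#'
#' @param data a daily data.frame (see [validate_daily_data()]).
#' @param spec a [model_spec()].
#' @return an object of class `pollution_design` with fields `X`, `y`,
#'   `penalties`, `column_map`, `model`, `spec`, `dates`, `dropped_days`,
#'   `increments`, `reference_levels`, `exposures` (retained lagged
#'   exposures), `smooth` (Model IV only) and `notes`.
#' @export
build_model <- function(data, spec) {
  validate_daily_data(data)
  n <- nrow(data)
  w <- length(spec$pollutant_lag)
  conf <- build_confounders(data, spec)
  ma <- cbind(pm10 = moving_average(data$pm10, w),
              no2 = moving_average(data$no2, w),
              so2 = moving_average(data$so2, w))

  needed_poll <- switch(spec$model, I = spec$pollutant,
                        c("pm10", "no2", "so2"))
  keep <- stats::complete.cases(conf) & !is.na(data$deaths) &
    stats::complete.cases(ma[, needed_poll, drop = FALSE])
  if (!any(keep)) stop("all days dropped; no usable data")
  notes <- character(0)
  if (mean(!keep) > 0.10) {
    notes <- c(notes, sprintf("warning: %.1f%% of days dropped", 100 * mean(!keep)))
    warning(sprintf("%.1f%% of days dropped for missingness/lag warm-up",
                    100 * mean(!keep)))
  }

  confk <- conf[keep, , drop = FALSE]
  ## all-zero parametric columns (e.g. holiday absent in a subset) are
  ## removed so the penalized Hessian stays full rank
  nz <- colSums(abs(confk)) > 0
  if (!all(nz)) {
    notes <- c(notes, paste("dropped empty columns:",
                            paste(colnames(confk)[!nz], collapse = ", ")))
    confk <- confk[, nz, drop = FALSE]
  }
  mak <- ma[keep, , drop = FALSE]
  y <- as.numeric(data$deaths[keep])
  dates <- as.Date(data$date)[keep]
  dropped <- as.Date(data$date)[!keep]

  increments <- apply(mak[, needed_poll, drop = FALSE], 2L, stats::IQR)
  reference_levels <- apply(mak[, needed_poll, drop = FALSE], 2L,
                            stats::quantile, probs = 0.25, names = FALSE)
  if (any(increments <= 0)) stop("degenerate exposure: zero IQR")

  X <- cbind(`(Intercept)` = 1, confk)
  column_map <- list(intercept = 1L)
  pos <- ncol(X)
  column_map$confounders <- 2L:pos
  penalties <- list()
  smooth <- NULL

  add_cols <- function(X, M) {
    out <- cbind(X, M)
    idx <- (ncol(X) + 1L):ncol(out)
    list(X = out, idx = idx)
  }

  if (spec$model == "I") {
    M <- mak[, spec$pollutant, drop = FALSE]
    a <- add_cols(X, M); X <- a$X
    column_map[[spec$pollutant]] <- a$idx
  } else if (spec$model %in% c("II", "III")) {
    for (p in c("pm10", "no2", "so2")) {
      a <- add_cols(X, mak[, p, drop = FALSE]); X <- a$X
      column_map[[p]] <- a$idx
    }
    if (spec$model == "III") {
      prods <- cbind(pm10_no2 = mak[, "pm10"] * mak[, "no2"],
                     pm10_so2 = mak[, "pm10"] * mak[, "so2"],
                     no2_so2 = mak[, "no2"] * mak[, "so2"])
      a <- add_cols(X, prods); X <- a$X
      column_map$interactions <- a$idx
      names(column_map$interactions) <- colnames(prods)
    }
  } else { # Model IV
    margins <- list(
      cubic_marginal(mak[, "pm10"], spec$tensor_dims[1L], name = "pm10"),
      cubic_marginal(mak[, "no2"], spec$tensor_dims[2L], name = "no2"),
      cubic_marginal(mak[, "so2"], spec$tensor_dims[3L], name = "so2"))
    sm <- tensor_smooth(margins)
    Traw <- tensor_basis_row(margins, mak)
    cc <- apply_centering(sm, Traw)
    smooth <- cc$smooth
    colnames(cc$design) <- paste0("te_", seq_len(ncol(cc$design)))
    a <- add_cols(X, cc$design); X <- a$X
    column_map$smooth <- a$idx
    penalties <- lapply(names(cc$penalties), function(nm)
      list(label = nm, cols = a$idx, S = cc$penalties[[nm]]))
    names(penalties) <- names(cc$penalties)
  }

  structure(list(X = X, y = y, penalties = penalties,
                 column_map = column_map, model = spec$model, spec = spec,
                 dates = dates, dropped_days = dropped,
                 increments = increments,
                 reference_levels = reference_levels,
                 exposures = mak, smooth = smooth, notes = notes),
            class = "pollution_design")
}

#' Export a built model matrix to CSV
#' @param design a `pollution_design`.
#' @param path file path.
#' @export
export_design_csv <- function(design, path) {
  out <- data.frame(date = format(design$dates, "%Y-%m-%d"),
                    deaths = design$y,
                    design$X, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
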