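#' Run configuration for the full model-comparison pipeline
#'
#' @param input `"simulate"` or a path to a daily CSV (see
#'   [read_daily_csv()]).
#' @param simulation a [simulation_config()] (used when `input = "simulate"`).
#' @param models which of Models I-IV to fit.
#' @param pollutant_lag inclusive lag range for pollutant moving averages.
#' @param sensitivity_lags list of lag ranges for [run_lag_sensitivity()].
#' @param tensor_dims marginal dimensions for Model IV.
#' @param gcv a [gcv_control()] for Model IV smoothing selection.
#' @param n_missing pollutant-missing days injected into simulated data.
#' @param output_dir directory for artifacts.
#' @param seed master seed (mandatory for simulation).
#' @return an object of class `run_config`.
#' @export
run_config <- function(input = "simulate",
                       simulation = simulation_config(),
                       models = c("I", "II", "III", "IV"),
                       pollutant_lag = 0:2,
                       sensitivity_lags = list(0:1, 0:2),
                       tensor_dims = c(5L, 5L, 5L),
                       gcv = gcv_control(),
                       n_missing = 40L,
                       output_dir = tempfile("temort_run_"),
                       seed = 1L) {
  if (!length(models)) stop("at least one model must be requested")
  structure(list(input = input, simulation = simulation,
                 models = match.arg(models, c("I", "II", "III", "IV"),
                                    several.ok = TRUE),
                 pollutant_lag = as.integer(pollutant_lag),
                 sensitivity_lags = sensitivity_lags,
                 tensor_dims = as.integer(tensor_dims),
                 gcv = gcv, n_missing = as.integer(n_missing),
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL # run-specific location, not part of the analysis
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(cfg, control = c("exact")), tf)
  unname(tools::md5sum(tf))
}

load_or_simulate <- function(config) {
  if (identical(config$input, "simulate"))
    simulate_daily_data(config$simulation, seed = config$seed,
                        n_missing = config$n_missing)
  else read_daily_csv(config$input)
}

#' Fit a set of models and tabulate their effects
#'
#' Shared worker behind [run_pipeline()], [run_stratified()] and
#' [run_lag_sensitivity()]: builds and fits every requested model on one
#' dataset and extracts per-pollutant and combined IQR-increase effects.
#' One model's failure is recorded without aborting the rest.
#'
#' @param data a daily data.frame.
#' @param config a [run_config()].
#' @param pollutant_lag lag range overriding the config's.
#' @return list with `fits` (per model), `table` (a data.frame in the
#'   comparison-table layout), `diagnostics` and `failures`.
#' @export
fit_model_set <- function(data, config, pollutant_lag = config$pollutant_lag) {
  fits <- list(); failures <- list(); rows <- list(); diags <- list()
  add_rows <- function(model, fit_obj) {
    for (p in c("pm10", "no2", "so2")) {
      est <- iqr_effect(fit_obj, p)
      rows[[length(rows) + 1L]] <<- effect_row(model, p, est)
    }
    est <- iqr_effect(fit_obj)
    rows[[length(rows) + 1L]] <<- effect_row(model, "combined", est)
  }
  for (m in config$models) {
    res <- tryCatch({
      if (m == "I") {
        fit_obj <- lapply(c("pm10", "no2", "so2"), function(p)
          pirls_fit(build_model(data, model_spec("I", pollutant = p,
                                                 pollutant_lag = pollutant_lag))))
        names(fit_obj) <- c("pm10", "no2", "so2")
        diag <- list(edf = vapply(fit_obj, `[[`, numeric(1), "edf"),
                     dispersion = vapply(fit_obj, `[[`, numeric(1), "dispersion"))
      } else if (m %in% c("II", "III")) {
        fit_obj <- pirls_fit(build_model(data, model_spec(m,
                                                          pollutant_lag = pollutant_lag)))
        diag <- list(edf = fit_obj$edf, dispersion = fit_obj$dispersion)
      } else {
        des <- build_model(data, model_spec("IV", pollutant_lag = pollutant_lag,
                                            tensor_dims = config$tensor_dims))
        sel <- gcv_select(des, control = config$gcv)
        fit_obj <- sel$fit
        diag <- list(edf = fit_obj$edf, dispersion = fit_obj$dispersion,
                     lambdas = sel$lambdas, gcv = sel$gcv,
                     boundary = sel$boundary)
      }
      add_rows(m, fit_obj)
      list(fit = fit_obj, diag = diag)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[m]] <- conditionMessage(res)
    } else {
      fits[[m]] <- res$fit
      diags[[m]] <- res$diag
    }
  }
  table <- do.call(rbind, rows)
  list(fits = fits, table = table, diagnostics = diags, failures = failures)
}

effect_row <- function(model, pollutant, est) {
  ctr <- if (!is.null(est$contrast$increments)) {
    inc <- unlist(est$contrast$increments)
    paste0(names(inc), "+", signif(inc, 4), collapse = ";")
  } else {
    fr <- unlist(est$contrast$from); to <- unlist(est$contrast$to)
    paste0(names(to), ":", signif(fr, 4), "->", signif(to, 4),
           collapse = ";")
  }
  data.frame(model = model, pollutant = pollutant, contrast = ctr,
             rr = est$rr, er_percent = est$er_percent,
             er_ci_low = est$er_ci_low, er_ci_high = est$er_ci_high,
             se_log_rr = est$se_log_rr)
}

#' Run the full comparison pipeline
#'
#' Simulates (or loads) the daily dataset, fits every requested model,
#' writes the comparison table, per-model fit logs, the Model IV surface
#' and exposure-response grids and a machine-readable report, and returns
#' the report. Deterministic given the config and seed.
#'
#' @param config a [run_config()].
#' @return the comparison report (invisibly also on disk as `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  data <- load_or_simulate(config)
  res <- fit_model_set(data, config)

  out <- function(f) file.path(config$output_dir, f)
  utils::write.csv(res$table, out("comparison_table.csv"), row.names = FALSE)
  for (m in names(res$fits)) {
    if (m == "I") {
      for (p in names(res$fits$I))
        write_fit_log(res$fits$I[[p]], out(sprintf("fit_model_I_%s.log", p)))
    } else write_fit_log(res$fits[[m]], out(sprintf("fit_model_%s.log", m)))
  }
  if (!is.null(res$fits$IV)) {
    for (fx in c("pm10", "no2", "so2")) {
      surf <- rr_surface(res$fits$IV, fixed_pollutant = fx)
      write_rr_surface(surf, out(sprintf("model_iv_surface_%s_fixed.csv", fx)))
    }
    for (p in c("pm10", "no2", "so2")) {
      crv <- exposure_response_curve(res$fits$IV, p)
      utils::write.csv(crv, out(sprintf("model_iv_curve_%s.csv", p)),
                       row.names = FALSE)
    }
  }
  report <- list(
    provenance = list(config_hash = config_hash(config), seed = config$seed,
                      package = "temort",
                      version = as.character(utils::packageVersion("temort"))),
    n_days = nrow(data),
    dropped_days = {
      ff <- if (length(res$fits)) res$fits[[1L]] else NULL
      if (inherits(ff, "temort_fit")) length(ff$design$dropped_days)
      else if (is.list(ff) && inherits(ff[[1L]], "temort_fit"))
        length(ff[[1L]]$design$dropped_days)
      else NA
    },
    diagnostics = res$diagnostics,
    failures = res$failures,
    table = res$table)
  jsonlite::write_json(report, out("report.json"), digits = NA,
                       auto_unbox = TRUE, force = TRUE)
  invisible(report)
}

#' Stratified analyses
#'
#' Runs the full model set independently on each stratum dataset (the
#' strata are separate series, e.g. sex- or age-specific death counts with
#' shared exposures) and tabulates the tensor-model combined effects per
#' stratum. Strata with fewer than 365 days of counts are skipped with a
#' warning.
#'
#' @param config a [run_config()].
#' @param strata_datasets named list of daily data.frames.
#' @return named list of per-stratum results (as [fit_model_set()]), with a
#'   `summary` data.frame of combined tensor-model effects.
#' @export
run_stratified <- function(config, strata_datasets) {
  if (is.null(names(strata_datasets)) || any(names(strata_datasets) == ""))
    stop("strata_datasets must be a named list")
  results <- list(); rows <- list()
  for (s in names(strata_datasets)) {
    d <- strata_datasets[[s]]
    validate_daily_data(d)
    if (sum(!is.na(d$deaths)) < 365L) {
      warning("stratum '", s, "' has fewer than 365 days of counts; skipped")
      next
    }
    results[[s]] <- fit_model_set(d, config)
    tb <- results[[s]]$table
    cmb <- tb[tb$model == "IV" & tb$pollutant == "combined", , drop = FALSE]
    if (nrow(cmb))
      rows[[s]] <- data.frame(stratum = s,
                              deaths = sum(d$deaths, na.rm = TRUE), cmb)
  }
  if (!length(results)) stop("no stratum was large enough to analyse")
  attr(results, "summary") <- if (length(rows)) do.call(rbind, rows) else NULL
  results
}

#' Lag sensitivity analysis
#'
#' Refits the full model set at each pollutant moving-average window in
#' `config$sensitivity_lags` on the same dataset and returns the paired
#' comparison of effect tables.
#'
#' @param config a [run_config()].
#' @param data optional dataset (defaults to the config's input/simulation).
#' @return list with per-lag `fit_model_set` results and a combined `table`
#'   carrying a `lag` column.
#' @export
run_lag_sensitivity <- function(config, data = NULL) {
  lags <- config$sensitivity_lags
  if (!length(lags)) stop("sensitivity_lags is empty")
  if (is.null(data)) data <- load_or_simulate(config)
  keys <- make.unique(vapply(lags, function(lg)
    sprintf("lag%d-%d", min(lg), max(lg)), character(1L)))
  per_lag <- list(); tabs <- list()
  for (i in seq_along(lags)) {
    per_lag[[keys[i]]] <- fit_model_set(data, config,
                                        pollutant_lag = lags[[i]])
    tabs[[keys[i]]] <- cbind(lag = sub("\\.[0-9]+$", "", keys[i]),
                             per_lag[[keys[i]]]$table)
  }
  list(per_lag = per_lag, table = do.call(rbind, tabs))
}
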