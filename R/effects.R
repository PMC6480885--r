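#' Excess risk from a rate ratio
#'
#' `ER = (RR - 1) * 100`, the percentage increase in mortality.
#' @param rr positive rate ratio(s).
#' @return excess risk in percent.
#' @export
er_from_rr <- function(rr) {
  if (any(rr <= 0)) stop("rate ratios must be positive")
  (rr - 1) * 100
}

new_effect_estimate <- function(log_rr, se, contrast, model,
                                conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rr <- exp(log_rr)
  structure(list(rr = rr,
                 er_percent = (rr - 1) * 100,
                 se_log_rr = se,
                 ci_low = exp(log_rr - z * se),
                 ci_high = exp(log_rr + z * se),
                 er_ci_low = (exp(log_rr - z * se) - 1) * 100,
                 er_ci_high = (exp(log_rr + z * se) - 1) * 100,
                 contrast = contrast, model = model,
                 conf_level = conf_level),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("Model %s  RR = %.4f (%.4f-%.4f)  ER = %.2f%% (%.2f-%.2f%%)\n",
              x$model, x$rr, x$ci_low, x$ci_high,
              x$er_percent, x$er_ci_low, x$er_ci_high))
  invisible(x)
}

pollutant_coef_index <- function(fit, pollutant) {
  idx <- fit$design$column_map[[pollutant]]
  if (is.null(idx)) stop("pollutant '", pollutant, "' absent from the fit")
  idx
}

#' Combined rate ratio for log-linear pollutant terms
#'
#' For the single-pollutant model (three separate fits) and the
#' three-pollutant non-interaction model: the combined log rate ratio is
#' the sum of each pollutant's coefficient times its increment, with
#' delta-method variance `d' Sigma d` from the coefficient covariance
#' (across separate single-pollutant fits the between-fit covariances are
#' zero, so variances add).
#'
#' @param fits a single Model II `temort_fit`, or a list of Model I fits.
#' @param increments named increments (ug/m3) per pollutant; defaults to
#'   the IQR of the lagged exposure recorded on each design.
#' @return an `effect_estimate`.
#' @export
combined_rr_linear <- function(fits, increments = NULL) {
  if (inherits(fits, "temort_fit")) fits <- list(fits)
  log_rr <- 0; var_lr <- 0
  contrast <- list()
  for (f in fits) {
    polls <- intersect(c("pm10", "no2", "so2"), names(f$design$column_map))
    for (p in polls) {
      d <- if (!is.null(increments)) {
        if (is.null(increments[[p]]))
          stop("no increment supplied for pollutant '", p, "'")
        increments[[p]]
      } else f$design$increments[[p]]
      idx <- pollutant_coef_index(f, p)
      log_rr <- log_rr + f$coefficients[idx] * d
      contrast[[p]] <- d
    }
    idxs <- unlist(lapply(polls, pollutant_coef_index, fit = f))
    dvec <- vapply(polls, function(p) contrast[[p]], numeric(1))
    var_lr <- var_lr + drop(t(dvec) %*%
      f$covariance[idxs, idxs, drop = FALSE] %*% dvec)
  }
  model <- if (length(fits) > 1L) "I" else fits[[1L]]$design$model
  new_effect_estimate(unname(log_rr), sqrt(var_lr),
                      list(increments = contrast), model)
}

#' Combined rate ratio under first-order interactions
#'
#' For the three-pollutant interaction model: the log rate ratio between
#' two exposure profiles is the sum of main-effect coefficients times the
#' level differences plus each interaction coefficient times the difference
#' of the corresponding products; the variance is `c' Sigma c` over the
#' full main + interaction contrast vector.
#'
#' @param fit a Model III `temort_fit`.
#' @param from_levels,to_levels named 3-vectors (`pm10`, `no2`, `so2`) of
#'   lagged-exposure levels; default the 25th percentile and 25th + IQR.
#' @return an `effect_estimate`.
#' @export
combined_rr_interaction <- function(fit, from_levels = NULL,
                                    to_levels = NULL) {
  if (fit$design$model != "III")
    stop("combined_rr_interaction needs a Model III fit")
  ref <- fit$design$reference_levels
  if (is.null(from_levels)) from_levels <- ref
  if (is.null(to_levels)) to_levels <- ref + fit$design$increments
  from_levels <- from_levels[c("pm10", "no2", "so2")]
  to_levels <- to_levels[c("pm10", "no2", "so2")]
  rng <- apply(fit$design$exposures, 2L, range)
  if (any(to_levels < rng[1L, ] | to_levels > rng[2L, ]) ||
      any(from_levels < rng[1L, ] | from_levels > rng[2L, ]))
    warning("contrast levels outside the observed exposure range")

  p <- length(fit$coefficients)
  cvec <- numeric(p)
  for (pl in c("pm10", "no2", "so2"))
    cvec[pollutant_coef_index(fit, pl)] <-
      to_levels[[pl]] - from_levels[[pl]]
  pairs <- list(pm10_no2 = c("pm10", "no2"),
                pm10_so2 = c("pm10", "so2"),
                no2_so2 = c("no2", "so2"))
  icol <- fit$design$column_map$interactions
  for (nm in names(pairs)) {
    a <- pairs[[nm]][1L]; b <- pairs[[nm]][2L]
    cvec[icol[[nm]]] <- to_levels[[a]] * to_levels[[b]] -
      from_levels[[a]] * from_levels[[b]]
  }
  log_rr <- drop(crossprod(cvec, fit$coefficients))
  se <- sqrt(drop(t(cvec) %*% fit$covariance %*% cvec))
  new_effect_estimate(log_rr, se,
                      list(from = from_levels, to = to_levels), "III")
}

#' Rate ratio of a tensor-smooth contrast
#'
#' For the tensor-product model: evaluates the centered tensor basis at the
#' `to` and `from` exposure profiles, takes the difference row `te`, and
#' returns `RR = exp(te' v)` with delta-method standard error
#' `sqrt(te' Sigma te)` restricted to the smooth coefficient block (the
#' confounder columns cancel exactly in the contrast). Levels more than 10%
#' of the observed range beyond the training range are refused: tensor
#' splines extrapolate wildly.
#'
#' @param fit a Model IV `temort_fit`.
#' @param from_levels,to_levels named 3-vectors (`pm10`, `no2`, `so2`);
#'   default 25th percentile and 25th + IQR of the lagged exposures.
#' @return an `effect_estimate`.
#' @export
rr_tensor <- function(fit, from_levels = NULL, to_levels = NULL) {
  if (fit$design$model != "IV")
    stop("rr_tensor needs a Model IV fit")
  smooth <- fit$design$smooth
  ref <- fit$design$reference_levels
  if (is.null(from_levels)) from_levels <- ref
  if (is.null(to_levels)) to_levels <- ref + fit$design$increments
  from_levels <- from_levels[c("pm10", "no2", "so2")]
  to_levels <- to_levels[c("pm10", "no2", "so2")]

  rng <- apply(fit$design$exposures, 2L, range)
  guard <- 0.10 * (rng[2L, ] - rng[1L, ])
  out_of_range <- function(lv)
    any(lv < rng[1L, ] - guard | lv > rng[2L, ] + guard)
  if (out_of_range(unlist(from_levels)) || out_of_range(unlist(to_levels)))
    stop("contrast levels beyond 10% range inflation; refusing to extrapolate")

  te <- tensor_row_centered(smooth, unlist(to_levels)) -
    tensor_row_centered(smooth, unlist(from_levels))
  idx <- fit$design$column_map$smooth
  v <- fit$coefficients[idx]
  Sig <- fit$covariance[idx, idx, drop = FALSE]
  log_rr <- drop(crossprod(te, v))
  se <- sqrt(max(0, drop(t(te) %*% Sig %*% te)))
  new_effect_estimate(log_rr, se,
                      list(from = from_levels, to = to_levels), "IV")
}

#' Combined or single-pollutant effect for any fitted model
#'
#' Dispatcher used by the pipeline: the IQR-increase contrast in the given
#' pollutants (all three for the combined effect), others held at their
#' 25th-percentile reference.
#' @param fit a `temort_fit` (Model II, III or IV) or list of Model I fits.
#' @param pollutants which pollutants move from the 25th to the 75th
#'   percentile (default all three).
#' @return an `effect_estimate`.
#' @export
iqr_effect <- function(fit, pollutants = c("pm10", "no2", "so2")) {
  if (!inherits(fit, "temort_fit")) { # list of single-pollutant fits
    fits <- Filter(function(f)
      any(pollutants %in% names(f$design$column_map)), fit)
    if (!length(fits)) stop("no fit carries the requested pollutants")
    est <- combined_rr_linear(fits)
    est$model <- "I"
    return(est)
  }
  model <- fit$design$model
  if (model %in% c("I", "II")) {
    incs <- as.list(fit$design$increments)
    for (p in setdiff(names(incs), pollutants)) incs[[p]] <- 0
    return(combined_rr_linear(fit, increments = incs))
  }
  ref <- fit$design$reference_levels
  to <- ref
  to[pollutants] <- ref[pollutants] + fit$design$increments[pollutants]
  if (model == "III") combined_rr_interaction(fit, ref, to)
  else rr_tensor(fit, ref, to)
}

#' Rate-ratio surface over two pollutants
#'
#' Fixes one pollutant at its reference level (the 25th percentile of the
#' lagged exposure) and evaluates the tensor-smooth rate ratio, relative to
#' the joint reference, on a grid spanning the central 1st-99th percentile
#' range of the two free pollutants. The reference level is inserted into
#' each grid so the surface equals 1 exactly at the reference point.
#'
#' @param fit a Model IV `temort_fit`.
#' @param fixed_pollutant `"pm10"`, `"no2"` or `"so2"`.
#' @param grid_resolution points per free axis.
#' @return an object of class `rr_surface`: `grid1`, `grid2` (levels),
#'   `rr`, `se` (matrices), `free` (names), `fixed` (name and level).
#' @export
rr_surface <- function(fit, fixed_pollutant = "so2", grid_resolution = 20L) {
  if (fit$design$model != "IV") stop("rr_surface needs a Model IV fit")
  fixed_pollutant <- match.arg(fixed_pollutant, c("pm10", "no2", "so2"))
  free <- setdiff(c("pm10", "no2", "so2"), fixed_pollutant)
  ref <- fit$design$reference_levels
  ex <- fit$design$exposures
  mk_grid <- function(p) {
    q <- stats::quantile(ex[, p], c(0.01, 0.99), names = FALSE)
    sort(unique(c(seq(q[1L], q[2L], length.out = grid_resolution), ref[[p]])))
  }
  g1 <- mk_grid(free[1L]); g2 <- mk_grid(free[2L])
  rr <- se <- matrix(NA_real_, length(g1), length(g2))
  for (i in seq_along(g1)) for (j in seq_along(g2)) {
    to <- ref
    to[[free[1L]]] <- g1[i]; to[[free[2L]]] <- g2[j]
    est <- rr_tensor(fit, ref, to)
    rr[i, j] <- est$rr; se[i, j] <- est$se_log_rr
  }
  structure(list(grid1 = g1, grid2 = g2, rr = rr, se = se,
                 free = free,
                 fixed = stats::setNames(ref[[fixed_pollutant]],
                                         fixed_pollutant)),
            class = "rr_surface")
}

#' Export / reload a rate-ratio surface as long-format CSV
#'
#' Columns `level1, level2, rr, se`; levels are written at full precision
#' so a reloaded grid reproduces the exported one exactly.
#' @param surface an `rr_surface`.
#' @param path file path.
#' @export
write_rr_surface <- function(surface, path) {
  long <- expand.grid(level1 = surface$grid1, level2 = surface$grid2,
                      KEEP.OUT.ATTRS = FALSE)
  long$rr <- as.vector(surface$rr)
  long$se <- as.vector(surface$se)
  header <- sprintf("# free: %s,%s fixed: %s=%.17g",
                    surface$free[1L], surface$free[2L],
                    names(surface$fixed), surface$fixed)
  con <- file(path, "w")
  writeLines(header, con)
  writeLines("level1,level2,rr,se", con)
  writeLines(sprintf("%.17g,%.17g,%.17g,%.17g",
                     long$level1, long$level2, long$rr, long$se), con)
  close(con)
  invisible(path)
}

#' @rdname write_rr_surface
#' @export
read_rr_surface_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Exposure-response curve for one pollutant
#'
#' Rate ratio (with pointwise 95% bands) as the pollutant moves across its
#' central range, the other two held at their 25th-percentile reference.
#' Log-linear by construction for Models I-III; evaluated through the
#' tensor smooth for Model IV.
#'
#' @param fit a `temort_fit` (or, for Model I, the fit for this pollutant).
#' @param pollutant `"pm10"`, `"no2"` or `"so2"`.
#' @param n_points number of curve points.
#' @return a data.frame `level`, `rr`, `ci_low`, `ci_high`.
#' @export
exposure_response_curve <- function(fit, pollutant, n_points = 50L) {
  pollutant <- match.arg(pollutant, c("pm10", "no2", "so2"))
  design <- fit$design
  ex <- design$exposures
  q <- stats::quantile(ex[, pollutant], c(0.01, 0.99), names = FALSE)
  ref_p <- design$reference_levels[[pollutant]]
  levels <- sort(unique(c(seq(q[1L], q[2L], length.out = n_points), ref_p)))
  z <- stats::qnorm(0.975)
  if (design$model %in% c("I", "II")) {
    idx <- pollutant_coef_index(fit, pollutant)
    b <- fit$coefficients[idx]
    s <- sqrt(fit$covariance[idx, idx])
    lr <- b * (levels - ref_p)
    se <- abs(levels - ref_p) * s
  } else if (design$model == "III") {
    ests <- lapply(levels, function(lv) {
      to <- design$reference_levels; to[[pollutant]] <- lv
      suppressWarnings(
        combined_rr_interaction(fit, design$reference_levels, to))
    })
    lr <- log(vapply(ests, `[[`, numeric(1), "rr"))
    se <- vapply(ests, `[[`, numeric(1), "se_log_rr")
  } else {
    ests <- lapply(levels, function(lv) {
      to <- design$reference_levels; to[[pollutant]] <- lv
      rr_tensor(fit, design$reference_levels, to)
    })
    lr <- log(vapply(ests, `[[`, numeric(1), "rr"))
    se <- vapply(ests, `[[`, numeric(1), "se_log_rr")
  }
  data.frame(level = levels, rr = exp(lr),
             ci_low = exp(lr - z * se), ci_high = exp(lr + z * se))
}
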