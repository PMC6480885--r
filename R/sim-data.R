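#' Simulation configuration for synthetic daily mortality/pollution series
#'
#' Defines the generative law for a synthetic city-level daily time series
#' with the statistical structure typical of multi-pollutant mortality
#' studies: three right-skewed, strongly rank-correlated pollutant series
#' sharing an annual seasonal cycle with mortality, seasonal weather, and
#' overdispersed daily death counts driven by a known true log-rate surface.
#'
#' Pollutants are generated as exponentiated Gaussian latents (log-normal
#' marginals guarantee positivity and right skew) with a Gaussian copula.
#' Rank correlations are targeted through the exact Gaussian-copula
#' conversion \eqn{\rho_{Pearson} = 2\sin(\pi\rho_{Spearman}/6)}; the share
#' of association contributed by the common deterministic annual sinusoid is
#' removed analytically from the residual latent correlation, so the total
#' association of the generated series matches the configured targets.
#'
#' @param n_days number of consecutive days (>= 400).
#' @param start_date first calendar date of the series.
#' @param pollutant_means named 3-vector, mean concentration in ug/m3 for
#'   `pm10`, `no2`, `so2`.
#' @param pollutant_log_sds named 3-vector, standard deviation of the
#'   Gaussian latent (log scale) for each pollutant.
#' @param latent_correlation 3x3 symmetric positive-definite matrix of target
#'   Spearman rank correlations between pollutants (unit diagonal), in the
#'   order pm10, no2, so2.
#' @param seasonal_amplitudes named list/vector of annual-sinusoid
#'   amplitudes: `pollutants` (log scale, one shared value or 3-vector),
#'   `temperature` (degrees C), `mortality` (log scale).
#' @param seasonal_phase peak day-of-year of the pollutant/mortality
#'   sinusoid (default 15, a winter peak); temperature peaks half a year
#'   away. The phase convention is configurable and carries no claim about
#'   any particular city's seasons.
#' @param baseline_rate expected deaths/day at reference conditions.
#' @param dispersion overdispersion factor `phi_true` (variance = phi * mean),
#'   must be >= 1; 1 gives Poisson counts.
#' @param true_effect specification of the true pollutant log-rate term, a
#'   list with `type` one of `"linear"` (field `slopes`, named 3-vector per
#'   ug/m3), `"interaction"` (`slopes` plus named `pairwise` products
#'   `pm10_no2`, `pm10_so2`, `no2_so2`), `"surface"` (field `fun`, a
#'   function of three equal-length vectors pm10, no2, so2 returning the
#'   log-rate contribution), or `"null"`. The term is evaluated on
#'   moving-average exposures with window `effect_lag` (inclusive lag range,
#'   default 0:2).
#' @param effect_lag integer vector of lags entering the true-effect moving
#'   average, default `0:2`.
#'
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_days = 2922L,
                              start_date = as.Date("2005-01-01"),
                              pollutant_means = c(pm10 = 74.9, no2 = 62.4, so2 = 41.0),
                              pollutant_log_sds = c(pm10 = 0.497, no2 = 0.429, so2 = 0.655),
                              latent_correlation = default_spearman_targets(),
                              seasonal_amplitudes = list(pollutants = 0.22,
                                                         temperature = 7.5,
                                                         mortality = 0.12),
                              seasonal_phase = 15,
                              baseline_rate = 66,
                              dispersion = 1.5,
                              true_effect = list(type = "linear",
                                                 slopes = c(pm10 = 3e-4, no2 = 4e-4, so2 = 4e-4)),
                              effect_lag = 0:2) {
  n_days <- as.integer(n_days)
  if (n_days < 400L) stop("n_days must be >= 400")
  if (dispersion < 1) stop("dispersion must be >= 1 (quasi-Poisson factor)")
  stopifnot(length(pollutant_means) == 3L, length(pollutant_log_sds) == 3L)
  latent_correlation <- as.matrix(latent_correlation)
  check_correlation_matrix(latent_correlation)
  amp <- seasonal_amplitudes
  if (is.null(names(amp))) stop("seasonal_amplitudes must be named")
  amp_poll <- rep_len(amp$pollutants %||% 0, 3L)
  true_effect <- validate_true_effect(true_effect)
  structure(list(
    n_days = n_days,
    start_date = as.Date(start_date),
    pollutant_means = unname(pollutant_means),
    pollutant_log_sds = unname(pollutant_log_sds),
    latent_correlation = latent_correlation,
    amp_poll = amp_poll,
    amp_temp = amp$temperature %||% 0,
    amp_mort = amp$mortality %||% 0,
    seasonal_phase = seasonal_phase,
    baseline_rate = baseline_rate,
    dispersion = dispersion,
    true_effect = true_effect,
    effect_lag = as.integer(effect_lag)
  ), class = "simulation_config")
}

default_spearman_targets <- function() {
  m <- matrix(c(1, 0.83, 0.60,
                0.83, 1, 0.65,
                0.60, 0.65, 1), 3, 3)
  dimnames(m) <- list(c("pm10", "no2", "so2"), c("pm10", "no2", "so2"))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_correlation_matrix <- function(m) {
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("correlation matrix must be symmetric")
  if (any(abs(diag(m) - 1) > 1e-8))
    stop("correlation matrix must have unit diagonal")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("correlation matrix is not positive definite (min eigenvalue ",
         format(min(ev)), ")")
  invisible(m)
}

validate_true_effect <- function(te) {
  if (is.null(te$type)) stop("true_effect must have a 'type'")
  te$type <- match.arg(te$type, c("linear", "interaction", "surface", "null"))
  if (te$type == "null") te$slopes <- c(pm10 = 0, no2 = 0, so2 = 0)
  if (te$type %in% c("linear", "interaction")) {
    if (is.null(te$slopes) || length(te$slopes) != 3L)
      stop("true_effect$slopes must be a named 3-vector")
  }
  if (te$type == "interaction" && is.null(te$pairwise))
    te$pairwise <- c(pm10_no2 = 0, pm10_so2 = 0, no2_so2 = 0)
  if (te$type == "surface" && !is.function(te$fun))
    stop("true_effect$fun must be a function(pm10, no2, so2)")
  te
}

#' Read a simulation configuration from a JSON file
#'
#' Key names match the arguments of [simulation_config()].
#' @param path path to a JSON file.
#' @return a `simulation_config`.
#' @export
simulation_config_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$latent_correlation))
    raw$latent_correlation <- matrix(unlist(raw$latent_correlation), 3, 3)
  if (!is.null(raw$start_date)) raw$start_date <- as.Date(raw$start_date)
  do.call(simulation_config, raw)
}

annual_sinusoid <- function(day_index, phase_day, period = 365.25) {
  cos(2 * pi * (day_index - phase_day) / period)
}

#' Generate correlated seasonal exposure and weather series
#'
#' Draws the pollutant, weather and calendar part of a daily dataset:
#' log-normal pollutants with a Gaussian copula hitting the configured
#' Spearman targets, an annual temperature cycle, humidity and pressure with
#' mild seasonality, day-of-week and a synthetic holiday flag.
#'
#' @param config a [simulation_config()].
#' @param seed integer RNG seed; the output is a deterministic function of
#'   `(config, seed)`.
#' @return a data.frame with columns date, pm10, no2, so2, temp, rh,
#'   pressure, dow, holiday.
#' @export
generate_exposures <- function(config, seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(as.integer(seed))
  n <- config$n_days
  t_idx <- seq_len(n)
  date <- config$start_date + (t_idx - 1L)

  sig <- config$pollutant_log_sds
  a <- config$amp_poll
  s <- annual_sinusoid(t_idx, config$seasonal_phase)

  ## residual latent correlation: strip the deterministic seasonal share
  ## (Var of the sinusoid over whole years is a^2/2) from the total
  ## Gaussian-equivalent target 2*sin(pi*rho_s/6)
  rho_tot <- 2 * sin(pi * config$latent_correlation / 6)
  tot_sd <- sqrt(sig^2 + a^2 / 2)
  rho_eps <- matrix(1, 3, 3)
  for (i in 1:2) for (j in (i + 1):3) {
    r <- (rho_tot[i, j] * tot_sd[i] * tot_sd[j] - a[i] * a[j] / 2) /
      (sig[i] * sig[j])
    rho_eps[i, j] <- rho_eps[j, i] <- r
  }
  if (any(abs(rho_eps) > 1)) {
    stop("seasonal amplitudes too large for the requested rank correlations")
  }
  check_correlation_matrix(rho_eps)

  L <- chol(rho_eps)
  eps <- matrix(stats::rnorm(n * 3L), n, 3L) %*% L
  latent <- sweep(eps, 2L, sig, `*`) + outer(s, a)
  ## E[exp(a*s)] over whole years is besselI(a, 0); centre so that the
  ## marginal means match the configured concentrations
  mu_log <- log(config$pollutant_means) - sig^2 / 2 - log(besselI(a, 0))
  conc <- exp(sweep(latent, 2L, mu_log, `+`))

  temp <- 22.5 - config$amp_temp * s + stats::rnorm(n, sd = 3)
  rh <- pmin(100, pmax(0, 72.9 + 4 * s + stats::rnorm(n, sd = 11)))
  pressure <- 1007.4 + 6 * s + stats::rnorm(n, sd = 4)

  dow <- factor(weekdays(date, abbreviate = TRUE),
                levels = weekdays(as.Date("2024-01-01") + 0:6, abbreviate = TRUE))
  doy <- as.integer(strftime(date, "%j"))
  holiday <- as.integer(doy %in% c(1L, 2L, 3L, 94L, 121L, 122L, 123L,
                                   166L, 258L, 274L, 275L, 276L))

  data.frame(date = date,
             pm10 = conc[, 1L], no2 = conc[, 2L], so2 = conc[, 3L],
             temp = temp, rh = rh, pressure = pressure,
             dow = dow, holiday = holiday)
}

true_log_effect <- function(exposures, config) {
  w <- length(config$effect_lag)
  ## partial-window mean during warm-up so every day has a defined truth
  ma_partial <- function(x) {
    cs <- cumsum(x)
    full <- (cs - c(rep(0, w), utils::head(cs, -w))) / w
    if (w > 1L) full[seq_len(w - 1L)] <- cs[seq_len(w - 1L)] / seq_len(w - 1L)
    full
  }
  pm <- ma_partial(exposures$pm10)
  no <- ma_partial(exposures$no2)
  so <- ma_partial(exposures$so2)
  te <- config$true_effect
  eff <- switch(te$type,
    null = rep(0, nrow(exposures)),
    linear = te$slopes[["pm10"]] * pm + te$slopes[["no2"]] * no +
      te$slopes[["so2"]] * so,
    interaction = te$slopes[["pm10"]] * pm + te$slopes[["no2"]] * no +
      te$slopes[["so2"]] * so +
      te$pairwise[["pm10_no2"]] * pm * no +
      te$pairwise[["pm10_so2"]] * pm * so +
      te$pairwise[["no2_so2"]] * no * so,
    surface = te$fun(pm, no, so)
  )
  list(effect = eff, ma = data.frame(pm10 = pm, no2 = no, so2 = so))
}

#' Generate overdispersed daily death counts
#'
#' Adds counts to an exposure table: the true mean is
#' `mu_t = exp(log(baseline) + seasonal + effect(lagged exposures))` and
#' counts are Poisson when `dispersion == 1` or negative binomial
#' moment-matched to variance `dispersion * mu_t` otherwise. The true
#' per-day mean is returned in column `mu_true` for parameter-recovery
#' oracles (it is not part of the on-disk schema).
#'
#' @param exposures output of [generate_exposures()].
#' @param config the same [simulation_config()].
#' @param seed integer RNG seed for the count draw.
#' @return the exposure data.frame with `deaths` and `mu_true` columns added.
#' @export
generate_mortality <- function(exposures, config, seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(as.integer(seed))
  n <- nrow(exposures)
  t_idx <- seq_len(n)
  s <- annual_sinusoid(t_idx, config$seasonal_phase)
  eff <- true_log_effect(exposures, config)
  eta <- log(config$baseline_rate) + config$amp_mort * s + eff$effect
  if (any(eta > 30)) {
    bad <- which(eta > 30)[1L]
    stop("true log-rate exceeds 30 on day ", bad, " (",
         format(exposures$date[bad]), "); check true_effect scaling")
  }
  mu <- exp(eta)
  phi <- config$dispersion
  deaths <- if (phi == 1) {
    stats::rpois(n, mu)
  } else {
    ## NB with size mu/(phi-1): variance mu + mu^2/size = phi * mu
    stats::rnbinom(n, size = mu / (phi - 1), mu = mu)
  }
  out <- exposures
  out$deaths <- as.integer(deaths)
  out$mu_true <- mu
  out
}

#' Simulate a complete daily dataset
#'
#' Convenience wrapper: exposures then mortality, with sub-seeds derived
#' from one master seed.
#' @inheritParams generate_exposures
#' @param n_missing optional number of days whose pollutant values are set
#'   missing afterwards (see [inject_missing()]).
#' @return a complete daily data.frame (with `mu_true`).
#' @export
simulate_daily_data <- function(config, seed, n_missing = 0L) {
  seed <- as.integer(seed)
  dat <- generate_exposures(config, seed = seed)
  dat <- generate_mortality(dat, config, seed = seed + 1L)
  if (n_missing > 0L) dat <- inject_missing(dat, n_missing, seed = seed + 2L)
  dat
}

#' Set pollutant values missing on randomly chosen days
#'
#' Emulates the sporadic monitoring gaps of real city-level series: all
#' three pollutants are set missing on the sampled days; counts and weather
#' are untouched.
#'
#' @param data a daily data.frame.
#' @param n_missing number of days to blank (must be under 5 percent of days).
#' @param seed integer RNG seed.
#' @return the data.frame with missing pollutant days.
#' @export
inject_missing <- function(data, n_missing, seed) {
  n_missing <- as.integer(n_missing)
  if (n_missing == 0L) return(data)
  if (n_missing >= 0.05 * nrow(data))
    stop("n_missing must be below 5% of days")
  set.seed(as.integer(seed))
  days <- sample.int(nrow(data), n_missing)
  data$pm10[days] <- NA_real_
  data$no2[days] <- NA_real_
  data$so2[days] <- NA_real_
  data
}

#' Validate a daily dataset
#'
#' Checks the container invariants: equal-length series, strictly
#' consecutive dates, nonnegative integer counts, humidity within 0-100.
#' @param data a daily data.frame.
#' @return the data invisibly; errors describe the first violated invariant.
#' @export
validate_daily_data <- function(data) {
  needed <- c("date", "deaths", "pm10", "no2", "so2", "temp", "rh",
              "pressure", "dow", "holiday")
  miss <- setdiff(needed, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- as.Date(data$date)
  if (any(diff(as.integer(d)) != 1L))
    stop("dates must be consecutive calendar days")
  if (any(data$deaths < 0 | data$deaths != round(data$deaths), na.rm = TRUE))
    stop("deaths must be nonnegative integers")
  if (any(data$rh < 0 | data$rh > 100, na.rm = TRUE))
    stop("humidity must lie in [0, 100]")
  for (p in c("pm10", "no2", "so2"))
    if (any(data[[p]] < 0, na.rm = TRUE)) stop(p, " must be nonnegative")
  invisible(data)
}

#' Write / read the canonical daily CSV schema
#'
#' Columns: date (ISO-8601), deaths, pm10, no2, so2, temp, rh, pressure,
#' holiday (0/1). Missing values are empty fields; day-of-week is derived
#' from the date on read.
#' @param data a daily data.frame.
#' @param path file path.
#' @export
write_daily_csv <- function(data, path) {
  out <- data.frame(date = format(as.Date(data$date), "%Y-%m-%d"),
                    deaths = data$deaths,
                    pm10 = data$pm10, no2 = data$no2, so2 = data$so2,
                    temp = data$temp, rh = data$rh, pressure = data$pressure,
                    holiday = as.integer(data$holiday))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_daily_csv
#' @export
read_daily_csv <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  dat$date <- as.Date(dat$date)
  dat$dow <- factor(weekdays(dat$date, abbreviate = TRUE),
                    levels = weekdays(as.Date("2024-01-01") + 0:6,
                                      abbreviate = TRUE))
  validate_daily_data(dat)
  dat
}
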