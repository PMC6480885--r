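#' Control parameters for the penalized IRLS fit
#' @param epsilon relative penalized-deviance convergence tolerance.
#' @param maxit maximum IRLS iterations.
#' @param max_halvings maximum step-halvings per iteration.
#' @return a list of control values.
#' @export
pirls_control <- function(epsilon = 1e-8, maxit = 200L, max_halvings = 30L) {
  list(epsilon = epsilon, maxit = as.integer(maxit),
       max_halvings = as.integer(max_halvings))
}

quasi_poisson_deviance <- function(y, mu) {
  r <- y - mu
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(t1 - r)
}

## embed the penalty blocks into p x p and sum with weights lambda
penalty_total <- function(design, lambdas) {
  p <- ncol(design$X)
  S <- matrix(0, p, p)
  if (!length(design$penalties)) return(S)
  lambdas <- check_lambdas(design, lambdas)
  for (i in seq_along(design$penalties)) {
    pen <- design$penalties[[i]]
    S[pen$cols, pen$cols] <- S[pen$cols, pen$cols] + lambdas[i] * pen$S
  }
  S
}

check_lambdas <- function(design, lambdas) {
  k <- length(design$penalties)
  if (length(lambdas) == 1L && k > 1L) lambdas <- rep(lambdas, k)
  if (length(lambdas) != k)
    stop("need ", k, " smoothing parameters, got ", length(lambdas))
  if (any(lambdas < 0)) stop("smoothing parameters must be nonnegative")
  lambdas
}

#' Penalized quasi-Poisson fit by iteratively re-weighted least squares
#'
#' Maximizes the quasi-Poisson log-likelihood minus the quadratic roughness
#' penalty `sum_m lambda_m beta' S_m beta` for fixed smoothing parameters,
#' by penalized iteratively re-weighted least squares with step-halving (the
#' penalized deviance is non-increasing across iterations). The dispersion
#' is estimated afterwards from Pearson residuals and never enters the mean
#' fit — under quasi-likelihood the mean structure is free of the scale.
#'
#' @param design a `pollution_design` (or any list with `X`, `y`,
#'   `penalties` as documented there).
#' @param lambdas nonnegative vector, one per penalty in `design$penalties`
#'   (may be empty for the unpenalized Models I-III).
#' @param control see [pirls_control()].
#' @param cov_type `"sandwich"` (default) for the frequentist form
#'   `phi F A F` with `F = (X'WX + S_lambda)^-1`, `A = X'WX`, or `"bayes"`
#'   for the posterior-style `phi F`.
#' @return an object of class `temort_fit`: coefficients, covariance,
#'   dispersion, lambdas, edf, gcv, fitted_mu and diagnostics; the design
#'   is kept on the fit for downstream effect estimation.
#' @export
pirls_fit <- function(design, lambdas = numeric(0),
                      control = pirls_control(),
                      cov_type = c("sandwich", "bayes")) {
  cov_type <- match.arg(cov_type)
  X <- design$X
  y <- design$y
  n <- nrow(X); p <- ncol(X)
  if (any(y < 0)) stop("counts must be nonnegative")
  lambdas <- if (length(design$penalties)) check_lambdas(design, lambdas)
             else numeric(0)
  S_lam <- penalty_total(design, lambdas)

  mu <- y + 0.5
  eta <- log(mu)
  beta <- rep(0, p)
  pdev <- quasi_poisson_deviance(y, mu) # beta = 0 penalty-free
  trace <- numeric(0)
  converged <- FALSE

  for (it in seq_len(control$maxit)) {
    W <- mu
    z <- eta + (y - mu) / mu
    sw <- sqrt(W)
    Xw <- X * sw
    A <- crossprod(Xw)
    H <- A + S_lam
    R <- tryCatch(chol(H), error = function(e)
      stop("rank-deficient penalized Hessian at iteration ", it,
           ": ", conditionMessage(e)))
    beta_new <- backsolve(R, forwardsolve(t(R), crossprod(Xw, sw * z)))

    step <- 1
    for (h in seq_len(control$max_halvings + 1L)) {
      beta_try <- beta + step * (beta_new - beta)
      eta_try <- drop(X %*% beta_try)
      if (max(eta_try) < 35) {
        mu_try <- exp(eta_try)
        pdev_try <- quasi_poisson_deviance(y, mu_try) +
          drop(crossprod(beta_try, S_lam %*% beta_try))
        if (is.finite(pdev_try) && (pdev_try <= pdev + 1e-12 || it == 1L))
          break
      }
      step <- step / 2
      if (h > control$max_halvings)
        stop("step-halving failed at iteration ", it,
             "; deviance trace: ", paste(signif(trace, 8), collapse = ", "))
    }
    beta <- beta_try; eta <- eta_try; mu <- mu_try
    delta <- abs(pdev - pdev_try)
    pdev <- pdev_try
    trace <- c(trace, pdev)
    if (delta < control$epsilon * (abs(pdev) + 0.1)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("PIRLS did not converge in ", control$maxit,
         " iterations; penalized deviance trace (last 10): ",
         paste(signif(utils::tail(trace, 10), 8), collapse = ", "))

  ## quantities at convergence
  W <- mu
  Xw <- X * sqrt(W)
  A <- crossprod(Xw)
  H <- A + S_lam
  R <- chol(H)
  Hinv <- chol2inv(R)
  edf <- sum(diag(Hinv %*% A))
  pearson <- sum((y - mu)^2 / mu)
  phi <- pearson / (n - edf)
  F_ <- Hinv
  cov_sandwich <- phi * F_ %*% A %*% F_
  cov_bayes <- phi * F_
  covariance <- if (cov_type == "sandwich") cov_sandwich else cov_bayes
  covariance <- (covariance + t(covariance)) / 2
  gcv <- n * pearson / (n - edf)^2

  beta <- drop(beta)
  names(beta) <- colnames(X)
  structure(list(coefficients = beta,
                 covariance = covariance,
                 cov_sandwich = (cov_sandwich + t(cov_sandwich)) / 2,
                 cov_bayes = (cov_bayes + t(cov_bayes)) / 2,
                 cov_type = cov_type,
                 dispersion = phi, lambdas = lambdas,
                 edf = edf, gcv = gcv,
                 fitted_mu = mu, linear_predictor = eta,
                 deviance = quasi_poisson_deviance(y, mu),
                 pearson = pearson,
                 iterations = length(trace), dev_trace = trace,
                 converged = converged,
                 XtWX = A, S_lam = S_lam,
                 design = design),
            class = "temort_fit")
}

#' @export
print.temort_fit <- function(x, ...) {
  cat("Penalized quasi-Poisson fit (model ",
      x$design$model %||% "?", ")\n", sep = "")
  cat("  n = ", length(x$fitted_mu), ", p = ", length(x$coefficients),
      ", edf = ", format(x$edf, digits = 5), "\n", sep = "")
  cat("  dispersion = ", format(x$dispersion, digits = 5),
      ", deviance = ", format(x$deviance, digits = 7), "\n", sep = "")
  if (length(x$lambdas))
    cat("  lambdas: ", paste(signif(x$lambdas, 4), collapse = ", "),
        " (GCV = ", format(x$gcv, digits = 6), ")\n", sep = "")
  invisible(x)
}

#' Pearson dispersion estimate
#'
#' `phi_hat = sum((y - mu)^2 / mu) / (n - edf)`, the quasi-Poisson scale.
#' @param fit a `temort_fit`.
#' @param y optional counts (defaults to the fitted design's response).
#' @return the scalar dispersion estimate.
#' @export
pearson_dispersion <- function(fit, y = fit$design$y) {
  mu <- fit$fitted_mu
  sum((y - mu)^2 / mu) / (length(y) - fit$edf)
}

#' Coefficient covariance of a penalized fit
#'
#' Frequentist sandwich `phi F A F` with `F = (X'WX + S_lambda)^-1` and
#' `A = X'WX` at the converged weights (default), or the posterior-style
#' `phi F`. The two agree when no penalty is active.
#' @param fit a `temort_fit`.
#' @param type `"sandwich"` or `"bayes"`.
#' @return a symmetric PSD `p x p` matrix.
#' @export
coef_covariance <- function(fit, type = c("sandwich", "bayes")) {
  type <- match.arg(type)
  if (type == "sandwich") fit$cov_sandwich else fit$cov_bayes
}

#' Control for GCV smoothing-parameter selection
#'
#' @param lambda_range log10 endpoints of the search grid.
#' @param points_per_decade grid density (default 7).
#' @param cycles coordinate-descent sweeps over the three parameters per
#'   outer iteration.
#' @param outer_iterations maximum outer (re-weighting) iterations.
#' @param refine logical: golden-section refinement around the grid
#'   minimizer of each coordinate.
#' @param init_lambda starting value for all smoothing parameters.
#' @return a list of control values.
#' @export
gcv_control <- function(lambda_range = c(-4, 6), points_per_decade = 7,
                        cycles = 2L, outer_iterations = 3L, refine = TRUE,
                        init_lambda = 1) {
  list(lambda_range = lambda_range,
       points_per_decade = points_per_decade,
       cycles = as.integer(cycles),
       outer_iterations = as.integer(outer_iterations),
       refine = refine, init_lambda = init_lambda)
}

## GCV of the working penalized least-squares problem at frozen weights.
## At a PIRLS fixed point sum(W * (z - X beta)^2) equals the Pearson
## statistic of the count model, so this criterion coincides with
## n * Pearson / (n - edf)^2 at convergence.
working_gcv <- function(A, Xw, zw, design, lambdas) {
  S_lam <- penalty_total(design, lambdas)
  H <- A + S_lam
  R <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(R)) return(Inf)
  beta <- backsolve(R, forwardsolve(t(R), crossprod(Xw, zw)))
  n <- nrow(Xw)
  rss <- sum((zw - Xw %*% beta)^2)
  edf <- sum(diag(chol2inv(R) %*% A))
  n * rss / (n - edf)^2
}

golden_min <- function(f, lo, hi, tol = 0.02) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  while (hi - lo > tol) {
    if (f1 <= f2) {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- f(x1)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- f(x2)
    }
  }
  if (f1 <= f2) list(x = x1, f = f1) else list(x = x2, f = f2)
}

#' Select smoothing parameters by generalized cross-validation
#'
#' Minimizes `GCV(lambda) = n P(lambda) / (n - edf(lambda))^2` (P the
#' Pearson statistic) over the smoothing parameters by performance
#' iteration: the model is fit by PIRLS at the current `lambda`, the
#' criterion is then minimized on the frozen working least-squares problem
#' by cyclic coordinate descent over a log-spaced grid with golden-section
#' refinement, and the model is refit; the loop stops when `lambda` is
#' stable. Deterministic. A minimum on the grid boundary is recorded in
#' the fit notes.
#'
#' @param design a `pollution_design` with at least one penalty.
#' @param control see [gcv_control()].
#' @param cov_type passed to [pirls_fit()].
#' @return list with `lambdas`, `fit` (the refit at the minimizer), `gcv`,
#'   `boundary` (logical), and `outer_iterations`.
#' @export
gcv_select <- function(design, control = gcv_control(),
                       cov_type = c("sandwich", "bayes")) {
  cov_type <- match.arg(cov_type)
  k <- length(design$penalties)
  if (k == 0L) stop("design has no penalized terms; nothing to select")
  lr <- control$lambda_range
  grid <- seq(lr[1L], lr[2L], by = 1 / control$points_per_decade)
  log_lam <- rep(log10(control$init_lambda), k)
  boundary <- FALSE
  outer_used <- 0L

  for (outer in seq_len(control$outer_iterations)) {
    outer_used <- outer
    fit <- pirls_fit(design, 10^log_lam, cov_type = cov_type)
    W <- fit$fitted_mu
    sw <- sqrt(W)
    Xw <- design$X * sw
    z <- fit$linear_predictor + (design$y - W) / W
    zw <- sw * z
    A <- crossprod(Xw)

    obj <- function(ll) working_gcv(A, Xw, zw, design, 10^ll)
    prev <- log_lam
    for (cyc in seq_len(control$cycles)) {
      for (m in seq_len(k)) {
        vals <- vapply(grid, function(g) {
          ll <- log_lam; ll[m] <- g; obj(ll)
        }, numeric(1))
        best <- which.min(vals)
        if (best == 1L || best == length(grid)) boundary <- TRUE
        gbest <- grid[best]
        if (control$refine) {
          lo <- grid[max(1L, best - 1L)]
          hi <- grid[min(length(grid), best + 1L)]
          r <- golden_min(function(g) {
            ll <- log_lam; ll[m] <- g; obj(ll)
          }, lo, hi)
          if (r$f <= vals[best]) gbest <- r$x
        }
        log_lam[m] <- gbest
      }
    }
    if (max(abs(log_lam - prev)) < 0.01 && outer > 1L) break
  }
  fit <- pirls_fit(design, 10^log_lam, cov_type = cov_type)
  if (boundary)
    fit$design$notes <- c(fit$design$notes,
                          "warning: GCV minimum on grid boundary")
  list(lambdas = 10^log_lam, fit = fit, gcv = fit$gcv,
       boundary = boundary, outer_iterations = outer_used)
}

#' Write a plain-text fit log
#' @param fit a `temort_fit`.
#' @param path file path.
#' @export
write_fit_log <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("model: %s", fit$design$model %||% "custom"),
    sprintf("n: %d  p: %d", length(fit$fitted_mu), length(fit$coefficients)),
    sprintf("converged: %s after %d iterations", fit$converged, fit$iterations),
    sprintf("deviance: %.10g  pearson: %.10g", fit$deviance, fit$pearson),
    sprintf("edf: %.6f  dispersion: %.6f", fit$edf, fit$dispersion),
    if (length(fit$lambdas))
      sprintf("lambdas: %s  gcv: %.10g",
              paste(signif(fit$lambdas, 6), collapse = " "), fit$gcv)
    else "lambdas: (none)",
    "iteration penalized deviances:",
    paste(sprintf("  %2d  %.10g", seq_along(fit$dev_trace), fit$dev_trace)),
    if (length(fit$design$notes)) fit$design$notes else "notes: none"
  ), con)
  invisible(path)
}

#' Serialize / reload a fitted model as plain text
#'
#' Writes everything needed to re-evaluate effects from a fit — model type,
#' coefficients, covariance, dispersion, smoothing parameters, column map,
#' exposure contrasts and (for the tensor model) the centered smooth — to
#' JSON with doubles encoded as hex floats, so a reloaded fit evaluates
#' bit-identically. The reloaded object carries no model matrix; it
#' supports the effect estimators, not refitting.
#'
#' @param fit a `temort_fit`.
#' @param path file path.
#' @export
save_fit_json <- function(fit, path) {
  d <- fit$design
  obj <- list(
    model = d$model,
    coefficients = list(names = names(fit$coefficients),
                        x = hex_num(fit$coefficients)),
    covariance = hex_mat(fit$covariance),
    cov_type = fit$cov_type,
    dispersion = hex_num(fit$dispersion),
    lambdas = hex_num(fit$lambdas),
    edf = hex_num(fit$edf), gcv = hex_num(fit$gcv),
    column_map = d$column_map,
    increments = list(names = names(d$increments), x = hex_num(d$increments)),
    reference_levels = list(names = names(d$reference_levels),
                            x = hex_num(d$reference_levels)),
    exposures = hex_mat(d$exposures),
    exposure_names = colnames(d$exposures),
    smooth = if (!is.null(d$smooth)) {
      tf <- tempfile(); on.exit(unlink(tf))
      save_tensor_smooth(d$smooth, tf)
      jsonlite::read_json(tf, simplifyVector = FALSE)
    })
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_fit_json
#' @export
load_fit_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  named_num <- function(o)
    stats::setNames(as.numeric(unlist(o$x)), unlist(o$names))
  smooth <- NULL
  if (!is.null(raw$smooth)) {
    tf <- tempfile()
    on.exit(unlink(tf))
    jsonlite::write_json(raw$smooth, tf, auto_unbox = TRUE)
    smooth <- load_tensor_smooth(tf)
  }
  ex <- unhex_mat(raw$exposures)
  colnames(ex) <- unlist(raw$exposure_names)
  design <- structure(list(
    model = raw$model,
    column_map = lapply(raw$column_map, function(v) {
      out <- as.integer(unlist(v))
      names(out) <- names(v)
      out
    }),
    increments = named_num(raw$increments),
    reference_levels = named_num(raw$reference_levels),
    exposures = ex, smooth = smooth, notes = character(0)),
    class = "pollution_design")
  structure(list(
    coefficients = named_num(raw$coefficients),
    covariance = unhex_mat(raw$covariance),
    cov_type = raw$cov_type,
    dispersion = as.numeric(unlist(raw$dispersion)),
    lambdas = as.numeric(unlist(raw$lambdas)),
    edf = as.numeric(unlist(raw$edf)),
    gcv = as.numeric(unlist(raw$gcv)),
    design = design), class = "temort_fit")
}
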