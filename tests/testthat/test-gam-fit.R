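# deeper fits are exercised on a 500-800 day simulated series; the fitting
# engine itself is size-agnostic

test_that("the unpenalized limit reproduces an independent Poisson GLM", {
  d <- quick_data(seed = 23L, n_days = 500L)
  des <- build_model(d, model_spec("II"))
  fit <- pirls_fit(des)
  df <- as.data.frame(des$X[, -1L]); df$y <- des$y
  g <- glm(y ~ ., data = df, family = quasipoisson())
  expect_lt(max(abs(unname(fit$coefficients) - unname(coef(g)))), 1e-6)
  # classical quasi-Poisson covariance in the unpenalized limit
  expect_equal(fit$dispersion, summary(g)$dispersion, tolerance = 1e-6)
  V <- coef_covariance(fit, "sandwich")
  expect_lt(max(abs(V - unname(vcov(g)))), 1e-8)
  # sandwich and posterior forms coincide without a penalty
  expect_equal(coef_covariance(fit, "bayes"), V, tolerance = 1e-10)
})

test_that("heavy penalties drive the smooth into the penalty null space", {
  d <- quick_data(seed = 24L, n_days = 600L)
  des <- build_model(d, model_spec("IV", tensor_dims = c(4L, 4L, 4L)))
  fit <- pirls_fit(des, rep(1e9, 3L))
  v <- fit$coefficients[des$column_map$smooth]
  for (pen in des$penalties)
    expect_lt(drop(t(v) %*% pen$S %*% v), 1e-6)
})

test_that("the penalized score equation holds at convergence", {
  d <- quick_data(seed = 25L, n_days = 600L)
  des <- build_model(d, model_spec("IV", tensor_dims = c(4L, 4L, 4L)))
  for (lam in list(c(0.1, 1, 10), c(100, 100, 100))) {
    fit <- pirls_fit(des, lam)
    S_lam <- matrix(0, ncol(des$X), ncol(des$X))
    for (i in seq_along(des$penalties)) {
      cols <- des$penalties[[i]]$cols
      S_lam[cols, cols] <- S_lam[cols, cols] + lam[i] * des$penalties[[i]]$S
    }
    score <- drop(crossprod(des$X, des$y - fit$fitted_mu)) -
      drop(S_lam %*% fit$coefficients)
    # per-coordinate, scaled by the working curvature
    expect_lt(max(abs(score)) / sqrt(max(diag(fit$XtWX))), 1e-6)
    # penalized deviance is non-increasing across iterations
    expect_true(all(diff(fit$dev_trace) <= 1e-8))
  }
})

test_that("PIRLS agrees with a derivative-free optimizer on a small problem", {
  set.seed(26)
  n <- 300L
  X <- cbind(1, scale(matrix(rnorm(n * 4L), n, 4L)))
  colnames(X) <- c("int", paste0("x", 1:4))
  eta <- drop(X %*% c(3, 0.2, -0.1, 0.05, 0))
  y <- rpois(n, exp(eta))
  S <- diag(c(0, 1, 1, 1, 1))
  des <- list(X = X, y = y,
              penalties = list(list(label = "ridge", cols = 1:5, S = S)))
  lam <- 2.5
  fit <- pirls_fit(des, lam)
  pen_dev <- function(b) {
    mu <- exp(drop(X %*% b))
    2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu)) +
      lam * drop(t(b) %*% S %*% b)
  }
  o <- optim(rep(0, 5L), pen_dev, method = "Nelder-Mead",
             control = list(maxit = 20000, reltol = 1e-14))
  expect_lt(max(abs(unname(fit$coefficients) - o$par)), 1e-4)
})

test_that("nonsense inputs fail loudly", {
  d <- quick_data(seed = 27L, n_days = 500L)
  des <- build_model(d, model_spec("II"))
  desb <- des; desb$y[1L] <- -3
  expect_error(pirls_fit(desb), "nonnegative")
  # rank deficiency: duplicated column
  desr <- des
  desr$X <- cbind(desr$X, dup = desr$X[, "pm10"])
  expect_error(pirls_fit(desr), "rank-deficient")
  des4 <- build_model(d, model_spec("IV", tensor_dims = c(4L, 4L, 4L)))
  expect_error(pirls_fit(des4, c(1, 2)), "smoothing parameters")
  expect_error(pirls_fit(des4, c(-1, 1, 1)), "nonnegative")
})

test_that("Pearson dispersion recovers the generating overdispersion", {
  n <- 2922L
  d1 <- simulate_daily_data(simulation_config(n_days = n, dispersion = 1),
                            seed = 28L)
  f1 <- pirls_fit(build_model(d1, model_spec("II")))
  expect_gt(pearson_dispersion(f1), 0.9)
  expect_lt(pearson_dispersion(f1), 1.1)
  d2 <- simulate_daily_data(simulation_config(n_days = n, dispersion = 2),
                            seed = 29L)
  f2 <- pirls_fit(build_model(d2, model_spec("II")))
  expect_gt(pearson_dispersion(f2), 1.8)
  expect_lt(pearson_dispersion(f2), 2.2)
  # exact fit means zero dispersion
  fx <- f1; fx$fitted_mu <- as.numeric(f1$design$y)
  expect_identical(pearson_dispersion(fx), 0)
})

test_that("delta-method contrast variance matches Monte-Carlo replication", {
  cfg <- quick_config(n_days = 800L)
  reps <- 200L
  out <- vapply(seq_len(reps), function(s) {
    dat <- simulate_daily_data(cfg, seed = 4000L + s)
    fit <- pirls_fit(build_model(dat, model_spec("II")))
    est <- iqr_effect(fit)
    c(log(est$rr), est$se_log_rr)
  }, numeric(2L))
  ratio <- mean(out[2L, ]) / sd(out[1L, ])
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
})

test_that("delta-method intervals attain nominal coverage", {
  cfg <- quick_config(n_days = 800L)
  slopes <- cfg$true_effect$slopes
  covers <- vapply(seq_len(300L), function(s) {
    dat <- simulate_daily_data(cfg, seed = 6000L + s)
    fit <- pirls_fit(build_model(dat, model_spec("II")))
    est <- iqr_effect(fit)
    true_rr <- exp(sum(slopes * fit$design$increments[c("pm10", "no2", "so2")]))
    est$ci_low <= true_rr && est$ci_high >= true_rr
  }, logical(1L))
  expect_gte(mean(covers), 0.93)
  expect_lte(mean(covers), 0.97)
})

test_that("covariance matrices are symmetric and positive semidefinite", {
  f <- small_iv_fit()
  for (type in c("sandwich", "bayes")) {
    V <- coef_covariance(f, type)
    expect_identical(V, t(V))
    expect_gt(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("grid GCV finds the dense-evaluation minimizer on a single-lambda problem", {
  set.seed(30)
  n <- 400L
  x <- sort(runif(n, 10, 100))
  mb <- cubic_marginal(x, 8L, "p")
  B <- eval_basis(mb, x)
  eta <- log(60) + 0.15 * sin(x / 12)
  y <- rpois(n, exp(eta))
  # B-splines form a partition of unity, so the basis spans the intercept
  des <- list(X = B, y = y,
              penalties = list(list(label = "p", cols = seq_len(8L),
                                    S = mb$penalty)))
  sel <- gcv_select(des, gcv_control(points_per_decade = 7, refine = FALSE,
                                     outer_iterations = 4L))
  # dense log-scale evaluation of the criterion by full refits
  dense <- seq(-4, 6, by = 0.05)
  gcvs <- vapply(dense, function(g) pirls_fit(des, 10^g)$gcv, numeric(1L))
  best_dense <- dense[which.min(gcvs)]
  expect_lt(abs(log10(sel$lambdas) - best_dense), 1 / 7 + 0.05)
})

test_that("GCV-selected smoothing beats both extremes under a curved truth", {
  bump <- function(pm, no, so)
    0.12 * exp(-(pm - 70)^2 / (2 * 25^2)) + 8e-4 * no + 5e-4 * so
  cfg <- simulation_config(n_days = 1500L,
                           true_effect = list(type = "surface", fun = bump))
  dat <- simulate_daily_data(cfg, seed = 31L)
  des <- build_model(dat, model_spec("IV"))
  sel <- gcv_select(des)
  mu_true <- dat$mu_true[dat$date %in% sel$fit$design$dates]
  mse <- function(f) mean((f$fitted_mu - mu_true)^2)
  expect_lt(mse(sel$fit), mse(pirls_fit(des, rep(1e-4, 3L))))
  expect_lt(mse(sel$fit), mse(pirls_fit(des, rep(1e9, 3L))))
})

test_that("fit logs record convergence and smoothing diagnostics", {
  f <- small_iv_fit()
  path <- withr::local_tempfile(fileext = ".log")
  write_fit_log(f, path)
  log <- readLines(path)
  expect_true(any(grepl("converged: TRUE", log)))
  expect_true(any(grepl("edf:", log)))
  expect_true(any(grepl("lambdas:", log)))
})

test_that("a reloaded fit evaluates effect contrasts bit-identically", {
  fit <- small_iv_fit()
  path <- withr::local_tempfile(fileext = ".json")
  save_fit_json(fit, path)
  back <- load_fit_json(path)
  ref <- fit$design$reference_levels
  to <- ref + fit$design$increments
  a <- rr_tensor(fit, ref, to)
  b <- rr_tensor(back, ref, to)
  expect_identical(a$rr, b$rr)
  expect_identical(a$se_log_rr, b$se_log_rr)
  expect_identical(back$coefficients, fit$coefficients)
  crv1 <- exposure_response_curve(fit, "pm10", n_points = 8L)
  crv2 <- exposure_response_curve(back, "pm10", n_points = 8L)
  expect_identical(crv1, crv2)
})
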