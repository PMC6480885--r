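test_that("natural cubic confounder basis reproduces lines and is natural", {
  set.seed(1)
  x <- runif(200, 0, 10)

  # df = 1 spans {x}: fitting y = 2x + 1 with intercept is exact
  B1 <- natural_cubic_basis(x, 1L)
  fit <- lm.fit(cbind(1, B1), 2 * x + 1)
  expect_lt(max(abs(fit$residuals)), 1e-10)

  # df = 3: second derivative vanishes beyond the boundary knots
  B3 <- natural_cubic_basis(x, 3L)
  bk <- attr(B3, "Boundary.knots")
  kn <- attr(B3, "knots")
  cf <- rnorm(3L)
  h <- 1e-3
  for (x0 in c(bk[1L] - 1, bk[2L] + 1)) {
    pts <- x0 + c(-h, 0, h)
    Bp <- splines::ns(pts, knots = kn, Boundary.knots = bk)
    d2 <- sum((Bp[1L, ] - 2 * Bp[2L, ] + Bp[3L, ]) * cf) / h^2
    expect_lt(abs(d2), 1e-6)
  }

  expect_error(natural_cubic_basis(rep(1:3, 10), 5L), "distinct")
})

test_that("natural spline interpolation matches the textbook construction", {
  set.seed(2)
  x <- sort(runif(60, 0, 10))
  B <- natural_cubic_basis(x, 4L)
  bk <- attr(B, "Boundary.knots")
  kn <- c(bk[1L], attr(B, "knots"), bk[2L])
  fk <- sin(kn)
  Bk <- splines::ns(kn, knots = attr(B, "knots"), Boundary.knots = bk)
  cf <- solve(cbind(1, Bk), fk)
  xe <- seq(bk[1L], bk[2L], length.out = 200L)
  Be <- splines::ns(xe, knots = attr(B, "knots"), Boundary.knots = bk)
  ours <- drop(cbind(1, Be) %*% cf)
  textbook <- spline(kn, fk, xout = xe, method = "natural")$y
  expect_lt(max(abs(ours - textbook)), 1e-10)
})

test_that("marginal penalty is the exact integral of squared curvature", {
  set.seed(3)
  x <- runif(500, 10, 110)
  for (dim in c(4L, 5L, 7L)) {
    mb <- cubic_marginal(x, dim, name = "pm10")
    B <- eval_basis(mb, x)
    # quadratic test function: integral of (f'')^2 = 4 * range
    cf2 <- qr.solve(B, x^2)
    expect_lt(max(abs(B %*% cf2 - x^2)), 1e-6) # quadratics representable
    qf <- drop(t(cf2) %*% mb$penalty %*% cf2)
    expect_lt(abs(qf - 4 * diff(mb$range)), 1e-6)
    # affine functions are in the penalty null space
    cfa <- qr.solve(B, 3 * x + 2)
    expect_lt(abs(drop(t(cfa) %*% mb$penalty %*% cfa)), 1e-10)
    # symmetric PSD
    expect_identical(mb$penalty, t(mb$penalty))
    expect_gt(min(eigen(mb$penalty, symmetric = TRUE,
                        only.values = TRUE)$values), -1e-10)
  }
  expect_error(cubic_marginal(x, 3L), ">= 4")
  expect_error(cubic_marginal(rep(1:4, 10), 6L), "distinct")
})

test_that("basis evaluation is exact at knots for interpolants", {
  set.seed(4)
  x <- runif(300, 0, 50)
  mb <- cubic_marginal(x, 6L, name = "so2")
  # interpolate a smooth function at 6 spread points, check exact there
  pts <- seq(min(x) + 1, max(x) - 1, length.out = 6L)
  B <- eval_basis(mb, pts)
  cf <- solve(B, sqrt(pts))
  expect_lt(max(abs(eval_basis(mb, pts) %*% cf - sqrt(pts))), 1e-9)
})

test_that("tensor rows equal the brute-force triple loop in the documented layout", {
  m <- list(toy_linear_margin("a"), toy_linear_margin("b"),
            toy_linear_margin("c"))
  lv <- c(0.3, 0.7, 0.2)
  r <- tensor_basis_row(m, lv)
  e1 <- c(1, lv[1L]); e2 <- c(1, lv[2L]); e3 <- c(1, lv[3L])
  bf <- numeric(8L)
  for (k in 1:2) for (l in 1:2) for (i in 1:2)
    bf[tensor_flat_index(c(2L, 2L, 2L), i, l, k)] <- e2[k] * e3[l] * e1[i]
  expect_equal(r, bf, tolerance = 1e-14)

  # a zero margin row zeroes the whole tensor row
  mz <- m
  mz[[2L]]$evalfun <- function(x, deriv = 0L) cbind(0 * x, 0 * x)
  expect_identical(unique(tensor_basis_row(mz, lv)), 0)

  # layout consistency: contracting a reshaped coefficient array with the
  # marginal rows reproduces the scalar smooth value
  set.seed(5)
  v <- rnorm(8L)
  arr <- array(v, dim = c(2L, 2L, 2L)) # (i, l, k): pm10 fastest, no2 slowest
  direct <- sum(r * v)
  contracted <- 0
  for (k in 1:2) for (l in 1:2) for (i in 1:2)
    contracted <- contracted + arr[i, l, k] * e1[i] * e3[l] * e2[k]
  expect_equal(direct, contracted, tolerance = 1e-12)
})

test_that("tensor rows factorize as Kronecker products on random inputs", {
  set.seed(6)
  x <- runif(200, 10, 100)
  margins <- list(cubic_marginal(x, 5L, "pm10"),
                  cubic_marginal(x * 0.8, 4L, "no2"),
                  cubic_marginal(x * 0.5, 6L, "so2"))
  for (rep in 1:20) {
    lv <- c(runif(1, 15, 95), runif(1, 10, 75), runif(1, 8, 45))
    r <- tensor_basis_row(margins, lv)
    kr <- kronecker(eval_basis(margins[[2L]], lv[2L]),
                    kronecker(eval_basis(margins[[3L]], lv[3L]),
                              eval_basis(margins[[1L]], lv[1L])))
    expect_equal(r, drop(kr), tolerance = 1e-12)
  }
})

test_that("expanded penalties equal brute-force integration of the marginal curvature", {
  ms <- list(toy_poly_margin("a"), toy_poly_margin("b"), toy_poly_margin("c"))
  Sx <- expand_penalties(ms)
  # 3D midpoint assembly of the integral of the squared second partial
  # with respect to the first margin, independent of the Kronecker code
  n1 <- 60L
  xs <- (seq_len(n1) - 0.5) / n1
  S_bf <- matrix(0, 27L, 27L)
  r1d2 <- ms[[1L]]$evalfun(xs, 2L)
  for (u in xs) for (v in xs) {
    rows <- kronecker(ms[[2L]]$evalfun(u), kronecker(ms[[3L]]$evalfun(v), r1d2))
    S_bf <- S_bf + crossprod(rows) / n1
  }
  S_bf <- S_bf / n1^2
  expect_lt(max(abs(S_bf - Sx$pm10)), 1e-3)

  # null spaces: a coefficient vector constant in margin m has zero
  # roughness under margin m's penalty
  set.seed(7)
  for (m in 1:3) {
    arr <- array(0, dim = c(3L, 3L, 3L))
    # fill the array so it only involves the affine part of margin m
    for (i in 1:3) for (l in 1:3) for (k in 1:3) {
      w <- c(i, l, k)[c(1L, 3L, 2L)[m]] # margin index along m (i/k/l order)
      arr[i, l, k] <- if (w <= 2L) rnorm(1L) else 0 # {1, x} part only
    }
    v <- as.vector(arr)
    S <- Sx[[c("pm10", "no2", "so2")[m]]]
    expect_lt(drop(t(v) %*% S %*% v), 1e-8)
  }

  # PSD: nonnegative quadratic forms for random coefficient vectors
  set.seed(8)
  V <- matrix(rnorm(27L * 200L), 200L, 27L)
  for (S in Sx) expect_gt(min(rowSums((V %*% S) * V)), -1e-10)
})

test_that("centering identifies the smooth without changing contrasts", {
  set.seed(9)
  x <- cbind(runif(300, 10, 100), runif(300, 10, 80), runif(300, 5, 50))
  margins <- list(cubic_marginal(x[, 1L], 4L, "pm10"),
                  cubic_marginal(x[, 2L], 4L, "no2"),
                  cubic_marginal(x[, 3L], 4L, "so2"))
  sm <- tensor_smooth(margins)
  Traw <- tensor_basis_row(margins, x)
  cc <- apply_centering(sm, Traw)

  # fitted smooth sums to zero over the sample for any coefficients
  u <- rnorm(ncol(cc$design))
  expect_lt(abs(mean(cc$design %*% u)), 1e-10)

  # reparameterization: least-squares fits with and without the constraint
  # (intercept included) give identical fitted values
  y <- sin(x[, 1L] / 20) + 0.01 * x[, 2L] + rnorm(300, sd = 0.1)
  f_uncon <- lm.fit(cbind(1, Traw), y)$fitted.values
  f_con <- lm.fit(cbind(1, cc$design), y)$fitted.values
  expect_lt(max(abs(f_uncon - f_con)), 1e-8)

  # contrasts are invariant to centering
  v <- rnorm(sm$dimension)
  uz <- drop(crossprod(cc$smooth$constraint$Z, v))
  a <- c(40, 30, 20); b <- c(80, 60, 35)
  d_raw <- sum((tensor_basis_row(margins, b) - tensor_basis_row(margins, a)) * v)
  ## project v onto the constrained space: contrast of the projected smooth
  d_con <- sum((tensor_row_centered(cc$smooth, b) -
                tensor_row_centered(cc$smooth, a)) * uz)
  vproj <- cc$smooth$constraint$Z %*% uz
  d_proj <- sum((tensor_basis_row(margins, b) -
                 tensor_basis_row(margins, a)) * vproj)
  expect_equal(d_con, d_proj, tolerance = 1e-10)
})

test_that("fitted smooths are invariant to a change of concentration units", {
  set.seed(10)
  x <- runif(400, 10, 100)
  y <- sin(x / 15) + rnorm(400, sd = 0.1)
  fit_with <- function(scale) {
    mb <- cubic_marginal(x * scale, 5L, "p")
    B <- eval_basis(mb, x * scale)
    lm.fit(cbind(1, B), y)$fitted.values
  }
  expect_lt(max(abs(fit_with(1) - fit_with(10))), 1e-8)
  # knots scale consistently
  mb1 <- cubic_marginal(x, 5L, "p"); mb10 <- cubic_marginal(x * 10, 5L, "p")
  expect_equal(mb10$knots, mb1$knots * 10, tolerance = 1e-12)
})

test_that("spline objects serialize to text and reload bit-identically", {
  set.seed(11)
  x <- cbind(runif(200, 10, 100), runif(200, 10, 80), runif(200, 5, 50))
  margins <- list(cubic_marginal(x[, 1L], 5L, "pm10"),
                  cubic_marginal(x[, 2L], 4L, "no2"),
                  cubic_marginal(x[, 3L], 4L, "so2"))
  sm <- tensor_smooth(margins)
  cc <- apply_centering(sm, tensor_basis_row(margins, x))
  path <- withr::local_tempfile(fileext = ".json")
  save_tensor_smooth(cc$smooth, path)
  sm2 <- load_tensor_smooth(path)
  lv <- c(55, 40, 22)
  expect_identical(tensor_row_centered(cc$smooth, lv),
                   tensor_row_centered(sm2, lv))
  expect_identical(sm$penalties$no2, sm2$penalties$no2)
})
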