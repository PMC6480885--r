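#' Natural cubic spline basis for confounders
#'
#' Thin wrapper around [splines::ns()]: a natural cubic spline basis
#' (linear beyond the boundary knots) with interior knots at equally spaced
#' quantiles of `x`, the standard way time-series mortality models absorb
#' smooth confounders (temperature, humidity, pressure, long-term trend).
#'
#' @param x numeric vector (missing values propagate to missing rows).
#' @param df basis dimension (>= 1).
#' @return an `n x df` matrix with attributes `knots` and `Boundary.knots`.
#' @export
natural_cubic_basis <- function(x, df) {
  df <- as.integer(df)
  if (df < 1L) stop("df must be >= 1")
  ok <- !is.na(x)
  if (length(unique(x[ok])) < df + 1L)
    stop("need at least df + 1 distinct values to build a df=", df, " basis")
  B <- splines::ns(x, df = df)
  out <- matrix(NA_real_, length(x), df)
  out[ok, ] <- B[ok, , drop = FALSE]
  attr(out, "knots") <- attr(B, "knots")
  attr(out, "Boundary.knots") <- attr(B, "Boundary.knots")
  out
}

## Gauss-Legendre nodes/weights on [-1, 1]
gauss_legendre <- function(k) {
  switch(as.character(k),
    "2" = list(x = c(-1, 1) / sqrt(3), w = c(1, 1)),
    "4" = {
      a <- sqrt(3 / 7 - 2 / 7 * sqrt(6 / 5))
      b <- sqrt(3 / 7 + 2 / 7 * sqrt(6 / 5))
      wa <- (18 + sqrt(30)) / 36
      wb <- (18 - sqrt(30)) / 36
      list(x = c(-b, -a, a, b), w = c(wb, wa, wa, wb))
    },
    stop("unsupported rule"))
}

## integrate crossprod of basis rows (derivative `deriv`) exactly over the
## knot span; integrand is piecewise polynomial of degree 2*(3 - deriv)
basis_product_integral <- function(knots_full, deriv, npts) {
  brk <- unique(knots_full)
  gl <- gauss_legendre(npts)
  p <- length(knots_full) - 4L
  S <- matrix(0, p, p)
  for (j in seq_len(length(brk) - 1L)) {
    a <- brk[j]; b <- brk[j + 1L]
    xs <- (a + b) / 2 + (b - a) / 2 * gl$x
    B <- splines::splineDesign(knots_full, xs, ord = 4L,
                               derivs = rep(deriv, length(xs)))
    S <- S + crossprod(B * sqrt(gl$w * (b - a) / 2))
  }
  (S + t(S)) / 2
}

#' Cubic regression spline marginal basis with exact roughness penalty
#'
#' Builds one pollutant's marginal smooth basis: cubic B-splines with
#' boundary knots at the data range and interior knots at equally spaced
#' quantiles, together with the roughness penalty matrix `S` whose quadratic
#' form `c' S c` equals the exact integral of the squared second derivative
#' of the represented function over the observed range (the second
#' derivative of a cubic spline is piecewise linear, so Gauss quadrature of
#' the products is exact), and the Gram matrix `G` of exact basis-function
#' products used when marginal penalties are expanded over a tensor product.
#'
#' @param x numeric vector of observed concentrations (missing dropped for
#'   knot placement).
#' @param dimension basis dimension (>= 4; a cubic spline space needs at
#'   least four functions).
#' @param name variable label carried through to the tensor smooth.
#' @return an object of class `marginal_basis` with fields `variable_name`,
#'   `dimension`, `knots` (full knot vector, boundary knots repeated),
#'   `penalty`, `gram`, and `evalfun(x, deriv)`.
#' @export
cubic_marginal <- function(x, dimension, name = deparse(substitute(x))) {
  dimension <- as.integer(dimension)
  if (dimension < 4L)
    stop("dimension must be >= 4 for a cubic spline basis")
  xs <- sort(unique(x[!is.na(x)]))
  if (dimension > length(xs))
    stop("dimension exceeds the number of distinct values of ", name)
  a <- xs[1L]; b <- xs[length(xs)]
  n_int <- dimension - 4L
  interior <- if (n_int > 0L)
    stats::quantile(x, probs = seq_len(n_int) / (n_int + 1L),
                    na.rm = TRUE, names = FALSE, type = 7)
  else numeric(0)
  knots_full <- c(rep(a, 4L), interior, rep(b, 4L))
  S <- basis_product_integral(knots_full, deriv = 2L, npts = 2L)
  G <- basis_product_integral(knots_full, deriv = 0L, npts = 4L)
  new_marginal_basis(name, dimension, knots_full, S, G)
}

new_marginal_basis <- function(name, dimension, knots_full, S, G) {
  a <- knots_full[1L]; b <- knots_full[length(knots_full)]
  structure(list(
    variable_name = name,
    dimension = dimension,
    knots = knots_full,
    range = c(a, b),
    penalty = S,
    gram = G,
    ## evaluation clamps to the knot span: beyond the boundary knots the
    ## smooth is held at its boundary value (tensor splines extrapolate
    ## wildly; the effects layer enforces its own extrapolation guard)
    evalfun = function(x, deriv = 0L) {
      xc <- pmin(b, pmax(a, x))
      splines::splineDesign(knots_full, xc, ord = 4L,
                            derivs = rep(as.integer(deriv), length(xc)))
    }
  ), class = "marginal_basis")
}

#' Evaluate a marginal basis
#' @param basis a `marginal_basis`.
#' @param x numeric vector.
#' @param deriv derivative order (0, 1 or 2).
#' @return an `n x dimension` matrix.
#' @export
eval_basis <- function(basis, x, deriv = 0L) basis$evalfun(x, deriv)

#' Three-way tensor product smooth
#'
#' Combines three marginal bases (order: PM10, NO2, SO2) into one smooth of
#' the joint concentration space. A design row at levels `(p, n, s)` is the
#' Kronecker product of the marginal evaluation rows; the coefficient
#' layout indexes the PM10 margin fastest, then SO2, then NO2:
#' `flat = i + (l - 1) * I + (k - 1) * I * L` for coefficient `v[i, l, k]`
#' with `i = 1..I` (PM10), `l = 1..L` (SO2), `k = 1..K` (NO2).
#'
#' One expanded roughness penalty per margin is attached: the exact
#' integral over the joint observed box of the squared pure second partial
#' with respect to that margin, which in the Kronecker layout pairs the
#' margin's own penalty matrix with the Gram (overlap) matrices of the
#' other two margins. Each smoothing parameter multiplies exactly one of
#' these at fit time. The three penalties' common null space contains the
#' constant function (and every function affine in all three arguments).
#'
#' @param margins list of three `marginal_basis` objects in the order
#'   PM10, NO2, SO2.
#' @return an object of class `tensor_smooth`.
#' @export
tensor_smooth <- function(margins) {
  stopifnot(length(margins) == 3L)
  dims <- vapply(margins, function(m) m$dimension, integer(1))
  structure(list(
    margins = margins,
    dims = dims,              # (I, K, L) for (pm10, no2, so2)
    dimension = prod(dims),
    penalties = expand_penalties(margins),
    constraint = NULL
  ), class = "tensor_smooth")
}

#' Tensor-product design row(s)
#'
#' Evaluates the (unconstrained) tensor basis at given pollutant levels:
#' the row-wise Kronecker product of the three marginal rows in the layout
#' documented under [tensor_smooth()].
#'
#' @param margins list of three `marginal_basis` (PM10, NO2, SO2 order), or
#'   a `tensor_smooth`.
#' @param levels numeric 3-vector `(pm10, no2, so2)` or an `n x 3` matrix.
#' @return a vector of length `I*K*L`, or an `n x (I*K*L)` matrix.
#' @export
tensor_basis_row <- function(margins, levels) {
  if (inherits(margins, "tensor_smooth")) margins <- margins$margins
  lv <- if (is.matrix(levels)) levels else matrix(levels, nrow = 1L)
  stopifnot(ncol(lv) == 3L)
  A1 <- eval_basis(margins[[1L]], lv[, 1L])  # PM10, dim I
  A2 <- eval_basis(margins[[2L]], lv[, 2L])  # NO2,  dim K
  A3 <- eval_basis(margins[[3L]], lv[, 3L])  # SO2,  dim L
  I <- ncol(A1); K <- ncol(A2); L <- ncol(A3)
  out <- A2[, rep(seq_len(K), each = I * L), drop = FALSE] *
    A3[, rep(rep(seq_len(L), each = I), times = K), drop = FALSE] *
    A1[, rep(seq_len(I), times = L * K), drop = FALSE]
  dimnames(out) <- NULL
  if (is.matrix(levels)) out else drop(out)
}

#' Map between tensor coefficient indices and the flat layout
#' @param dims integer 3-vector `(I, K, L)` of marginal dimensions.
#' @param i,l,k marginal indices (PM10, SO2, NO2 respectively).
#' @return the flat coefficient index.
#' @export
tensor_flat_index <- function(dims, i, l, k) {
  I <- dims[1L]; L <- dims[3L]
  i + (l - 1L) * I + (k - 1L) * I * L
}

#' Expanded per-margin tensor penalties
#'
#' For each margin, the `(I*K*L)^2` matrix whose quadratic form in the
#' tensor coefficients equals the integral over the joint observed box of
#' the squared pure second partial derivative with respect to that margin:
#' the margin's own penalty Kronecker-combined with the Gram matrices of
#' the other margins, in the documented layout order (NO2 slowest, SO2,
#' PM10 fastest).
#'
#' @param margins list of three `marginal_basis` (PM10, NO2, SO2 order).
#' @return named list of three symmetric PSD matrices (`pm10`, `no2`, `so2`).
#' @export
expand_penalties <- function(margins) {
  S <- lapply(margins, `[[`, "penalty")
  G <- lapply(margins, `[[`, "gram")
  list(
    pm10 = kronecker(G[[2L]], kronecker(G[[3L]], S[[1L]])),
    no2  = kronecker(S[[2L]], kronecker(G[[3L]], G[[1L]])),
    so2  = kronecker(G[[2L]], kronecker(S[[3L]], G[[1L]]))
  )
}

#' Sum-to-zero centering of a tensor smooth
#'
#' Reparameterizes the smooth so that its fitted values sum to zero over
#' the sample, which identifies the model intercept. The constraint
#' `mean(X v) = 0` is absorbed by an orthonormal null-space basis `Z`
#' (`v = Z u`); the constrained design is `X Z` (one column fewer) and each
#' expanded penalty becomes `Z' S Z`. `Z` is stored on the smooth so
#' contrasts of the fitted surface can be evaluated later.
#'
#' @param smooth a `tensor_smooth`.
#' @param design_rows `n x (I*K*L)` unconstrained tensor design matrix.
#' @return list with `design` (the `n x (I*K*L - 1)` constrained matrix),
#'   `penalties` (constrained), and `smooth` (with the transform stored).
#' @export
apply_centering <- function(smooth, design_rows) {
  stopifnot(inherits(smooth, "tensor_smooth"),
            ncol(design_rows) == smooth$dimension)
  cvec <- colMeans(design_rows)
  qrc <- qr(matrix(cvec, ncol = 1L))
  Z <- qr.Q(qrc, complete = TRUE)[, -1L, drop = FALSE]
  smooth$constraint <- list(cvec = cvec, Z = Z)
  list(design = design_rows %*% Z,
       penalties = lapply(smooth$penalties,
                          function(S) crossprod(Z, S %*% Z)),
       smooth = smooth)
}

#' Constrained tensor row(s) for contrast evaluation
#'
#' Evaluates the centered tensor basis (the coordinates the fitted
#' coefficients live in) at given levels. Differences of such rows give
#' exact surface contrasts: the centering constant cancels.
#' @param smooth a centered `tensor_smooth` (after [apply_centering()]).
#' @param levels 3-vector or `n x 3` matrix `(pm10, no2, so2)`.
#' @return vector/matrix of length/width `I*K*L - 1`.
#' @export
tensor_row_centered <- function(smooth, levels) {
  if (is.null(smooth$constraint))
    stop("smooth has no centering transform; call apply_centering() first")
  r <- tensor_basis_row(smooth$margins, levels)
  if (is.matrix(r)) r %*% smooth$constraint$Z
  else drop(r %*% smooth$constraint$Z)
}

#' Serialize / restore spline objects as plain text
#'
#' Knot vectors, penalties and the centering transform are written to JSON
#' at full double precision, so a reloaded basis evaluates bit-identically.
#' @param basis a `marginal_basis`.
#' @return for `marginal_basis_to_list`, a plain list; `marginal_basis_from_list`
#'   inverts it.
#' @export
marginal_basis_to_list <- function(basis) {
  list(variable_name = basis$variable_name,
       dimension = basis$dimension,
       knots = basis$knots,
       penalty = basis$penalty,
       gram = basis$gram)
}

#' @rdname marginal_basis_to_list
#' @param x a list produced by `marginal_basis_to_list`.
#' @export
marginal_basis_from_list <- function(x) {
  d <- as.integer(x$dimension)
  as_mat <- function(m) {
    if (is.matrix(m)) m else matrix(unlist(m), d, d, byrow = TRUE)
  }
  new_marginal_basis(x$variable_name, d, as.numeric(unlist(x$knots)),
                     as_mat(x$penalty), as_mat(x$gram))
}

## doubles stored as C99 hexadecimal floats: decimal JSON parsers are not
## guaranteed correctly rounded, hex strings round-trip bit-exactly
hex_num <- function(x) sprintf("%a", as.numeric(x))
hex_mat <- function(m) list(dim = dim(m), x = hex_num(as.vector(m)))
unhex_mat <- function(h) {
  matrix(as.numeric(unlist(h$x)), unlist(h$dim)[1L], unlist(h$dim)[2L])
}

#' @rdname marginal_basis_to_list
#' @param smooth a centered or uncentered `tensor_smooth`.
#' @param path file path for the JSON model description.
#' @export
save_tensor_smooth <- function(smooth, path) {
  obj <- list(
    margins = lapply(smooth$margins, function(m)
      list(variable_name = m$variable_name, dimension = m$dimension,
           knots = hex_num(m$knots),
           penalty = hex_mat(m$penalty), gram = hex_mat(m$gram))),
    constraint = if (!is.null(smooth$constraint))
      list(cvec = hex_num(smooth$constraint$cvec),
           Z = hex_mat(smooth$constraint$Z)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname marginal_basis_to_list
#' @export
load_tensor_smooth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  margins <- lapply(raw$margins, function(m)
    new_marginal_basis(m$variable_name, as.integer(m$dimension),
                       as.numeric(unlist(m$knots)),
                       unhex_mat(m$penalty), unhex_mat(m$gram)))
  sm <- tensor_smooth(margins)
  if (!is.null(raw$constraint)) {
    sm$constraint <- list(cvec = as.numeric(unlist(raw$constraint$cvec)),
                          Z = unhex_mat(raw$constraint$Z))
  }
  sm
}
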