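# shared fixtures: all data is generated in code at test time

quick_config <- function(n_days = 800L, ...) {
  simulation_config(n_days = n_days, ...)
}

quick_data <- function(seed = 1L, n_days = 800L, ...) {
  simulate_daily_data(quick_config(n_days = n_days, ...), seed = seed)
}

# polynomial toy marginal basis {1, x, x^2} on [0, 1] with numerically
# integrated penalty/gram, for tensor-assembly oracles that need analytic
# derivatives independent of the B-spline code path
toy_poly_margin <- function(name, nquad = 2000L) {
  evalfun <- function(x, deriv = 0L) {
    if (deriv == 0L) cbind(1, x, x^2)
    else if (deriv == 1L) cbind(0 * x, 1 + 0 * x, 2 * x)
    else cbind(0 * x, 0 * x, 2 + 0 * x)
  }
  midint <- function(d) {
    xs <- (seq_len(nquad) - 0.5) / nquad
    crossprod(evalfun(xs, d)) / nquad
  }
  structure(list(variable_name = name, dimension = 3L,
                 knots = NULL, range = c(0, 1),
                 penalty = midint(2L), gram = midint(0L),
                 evalfun = evalfun),
            class = "marginal_basis")
}

# small linear toy margin {1, x} for exact Kronecker-row oracles
toy_linear_margin <- function(name) {
  structure(list(variable_name = name, dimension = 2L,
                 knots = NULL, range = c(0, 1),
                 penalty = matrix(0, 2, 2), gram = diag(2),
                 evalfun = function(x, deriv = 0L) {
                   if (deriv == 0L) cbind(1 + 0 * x, x) else cbind(0 * x, 0 * x)
                 }),
            class = "marginal_basis")
}

# a small fitted tensor model shared by effect-identity tests
small_iv_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dat <- quick_data(seed = 42L, n_days = 800L)
      des <- build_model(dat, model_spec("IV", tensor_dims = c(4L, 4L, 4L)))
      cache <<- pirls_fit(des, c(10, 10, 10))
    }
    cache
  }
})
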