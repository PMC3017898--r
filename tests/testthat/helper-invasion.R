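# shared helpers for the chebinvade test suite

# evaluate a polynomial with coefficients co (ascending powers) and its
# exact derivative at points x -- the independent oracle for spectral
# differentiation tests
poly_eval <- function(co, x) {
  vapply(x, function(xx) sum(co * xx^(seq_along(co) - 1L)), numeric(1))
}
poly_deriv_eval <- function(co, x) {
  k <- seq_along(co) - 1L
  vapply(x, function(xx) sum(co[-1L] * k[-1L] * xx^(k[-1L] - 1L)),
         numeric(1))
}

# a smooth random non-negative state on the full grid (zero-flux layout)
random_state <- function(grid, variant = "proliferation") {
  x <- grid$nodes
  st <- initial_state(grid, invasion_params(), variant)
  st$n <- abs(0.5 + 0.4 * sin(2 * pi * x * runif(1, 0.5, 1.5)) *
                runif(1))
  st$f <- abs(0.5 + 0.3 * cos(pi * x) * runif(1))
  st$m <- abs(0.3 + 0.2 * sin(pi * x) * runif(1))
  st
}

fig1_params <- function() invasion_params(gamma = 0.005, eta = 10,
                                          alpha = 0.1, beta = 0)
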