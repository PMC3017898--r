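test_that("initial state follows the closed-form profiles", {
  g <- cgl_grid(30)
  p <- invasion_params()
  st <- initial_state(g, p, "proliferation")
  expect_equal(st$n[1], 1)            # exp(0)
  expect_equal(st$f[1], 0.5)
  expect_equal(st$m[1], 0.5)
  expect_equal(st$n, exp(-g$nodes^2 / p$epsilon))
  expect_equal(st$m / st$n, rep(0.5, g$N + 2))  # proportionality 1/2
  expect_true(all(st$n >= 0 & st$n <= 1))
  expect_true(all(st$f >= 0 & st$f <= 1))

  sti <- initial_state(g, invasion_params(du = 0.001), "inhibitor")
  expect_equal(sti$u, rep(0, g$N + 2))

  stb <- initial_state(g, p, "basic")
  expect_length(stb$n, g$N + 1)
  expect_equal(stb$f_right, 1 - 0.5 * exp(-1 / p$epsilon))
})

test_that("parameter validation enforces the model invariants", {
  expect_error(invasion_params(dn = 0), "dn")
  expect_error(invasion_params(dm = 0), "dm")
  expect_error(invasion_params(epsilon = 0), "epsilon")
  expect_error(invasion_params(gamma = -1), "gamma")
  g <- cgl_grid(8)
  expect_error(initial_state(g, invasion_params(), "inhibitor"), "du")
  expect_error(invasion_variant("nope"), "unknown")
  expect_identical(invasion_variant("BASIC_DIRICHLET"), "basic")
  expect_identical(invasion_variant("saturating_mde"), "saturating")
})

test_that("MDE production switches between linear and saturating laws", {
  n <- c(0, 0.5, 1)
  expect_equal(mde_production(n, "basic", 0.1), 0.1 * n)
  expect_equal(mde_production(n, "proliferation", 0.1), 0.1 * n)
  expect_equal(mde_production(n, "inhibitor", 0.1), 0.1 * n)
  expect_equal(mde_production(n, "saturating", 0.1),
               c(0, 0.025, 0))       # alpha n (1 - n)
})

test_that("haptotaxis divergence is exact on polynomial data", {
  g <- cgl_grid(16)
  ops <- boundary_operators(g)
  P <- g$N + 2
  expect_equal(haptotaxis_divergence(rep(0.7, P), rep(1, P), ops),
               rep(0, P), tolerance = 1e-10)
  expect_equal(haptotaxis_divergence(rep(0, P), g$nodes^3, ops),
               rep(0, P), tolerance = 1e-12)
  # n = 1, f = x^2: d/dx (2x) = 2 everywhere
  expect_equal(haptotaxis_divergence(rep(1, P), g$nodes^2, ops),
               rep(2, P), tolerance = 1e-8)
  expect_error(haptotaxis_divergence(rep(1, 3), g$nodes, ops), "dim")
})

test_that("basic-variant right-hand side has the expected structure", {
  g <- cgl_grid(20)
  ops <- boundary_operators(g)
  p <- fig1_params()
  st <- initial_state(g, p, "basic")

  # n = m = 0 everywhere is a fixed point whatever f is
  st0 <- st
  st0$n <- rep(0, g$N + 1); st0$m <- rep(0, g$N + 1)
  d0 <- rhs_basic(st0, g, ops, p)
  expect_equal(d0$n, rep(0, g$N + 1), tolerance = 1e-12)
  expect_equal(d0$f, rep(0, g$N + 1), tolerance = 1e-12)
  expect_equal(d0$m, rep(0, g$N + 1), tolerance = 1e-12)

  # spatially constant f: haptotaxis vanishes, pure diffusion remains
  stc <- st
  stc$f <- rep(0.8, g$N + 1); stc$f_right <- 0.8
  d <- rhs_basic(stc, g, ops, p)
  nx <- as.vector(ops$D0 %*% stc$n)   # left flux sum is 0 for constant f
  pure <- p$dn * (as.vector(ops$D1 %*% nx) +
                    boundary_sum(ops$rowLast, c(stc$n, 0)) * ops$w)
  expect_equal(d$n, pure, tolerance = 1e-10)

  expect_error(rhs_basic(initial_state(g, p, "proliferation"), g, ops, p),
               "basic")
})

test_that("zero-flux right-hand side: fixed points and pure diffusion", {
  g <- cgl_grid(20)
  ops <- boundary_operators(g)
  P <- g$N + 2

  # n = m = 0, f constant, mu2 = 0: every derivative vanishes
  p <- invasion_params(gamma = 0.01, eta = 10, alpha = 0.1, mu1 = 0.3)
  st <- initial_state(g, p, "proliferation")
  st$n <- rep(0, P); st$m <- rep(0, P); st$f <- rep(0.6, P)
  d <- rhs_zero_flux(st, g, ops, p)
  expect_equal(d$n, rep(0, P), tolerance = 1e-12)
  expect_equal(d$f, rep(0, P), tolerance = 1e-12)
  expect_equal(d$m, rep(0, P), tolerance = 1e-12)

  # all coupling off: dn/dt reduces to dn * D %*% D00 %*% n
  p2 <- invasion_params(gamma = 0, eta = 0, alpha = 0, beta = 0)
  st2 <- initial_state(g, p2, "proliferation")
  d2 <- rhs_zero_flux(st2, g, ops, p2)
  expect_equal(d2$n,
               p2$dn * as.vector(g$D %*% (ops$D00 %*% st2$n)),
               tolerance = 1e-12)

  expect_error(rhs_zero_flux(initial_state(g, p, "basic"), g, ops, p),
               "zero-flux")
})

test_that("discrete wall flux cancels identically in zero-flux scheme", {
  set.seed(11)
  g <- cgl_grid(24)
  ops <- boundary_operators(g)
  P <- g$N + 2
  p <- invasion_params(gamma = 0.02, eta = 10, alpha = 0.1, mu1 = 0.1,
                       mu2 = 0.5)
  for (rep in 1:20) {
    st <- random_state(g)
    fx <- as.vector(g$D %*% st$f)
    wvec <- numeric(P)
    wvec[1] <- fx[1] * st$n[1]
    wvec[P] <- fx[P] * st$n[P]
    nx_flux <- as.vector(ops$D00 %*% st$n) + (p$gamma / p$dn) * wvec
    flux <- p$dn * nx_flux - p$gamma * st$n * fx
    expect_lt(abs(flux[1]), 1e-12)
    expect_lt(abs(flux[P]), 1e-12)
  }
})

test_that("ECM density can only decrease when renewal is off", {
  set.seed(23)
  g <- cgl_grid(18)
  ops <- boundary_operators(g)
  p <- invasion_params(gamma = 0.01, eta = 7, alpha = 0.1, mu1 = 0.2,
                       mu2 = 0)
  for (rep in 1:20) {
    st <- random_state(g)
    d <- rhs_zero_flux(st, g, ops, p)
    expect_true(all(d$f <= 0))
  }
})

test_that("Dirichlet and zero-flux assemblies agree on interior nodes", {
  # a state decaying to ~0 at the right wall satisfies both boundary
  # treatments; the two right-hand sides then discretise the same PDE
  g <- cgl_grid(30)
  ops <- boundary_operators(g)
  p <- invasion_params(gamma = 0.005, eta = 10, alpha = 0.1, beta = 0.05)
  P <- g$N + 2
  stz <- initial_state(g, p, "proliferation")   # mu1 = mu2 = 0 here
  stb <- initial_state(g, p, "basic")
  dz <- rhs_zero_flux(stz, g, ops, p)
  db <- rhs_basic(stb, g, ops, p)
  interior <- 3:(P - 3)
  for (fl in c("n", "f", "m")) {
    expect_lt(max(abs(dz[[fl]][interior] - db[[fl]][interior])), 1e-4)
  }
})
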