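test_that("FD reference reproduces the heat-equation closed form", {
  p <- invasion_params(dn = 0.001, gamma = 0, eta = 0, alpha = 0,
                       beta = 0)
  M <- 2001L
  x <- seq(0, 1, length.out = M)
  init <- list(n = 1 + cos(pi * x), f = rep(0, M), m = rep(0, M))
  ref <- fd_reference_solve("proliferation", p, M,
                            snapshot_times = c(0, 10), initial = init)
  exact <- 1 + exp(-p$dn * pi^2 * 10) * cos(pi * x)
  expect_lt(max(abs(ref$fields$n[2, ] - exact)), 1e-4)
})

test_that("FD reference keeps an identically zero state at zero", {
  p <- invasion_params(gamma = 0.01, eta = 10, alpha = 0.1, mu1 = 0.1)
  M <- 101L
  zero <- rep(0, M)
  ref <- fd_reference_solve("proliferation", p, M,
                            snapshot_times = c(0, 5),
                            initial = list(n = zero, f = zero, m = zero))
  expect_equal(max(abs(unlist(ref$fields))), 0, tolerance = 1e-12)
  expect_error(fd_reference_solve("basic", p, 20), "M")
})

test_that("barycentric interpolation reproduces nodal and polynomial data", {
  g <- cgl_grid(30)
  vals <- sin(3 * g$nodes)
  expect_equal(barycentric_interpolate(g, vals, g$nodes), vals,
               tolerance = 1e-14)
  expect_equal(barycentric_interpolate(g, g$nodes^2, 0.3), 0.09,
               tolerance = 1e-12)
  # sharply peaked smooth function, compared with direct evaluation
  fvals <- exp(-g$nodes^2 / 0.01)
  xq <- seq(0, 1, length.out = 1001)
  expect_lt(max(abs(barycentric_interpolate(g, fvals, xq) -
                      exp(-xq^2 / 0.01))), 1e-6)
  expect_error(barycentric_interpolate(g, fvals, c(0.5, 1.2)), "within")
})

test_that("total mass integrates nodal fields as advertised", {
  g <- cgl_grid(30)
  expect_equal(total_mass(g, rep(1, g$N + 2)), 1, tolerance = 1e-12)
  expect_equal(total_mass(g, g$nodes), 0.5, tolerance = 1e-12)
  expect_equal(total_mass(g, g$nodes^4), 0.2, tolerance = 1e-12)
  expect_error(total_mass(g, rep(1, 5)), "length")
})

test_that("cluster counting matches direct inspection of known profiles", {
  x <- seq(0, 1, length.out = 1001)
  expect_identical(count_clusters(exp(-5 * x)), 1L)   # monotone decay
  expect_identical(count_clusters(rep(0, 100)), 0L)
  two <- exp(-(x - 0.1)^2 / 0.05^2) + 0.5 * exp(-(x - 0.5)^2 / 0.05^2)
  expect_identical(count_clusters(two), 2L)
  # shallow modulation is one cluster: dip never drops 10% below peaks
  shallow <- 1 + 0.01 * cos(4 * pi * x)
  expect_identical(count_clusters(shallow), 1L)
  # peaks below the height threshold are ignored
  small <- exp(-(x - 0.1)^2 / 0.05^2) +
    0.01 * exp(-(x - 0.7)^2 / 0.05^2)
  expect_identical(count_clusters(small), 1L)
  expect_error(count_clusters(numeric(0)), "empty")
  expect_error(count_clusters(c(1, NA)), "finite")
})

test_that("solution comparison is a faithful max-abs metric", {
  g <- cgl_grid(16)
  p <- invasion_params(dn = 0.001, gamma = 0, eta = 0, alpha = 0)
  st <- initial_state(g, p, "proliferation")
  st$n <- 1 + cos(pi * g$nodes)
  st$f <- rep(0, g$N + 2); st$m <- rep(0, g$N + 2)
  res <- solve_invasion("proliferation", p, g, initial = st,
                        snapshot_times = c(0, 10))
  M <- 501L
  x <- seq(0, 1, length.out = M)
  ref <- fd_reference_solve("proliferation", p, M,
                            snapshot_times = c(0, 10),
                            initial = list(n = 1 + cos(pi * x),
                                           f = rep(0, M), m = rep(0, M)))
  # both approximate the same closed form, so they agree closely
  expect_lt(compare_solutions(res, ref, "n", 10), 1e-4)
  # comparing the spectral t=0 snapshot with its own initial data
  expect_lt(compare_solutions(res, ref, "n", 0), 1e-12)
  expect_error(compare_solutions(res, ref, "n", 3.3),
               "not present|not a snapshot")
})
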