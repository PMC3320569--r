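test_that("symmetric double well has zero minima and an exact barrier", {
  s <- make_double_well_1d(c(-3, 3), barrier = 3)
  # internal maximum sits at the midpoint by symmetry and equals the barrier
  expect_equal(s$value(0), 3, tolerance = 1e-9)
  # both wells at the normalized zero
  x <- seq(-6, 6, 0.001)
  v <- s$value(x)
  left <- min(v[x < 0]); right <- min(v[x > 0])
  # 1e-3 scan granularity leaves O(curvature * h^2 / 2) ~ 1e-6 above the true 0
  expect_equal(left, 0, tolerance = 5e-6)
  expect_equal(right, 0, tolerance = 5e-6)
  expect_true(all(v > -1e-9))
})

test_that("asymmetry raises the second well by exactly the requested amount", {
  s <- make_double_well_1d(c(0, 6), barrier = 3, asymmetry = 1, width = 1.2,
                           bounds = c(-7, 16))
  x <- seq(-7, 16, 0.001)
  v <- s$value(x)
  expect_equal(min(v[x < 3]), 0, tolerance = 5e-6)
  expect_equal(min(v[x > 3 & x < 9]), 1, tolerance = 5e-6)
  # negative asymmetry flips which well is higher
  s2 <- make_double_well_1d(c(0, 6), barrier = 3, asymmetry = -0.5)
  v2 <- s2$value(x)
  expect_equal(min(v2[x < 3]), 0.5, tolerance = 5e-6)
  expect_equal(min(v2[x > 3 & x < 9]), 0, tolerance = 5e-6)
})

test_that("gradient vanishes at stationary points located on a dense grid", {
  s <- make_double_well_1d(c(-3, 3), barrier = 3, asymmetry = 0.7)
  x <- seq(-5.5, 5.5, 1e-4)
  v <- s$value(x)
  n <- length(v)
  st <- 1 + which((v[2:(n - 1)] - v[1:(n - 2)]) *
                    (v[3:n] - v[2:(n - 1)]) < 0)
  expect_length(st, 3)
  for (xi in x[st]) {
    opt <- stats::optimize(function(u) abs(s$grad(u)),
                           c(xi - 2e-4, xi + 2e-4), tol = 1e-10)
    expect_lt(abs(s$grad(opt$minimum)), 1e-6)
  }
})

test_that("surface value and gradient are finite and mutually consistent", {
  surfaces <- list(
    make_double_well_1d(c(0, 6), 3, 1, 1.2, bounds = c(-7, 16)),
    make_two_ion_surface_2d(c(0, 0), c(6, 6), 3),
    make_two_ion_surface_2d(c(0, 0), c(6, 4), 3.2, asymmetry = 0.8))
  for (s in surfaces) {
    set.seed(42)
    X <- sapply(seq_len(s$dim), function(k)
      runif(200, s$bounds[k, 1] + 0.01, s$bounds[k, 2] - 0.01))
    X <- matrix(X, ncol = s$dim)
    v <- s$value(X); g <- s$grad(X)
    expect_true(all(is.finite(v)) && all(is.finite(g)))
    gfd <- fd_gradient(s$value, X)
    denom <- pmax(sqrt(rowSums(gfd^2)), 1)
    expect_lt(max(sqrt(rowSums((g - gfd)^2)) / denom), 1e-4)
  }
})

test_that("degenerate well requests are rejected", {
  expect_error(make_double_well_1d(c(0, 6), barrier = 1, asymmetry = 1.5),
               "asymmetry")
  expect_error(make_double_well_1d(c(0, 6), barrier = 1, asymmetry = -1),
               "asymmetry")
  expect_error(make_two_ion_surface_2d(c(1, 1), c(1, 1), 3), "coincide")
  expect_error(make_two_ion_surface_2d(c(0, 0), c(6, 6), 2, asymmetry = 2.5),
               "asymmetry")
})

test_that("symmetric 2D surface has its saddle at the midpoint", {
  s <- make_two_ion_surface_2d(c(0, 0), c(6, 6), barrier = 3)
  expect_equal(s$value(c(3, 3)), 3, tolerance = 1e-9)
  expect_lt(max(abs(s$grad(c(3, 3)))), 1e-8)
  # saddle character: negative curvature along the diagonal, positive across
  h <- 1e-3
  u <- c(1, 1) / sqrt(2); w <- c(1, -1) / sqrt(2)
  along <- (s$value(c(3, 3) + h * u) - 2 * s$value(c(3, 3)) +
              s$value(c(3, 3) - h * u)) / h^2
  across <- (s$value(c(3, 3) + h * w) - 2 * s$value(c(3, 3)) +
               s$value(c(3, 3) - h * w)) / h^2
  expect_lt(along, 0)
  expect_gt(across, 0)
})

test_that("asymmetric 2D saddle value matches the grid minimax oracle", {
  s <- make_two_ion_surface_2d(c(0, 0), c(6, 4), barrier = 3.2,
                               asymmetry = 0.8)
  oracle <- minimax_saddle_oracle(s$value,
                                  rbind(c(-1.5, 7.5), c(-1.5, 5.5)),
                                  c(0, 0), c(6, 4), h = 0.05)
  expect_equal(oracle, 3.2, tolerance = 0.02)
  # higher minimum raised by the asymmetry
  g <- as.matrix(expand.grid(x = seq(4, 8, 0.01), y = seq(2, 6, 0.01)))
  expect_equal(min(s$value(g)), 0.8, tolerance = 1e-4)
})
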