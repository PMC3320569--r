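test_that("string path follows the symmetry diagonal of a mirror-symmetric
           surface", {
  s <- make_two_ion_surface_2d(c(0, 0), c(6, 6), barrier = 3)
  mep <- string_mep(s, c(0.4, -0.2), c(6.2, 5.9))
  expect_true(mep$converged)
  expect_lt(max(abs(mep$nodes[, 1] - mep$nodes[, 2])), 0.25)
  expect_equal(max(mep$F), 3, tolerance = 0.05)
  saddle <- mep$nodes[which.max(mep$F), ]
  expect_equal(as.numeric(saddle), c(3, 3), tolerance = 0.1)
})

test_that("on a quadratic bowl the string is the polyline through the
           minimum", {
  bowl <- analytic_surface(matrix(c(2, 2), 1), 0, 1, bg_k = 0.5,
                           bg_center = c(2, 2),
                           bounds = rbind(c(-2, 6), c(-2, 6)))
  mep <- string_mep(bowl, c(0, 1), c(4, 3), relax_endpoints = FALSE,
                    tol = 1e-4)
  # oracle: steepest descent on an isotropic bowl is radial, so the MEP is
  # the two straight segments endpoint -> center
  dist_to_polyline <- function(pt) {
    seg_dist <- function(a, b) {
      t <- sum((pt - a) * (b - a)) / sum((b - a)^2)
      t <- min(max(t, 0), 1)
      sqrt(sum((pt - (a + t * (b - a)))^2))
    }
    min(seg_dist(c(0, 1), c(2, 2)), seg_dist(c(2, 2), c(4, 3)))
  }
  dmax <- max(apply(mep$nodes, 1, dist_to_polyline))
  expect_lt(dmax, 0.05)
})

test_that("string saddle matches the grid minimax oracle on an asymmetric
           surface", {
  s <- make_two_ion_surface_2d(c(0, 0), c(6, 4), barrier = 3.2,
                               asymmetry = 0.8)
  mep <- string_mep(s, c(0.2, 0.1), c(5.9, 4.2))
  expect_true(mep$converged)
  oracle <- minimax_saddle_oracle(s$value,
                                  rbind(c(-1.5, 7.5), c(-1.5, 5.5)),
                                  c(0, 0), c(6, 4), h = 0.05)
  expect_lt(abs(max(mep$F) - oracle), 0.2)
})

test_that("a converged path is stationary under re-iteration", {
  s <- make_two_ion_surface_2d(c(0, 0), c(6, 4), barrier = 3.2,
                               asymmetry = 0.8)
  mep <- string_mep(s, c(0.2, 0.1), c(5.9, 4.2))
  again <- string_mep(s, mep$nodes[1, ], mep$nodes[nrow(mep$nodes), ])
  expect_lt(sqrt(mean(rowSums((again$nodes - mep$nodes)^2))), 2 * mep$tol)
})

test_that("nodes are equally spaced and the transverse gradient is small", {
  s <- make_two_ion_surface_2d(c(0, 0), c(6, 6), barrier = 3)
  mep <- string_mep(s, c(0.3, -0.3), c(5.8, 6.1))
  gaps <- diff(mep$arc)
  expect_lt(max(abs(gaps - mean(gaps))), 1e-6 * mean(gaps))
  n <- nrow(mep$nodes)
  tang <- mep$nodes[3:n, ] - mep$nodes[1:(n - 2), ]
  tang <- tang / sqrt(rowSums(tang^2))
  G <- s$grad(mep$nodes[2:(n - 1), ])
  perp <- G - tang * rowSums(G * tang)
  expect_lt(mean(sqrt(rowSums(perp^2))), 0.1)
})

test_that("profiles along paths carry F, arc length and both coordinates", {
  s <- make_two_ion_surface_2d(c(0, 0), c(6, 6), barrier = 3)
  mep <- string_mep(s, c(0.3, -0.3), c(5.8, 6.1))
  prof <- profile_along_path(s, mep)
  expect_equal(nrow(prof), 200)
  expect_named(prof, c("index", "d1", "d2", "arc", "F"))
  # symmetric double well: profile symmetric about mid-arc
  expect_lt(max(abs(prof$F - rev(prof$F))), 0.05)
  # constant surface gives a flat profile
  flat <- analytic_surface(matrix(c(0, 0), 1), 0, 1, bg_k = 0,
                           bounds = rbind(c(-5, 5), c(-5, 5)))
  straight <- cbind(seq(-3, 3, length.out = 50), seq(-3, 3, length.out = 50))
  pf <- profile_along_path(flat, straight)
  expect_equal(diff(range(pf$F)), 0)
})

test_that("barrier readout follows the forward/backward definitions", {
  rep1 <- find_minima_and_barriers(c(0.0, 2.0, 0.5), prominence = 0)
  expect_equal(nrow(rep1$minima), 2)
  expect_equal(rep1$pairs$forward, 2.0)
  expect_equal(rep1$pairs$backward, 1.5)
  expect_equal(rep1$pairs$dG, 0.5)
  # monotone profile: no internal pairs
  rep2 <- find_minima_and_barriers(seq(0, 3, length.out = 10))
  expect_equal(nrow(rep2$pairs), 0)
  # sub-prominence ripple is merged away
  prof <- c(0, 1, 0.95, 1, 2, 0.3)
  rep3 <- find_minima_and_barriers(prof, prominence = 0.1)
  expect_equal(nrow(rep3$minima), 2)
  expect_equal(rep3$minima$index, c(1, 6))
  # with zero prominence the ripple counts
  rep4 <- find_minima_and_barriers(prof, prominence = 0)
  expect_equal(nrow(rep4$minima), 3)
})

test_that("forward minus backward equals dG bitwise for every pair", {
  set.seed(77)
  for (rep in 1:20) {
    prof <- cumsum(rnorm(60))
    br <- find_minima_and_barriers(prof, prominence = 0.2)
    if (nrow(br$pairs) == 0) next
    expect_identical(br$pairs$forward - br$pairs$backward, br$pairs$dG)
    expect_true(all(br$pairs$forward >= 0))
    expect_true(all(br$pairs$backward >= 0))
    # the separating maximum bounds the climb in each direction
    expect_true(all(br$pairs$forward >= br$pairs$dG))
    expect_true(all(br$pairs$backward >= -br$pairs$dG))
  }
})

test_that("string errors on endpoints in disconnected mask components", {
  g <- quad_grid()
  g$mask[9, ] <- FALSE   # split the grid in two
  s <- interpolate_surface(g)
  left <- c(g$centers[[1]][4], g$centers[[2]][8])
  right <- c(g$centers[[1]][14], g$centers[[2]][8])
  expect_error(string_mep(s, left, right), "disconnected")
})
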