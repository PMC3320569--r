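window_from <- function(samples, center = 0, k = 10, d = 1) {
  b <- bias_potential(rep(center, d), k)
  umbrella_window(b, samples, times = seq_len(NROW(samples)) - 1)
}

test_that("half-open binning and count conservation", {
  w <- window_from(c(0.05, 0.15, 0.15))
  h <- histogram_windows(list(w), 0.1)
  i0 <- which(abs(h$centers[[1]] - 0.05) < 1e-9)
  expect_equal(h$counts[i0, 1], 1)
  expect_equal(h$counts[i0 + 1, 1], 2)
  expect_equal(sum(h$counts), 3)
  # sample exactly on an interior edge goes to the bin on its right
  h2 <- histogram_windows(list(window_from(c(0.1, 0.05))), 0.1)
  i <- which(abs(h2$centers[[1]] - 0.15) < 1e-9)
  expect_equal(h2$counts[i, 1], 1)
  # protocol-scale conservation: 20 windows x 450 samples
  set.seed(3)
  ws <- lapply(1:20, function(i) window_from(rnorm(450, i), center = i))
  expect_equal(sum(histogram_windows(ws, 0.1)$counts), 9000)
})

test_that("a single unbiased window reduces WHAM to the empirical estimator", {
  s <- make_double_well_1d(c(-1, 1), barrier = 1.5, width = 0.7,
                           bounds = c(-3, 3))
  kT <- kT_kcal(300)
  set.seed(8)
  xg <- seq(-3, 3, 0.001)
  p <- exp(-s$value(xg) / kT)
  # jitter off the grid so no sample sits exactly on a bin edge (hist()
  # closes bins on the opposite side from the half-open WHAM binning)
  x <- sample(xg, 5000, replace = TRUE, prob = p) + runif(5000, -4e-4, 4e-4)
  w <- window_from(x, center = 0, k = 0)
  pmf <- solve_wham(histogram_windows(list(w), 0.25), tol = 1e-12)
  hh <- hist(x, breaks = seq(min(pmf$centers[[1]]) - 0.125,
                             max(pmf$centers[[1]]) + 0.125, 0.25),
             plot = FALSE)
  emp <- -kT * log(hh$counts[hh$counts > 0])
  emp <- emp - min(emp)
  expect_equal(pmf$values[pmf$mask], emp, tolerance = 1e-10)
})

test_that("two coincident windows equal one window holding pooled counts", {
  set.seed(4)
  x1 <- rnorm(300, 0, 0.3); x2 <- rnorm(300, 0, 0.3)
  two <- list(window_from(x1), window_from(x2))
  one <- list(window_from(c(x1, x2)))
  edges_match <- function(h1, h2) isTRUE(all.equal(h1$edges, h2$edges))
  h_two <- histogram_windows(two, 0.1)
  h_one <- histogram_windows(one, 0.1)
  expect_true(edges_match(h_two, h_one))
  p_two <- solve_wham(h_two, tol = 1e-12)
  p_one <- solve_wham(h_one, tol = 1e-12)
  expect_equal(p_two$values[p_two$mask], p_one$values[p_one$mask],
               tolerance = 1e-10)
})

test_that("solver matches direct likelihood minimization on small problems", {
  set.seed(11)
  cases <- list(
    list(ws = list(window_from(rnorm(200, -0.4, 0.25), -0.5),
                   window_from(rnorm(200, 0.0, 0.25), 0),
                   window_from(rnorm(200, 0.4, 0.25), 0.5)), bw = 0.25),
    list(ws = list(window_from(rnorm(150, 0.2, 0.3), 0, k = 5),
                   window_from(rnorm(150, 0.8, 0.3), 1, k = 5)), bw = 0.3))
  for (cs in cases) {
    h <- histogram_windows(cs$ws, cs$bw)
    expect_lte(length(h$centers[[1]]), 20)
    pmf <- solve_wham(h, tol = 1e-11)
    oracle <- wham_likelihood_oracle(h)
    est <- pmf$values[pmf$mask]
    ref <- oracle$F
    ref <- ref - mean(ref) + mean(est)
    expect_lt(max(abs(est - ref)), 1e-6)
    expect_lt(wham_selfconsistency_residual(h, pmf), 1e-9)
  }
})

test_that("PMF is invariant to window order and bias energy offsets", {
  qp <- quick_protocol_1d(seed = 31)
  wins <- qp$sampled
  p1 <- solve_wham(histogram_windows(wins, 0.1))
  p2 <- solve_wham(histogram_windows(rev(wins), 0.1))
  expect_equal(p1$values, p2$values, tolerance = 1e-6)
  expect_equal(p1$mask, p2$mask)
})

test_that("PMF error decreases with tenfold more samples per window", {
  errs <- sapply(1:5, function(seed) {
    vapply(c(500, 5000), function(dur) {
      qp <- quick_protocol_1d(seed = 7000 + seed, duration = dur)
      p <- solve_wham(histogram_windows(qp$sampled, 0.1))
      sel <- p$mask & p$counts >= 20
      Ft <- qp$surface$value(p$centers[[1]])
      err <- p$values[sel] - Ft[sel]
      err <- err - mean(err)
      sqrt(mean(err^2))
    }, numeric(1))
  })
  expect_lt(mean(errs[2, ]), mean(errs[1, ]))
})

test_that("the -kT ln p estimator tracks temperature for unbiased windows", {
  s <- make_double_well_1d(c(-1, 1), barrier = 1.5, width = 0.7,
                           bounds = c(-3, 3))
  set.seed(21)
  xg <- seq(-3, 3, 0.001)
  v <- s$value(xg)
  for (Tm in c(150, 600)) {
    # samples drawn at Tm; the reconstruction at the same Tm must recover
    # the bin-averaged Boltzmann oracle of the surface at every well-sampled
    # bin, i.e. well depths in kcal/mol are temperature independent
    kT <- kT_kcal(Tm)
    x <- sample(xg, 40000, replace = TRUE, prob = exp(-v / kT)) +
      runif(40000, -4e-4, 4e-4)
    w <- umbrella_window(bias_potential(0, 0), x,
                         times = seq_along(x) - 1, temperature = Tm)
    pmf <- solve_wham(histogram_windows(list(w), 0.25))
    cc <- pmf$centers[[1]]
    bin_idx <- findInterval(xg, c(cc - 0.125, max(cc) + 0.125))
    p_true <- vapply(seq_along(cc), function(i)
      sum(exp(-v[bin_idx == i] / kT)), numeric(1))
    F_true <- -kT * log(p_true)
    sel <- pmf$mask & pmf$counts >= 500
    err <- pmf$values[sel] - F_true[sel]
    err <- err - mean(err)
    expect_lt(max(abs(err)), 0.15)
  }
})

test_that("disconnected window coverage is reported with its components", {
  wA <- window_from(rnorm(100, 0, 0.1), 0)
  wB <- window_from(rnorm(100, 10, 0.1), 10)
  expect_error(solve_wham(histogram_windows(list(wA, wB), 0.1)),
               "disconnected")
})

test_that("alignment conventions shift values as stated", {
  w <- window_from(c(rep(0.05, 4), rep(0.15, 2), rep(0.25, 1)), k = 0)
  p <- solve_wham(histogram_windows(list(w), 0.1))
  expect_equal(min(p$values[p$mask]), 0)
  p2 <- align_pmf(p, "min-zero")
  expect_equal(p2$values, p$values)
  anchor <- pmf_bin_at(p, 0.15)
  p3 <- align_pmf(p, "anchor", anchor)
  expect_equal(p3$values[anchor], 0)
  expect_equal(p3$values - min(p3$values[p3$mask]), p$values)
  # differences are convention independent and antisymmetric
  a <- pmf_bin_at(p, 0.05); b <- pmf_bin_at(p, 0.25)
  expect_equal(pmf_difference(p, a, b), pmf_difference(p3, a, b))
  expect_equal(pmf_difference(p, a, b), -pmf_difference(p, b, a))
  expect_equal(pmf_difference(p, a, a), 0)
  expect_error(pmf_difference(p, pmf_bin_at(p, min(p$centers[[1]])), a),
               "mask")
})

test_that("recovered well asymmetry matches the constructed landscape", {
  # single-run noise in the well-to-well difference is ~0.3 kcal/mol under
  # the 450-sample protocol, so compare the mean over three seeds
  dgs <- vapply(c(1111, 2222, 3333), function(seed) {
    qp <- quick_protocol_1d(seed = seed)
    p <- solve_wham(histogram_windows(qp$sampled, 0.1))
    near_min <- function(x0) {
      i <- pmf_bin_at(p, x0)
      span <- max(1, i - 10):min(length(p$values), i + 10)
      span[which.min(p$values[span])]
    }
    pmf_difference(p, near_min(6), near_min(0))
  }, numeric(1))
  expect_equal(mean(dgs), 1.0, tolerance = 0.5)
})
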