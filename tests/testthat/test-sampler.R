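flat_surface <- function(half_width = 50) {
  analytic_surface(matrix(0, 1, 1), 0, 1, bg_k = 0,
                   bounds = matrix(c(-half_width, half_width), 1))
}

test_that("thermal energy constant matches 0.596 kcal/mol at 300 K", {
  expect_equal(kT_kcal(300), 0.59616123, tolerance = 1e-8)
})

test_that("harmonic-bias sampling matches the Ornstein-Uhlenbeck law", {
  # surface == 0, bias k = 10 at center c: stationary Gaussian with mean c
  # and variance kT/k (1/2-factor convention: U = k/2 (x-c)^2)
  k <- 10; cc <- 1.5
  cfg <- sampler_config(n_samples = 20000, stride = 2, seed = 71)
  w <- sample_window(flat_surface(), bias_potential(cc, k), cfg)
  x <- as.numeric(w$samples)
  n <- length(x)
  var_true <- kT_kcal(300) / k            # 0.0596 A^2
  se_mean <- sqrt(var_true / n)
  se_var <- var_true * sqrt(2 / n)
  expect_lt(abs(mean(x) - cc), 3 * se_mean)
  expect_lt(abs(stats::var(x) - var_true), 3 * se_var + 0.01 * var_true)
})

test_that("zero-temperature limit collapses onto the potential minimum", {
  # scaling kT and D together keeps the deterministic drift and removes the
  # noise: every sample ends within 1e-2 A of the minimum of surface + bias
  s <- make_double_well_1d(c(-3, 3), barrier = 3)
  cfg <- sampler_config(temperature = 300e-6, diffusion = 0.1e-6,
                        n_samples = 200, stride = 1, seed = 5)
  b <- bias_potential(-2.4, 10)
  w <- sample_window(s, b, cfg)
  total <- function(x) s$value(x) + bias_energy(b, x)
  xmin <- stats::optimize(total, c(-4, 0), tol = 1e-10)$minimum
  # skip the deterministic descent transient from the bias center
  expect_lt(max(abs(w$samples[-(1:5), ] - xmin)), 1e-2)
})

test_that("sampling is a pure function of seed and config", {
  s <- make_double_well_1d(c(-3, 3), barrier = 3)
  cfg <- sampler_config(n_samples = 50, seed = 99)
  w1 <- sample_window(s, bias_potential(0), cfg)
  w2 <- sample_window(s, bias_potential(0), cfg)
  expect_identical(w1$samples, w2$samples)
  cfg2 <- sampler_config(n_samples = 50, seed = 100)
  w3 <- sample_window(s, bias_potential(0), cfg2)
  expect_false(identical(w1$samples, w3$samples))
})

test_that("empirical distribution passes a chi-square test against the
           analytic Gaussian for nearly all seeds", {
  k <- 10
  var_true <- kT_kcal(300) / k
  pvals <- vapply(1:10, function(seed) {
    cfg <- sampler_config(n_samples = 1e5, stride = 2, seed = 1000 + seed)
    w <- sample_window(flat_surface(), bias_potential(0, k), cfg)
    x <- as.numeric(w$samples)
    edges <- stats::qnorm(seq(0, 1, length.out = 21), 0, sqrt(var_true))
    obs <- table(cut(x, edges))
    stats::chisq.test(as.numeric(obs),
                      p = rep(1 / 20, 20))$p.value
  }, numeric(1))
  expect_gte(sum(pvals > 0.001), 9)
})

test_that("histogram converges to the Boltzmann weight as samples grow", {
  s <- make_double_well_1d(c(-1.5, 1.5), barrier = 2, width = 0.8,
                           bounds = c(-4, 4))
  b <- bias_potential(0, 1)
  kT <- kT_kcal(300)
  err_for <- function(n, seed) {
    cfg <- sampler_config(n_samples = n, stride = 2, seed = seed)
    w <- sample_window(s, b, cfg)
    br <- seq(-4, 4, 0.25)
    hh <- hist(as.numeric(w$samples), breaks = br, plot = FALSE)
    xc <- hh$mids
    pt <- exp(-(s$value(xc) + bias_energy(b, xc)) / kT)
    pt <- pt / sum(pt)
    keep <- hh$counts >= 100
    max(abs(hh$counts[keep] / sum(hh$counts) - pt[keep]))
  }
  errs <- vapply(1:4, function(sd)
    c(err_for(2000, sd), err_for(20000, sd)), numeric(2))
  expect_lt(mean(errs[2, ]), mean(errs[1, ]))
})

test_that("an unstable time step is reported instead of silently diverging", {
  steep <- analytic_surface(matrix(0, 1, 1), 0, 1, bg_k = 500,
                            bounds = matrix(c(-5, 5), 1))
  cfg <- sampler_config(n_samples = 100, dt = 0.05, stride = 1, seed = 1,
                        margin = 0.5)
  expect_error(sample_window(steep, bias_potential(4.5, 10), cfg),
               "unstable")
})
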