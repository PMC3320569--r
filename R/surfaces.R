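#' @useDynLib ionpmf, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Boltzmann constant in kcal/mol/K
#'
#' @param temperature Temperature in K.
#' @return Thermal energy kT in kcal/mol (about 0.596 kcal/mol at 300 K).
#' @export
kT_kcal <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  0.0019872041 * temperature
}

as_point_matrix <- function(x, dim) {
  if (is.matrix(x)) {
    if (ncol(x) != dim) stop("point matrix must have ", dim, " column(s)")
    return(x)
  }
  if (length(x) == dim) return(matrix(as.numeric(x), nrow = 1L))
  if (dim == 1L) return(matrix(as.numeric(x), ncol = 1L))
  stop("cannot interpret input as points of dimensionality ", dim)
}

#' Construct an analytic free-energy landscape
#'
#' Landscapes are sums of inverted isotropic Gaussian wells on a weak
#' confining quadratic background,
#' \deqn{F(x) = \sum_m -A_m e^{-|x - c_m|^2 / 2\sigma_m^2} + b|x - x_0|^2,}
#' normalized so the minimum over the domain is exactly 0.  They carry
#' closed-form value and gradient evaluators (kcal/mol and kcal/mol/A) and
#' are the ground truth against which the sampling/WHAM/string pipeline is
#' validated by parameter recovery.
#'
#' @param centers Matrix of well centers (one row per well), in A.
#' @param depths Well depths A_m in kcal/mol (positive).
#' @param widths Gaussian widths sigma_m in A (positive).
#' @param bg_k Background curvature b in kcal/mol/A^2 (>= 0).
#' @param bg_center Center of the quadratic background, in A.
#' @param bounds Matrix with one row per dimension, columns lower/upper (A).
#' @return An object of class \code{analytic_surface} with elements
#'   \code{dim}, \code{value(x)}, \code{grad(x)}, \code{params} (well table,
#'   background, normalization offset) and \code{bounds}.
#' @export
analytic_surface <- function(centers, depths, widths, bg_k = 0,
                             bg_center = NULL, bounds) {
  centers <- as.matrix(centers)
  d <- ncol(centers)
  m <- nrow(centers)
  stopifnot(d %in% c(1L, 2L), length(depths) == m, length(widths) == m,
            all(depths >= 0), all(widths > 0), bg_k >= 0)
  bounds <- matrix(as.numeric(bounds), ncol = 2L)
  stopifnot(nrow(bounds) == d, all(bounds[, 2] > bounds[, 1]))
  if (is.null(bg_center)) bg_center <- colMeans(centers)
  bg_center <- as.numeric(bg_center)
  stopifnot(length(bg_center) == d)

  raw_value <- function(X) {
    cpp_surface_value(as_point_matrix(X, d), centers, as.numeric(depths),
                      as.numeric(widths), bg_k, bg_center, 0)
  }
  # normalize: coarse grid scan then local polish from the best grid point
  grid_axes <- lapply(seq_len(d), function(k)
    seq(bounds[k, 1], bounds[k, 2], length.out = if (d == 1L) 4096L else 256L))
  G <- as.matrix(expand.grid(grid_axes))
  vg <- raw_value(G)
  x_best <- G[which.min(vg), , drop = TRUE]
  raw_grad <- function(x)
    cpp_surface_grad(rbind(x), centers, as.numeric(depths),
                     as.numeric(widths), bg_k, bg_center)
  pol <- stats::optim(x_best, function(x) raw_value(rbind(x)),
                      gr = function(x) as.numeric(raw_grad(x)),
                      method = "L-BFGS-B", lower = bounds[, 1],
                      upper = bounds[, 2],
                      control = list(factr = 10, pgtol = 1e-12))
  offset <- min(min(vg), pol$value)

  obj <- list(
    dim = d,
    params = list(centers = centers, depths = as.numeric(depths),
                  widths = as.numeric(widths), bg_k = bg_k,
                  bg_center = bg_center, offset = offset),
    bounds = bounds)
  obj$value <- function(x)
    cpp_surface_value(as_point_matrix(x, d), centers, as.numeric(depths),
                      as.numeric(widths), bg_k, bg_center, offset)
  obj$grad <- function(x)
    cpp_surface_grad(as_point_matrix(x, d), centers, as.numeric(depths),
                     as.numeric(widths), bg_k, bg_center)
  class(obj) <- "analytic_surface"
  obj
}

#' @export
print.analytic_surface <- function(x, ...) {
  cat("Analytic free-energy surface (", x$dim, "D)\n", sep = "")
  cat("  wells:\n")
  for (w in seq_len(nrow(x$params$centers)))
    cat(sprintf("    center (%s) A, depth %.4g kcal/mol, width %.3g A\n",
                paste(signif(x$params$centers[w, ], 4), collapse = ", "),
                x$params$depths[w], x$params$widths[w]))
  cat(sprintf("  background: %.3g kcal/mol/A^2 about (%s)\n", x$params$bg_k,
              paste(signif(x$params$bg_center, 4), collapse = ", ")))
  cat(sprintf("  domain: %s A\n",
              paste(apply(x$bounds, 1, function(b)
                sprintf("[%.3g, %.3g]", b[1], b[2])), collapse = " x ")))
  invisible(x)
}

# 1D section profile used by the depth calibration: two wells at arc
# positions 0 and L along the line joining the centers, with the background
# reduced to b (s - L/2)^2 (exact when the background center is the midpoint).
section_value <- function(s, A, L, sigma, bg_k) {
  -A[1] * exp(-s^2 / (2 * sigma^2)) -
    A[2] * exp(-(s - L)^2 / (2 * sigma^2)) + bg_k * (s - L / 2)^2
}

section_features <- function(A, L, sigma, bg_k) {
  f <- function(s) section_value(s, A, L, sigma, bg_k)
  pad <- 3 * sigma
  m1 <- stats::optimize(f, c(-pad, L / 2))
  m2 <- stats::optimize(f, c(L / 2, L + pad))
  mx <- stats::optimize(f, c(m1$minimum + 1e-6, m2$minimum - 1e-6),
                        maximum = TRUE)
  list(min1 = m1$objective, min2 = m2$objective, max = mx$objective,
       s_min1 = m1$minimum, s_min2 = m2$minimum, s_max = mx$maximum)
}

# Solve for the two well depths giving an exact barrier (saddle minus lower
# minimum) and exact asymmetry (second minus first minimum) on the section.
calibrate_depths <- function(L, sigma, bg_k, barrier, asymmetry) {
  resid <- function(A) {
    ft <- section_features(A, L, sigma, bg_k)
    lo <- min(ft$min1, ft$min2)
    c(ft$max - lo - barrier, (ft$min2 - ft$min1) - asymmetry)
  }
  A <- rep(barrier + abs(asymmetry) + 1, 2)
  for (iter in 1:80) {
    r <- resid(A)
    if (max(abs(r)) < 1e-11) break
    J <- matrix(0, 2, 2)
    h <- 1e-6 * pmax(A, 1)
    for (j in 1:2) {
      Ah <- A; Ah[j] <- Ah[j] + h[j]
      J[, j] <- (resid(Ah) - r) / h[j]
    }
    step <- tryCatch(solve(J, r), error = function(e)
      stop("depth calibration failed: wells too wide for the requested ",
           "barrier/asymmetry"))
    # damped Newton, keep depths positive
    lambda <- 1
    repeat {
      An <- A - lambda * step
      if (all(An > 0)) break
      lambda <- lambda / 2
      if (lambda < 1e-8) stop("depth calibration failed: no positive solution")
    }
    A <- An
  }
  if (max(abs(resid(A))) > 1e-8)
    stop("depth calibration did not converge; try narrower wells")
  A
}

#' Double-well 1D free-energy landscape
#'
#' Builds an analytic 1D landscape with exactly two local minima near the
#' requested centers and one internal maximum, with the barrier (internal
#' maximum minus lower minimum) and the asymmetry (second-center minimum
#' minus first-center minimum) matched exactly by calibrating the two well
#' depths.  The lower minimum sits at free energy 0.
#'
#' @param centers Two distinct well positions, A.
#' @param barrier Barrier height above the lower minimum, kcal/mol (> 0).
#' @param asymmetry Free-energy of the second-center well minus the first,
#'   kcal/mol; must satisfy \code{barrier > abs(asymmetry)}.
#' @param width Gaussian well width sigma, A.
#' @param bg_k Confining background curvature, kcal/mol/A^2.
#' @param bounds Domain bounds c(lower, upper), A; default pads the centers.
#' @return An \code{analytic_surface}.
#' @examples
#' s <- make_double_well_1d(c(-3, 3), barrier = 3)
#' s$value(0)   # 3 at the internal maximum
#' @export
make_double_well_1d <- function(centers, barrier, asymmetry = 0, width = 1,
                                bg_k = 0.05, bounds = NULL) {
  stopifnot(length(centers) == 2, centers[1] != centers[2],
            barrier > 0, width > 0)
  if (barrier <= abs(asymmetry))
    stop("barrier must exceed |asymmetry|, otherwise the second well vanishes")
  ord <- order(centers)
  c_lo <- centers[ord[1]]; c_hi <- centers[ord[2]]
  L <- c_hi - c_lo
  asym_section <- if (ord[1] == 1L) asymmetry else -asymmetry
  A <- calibrate_depths(L, width, bg_k, barrier, asym_section)
  if (is.null(bounds))
    bounds <- c(c_lo - 3 * width - 2, c_hi + 3 * width + 2)
  s <- analytic_surface(matrix(c(c_lo, c_hi), ncol = 1), A, rep(width, 2),
                        bg_k = bg_k, bg_center = (c_lo + c_hi) / 2,
                        bounds = matrix(bounds, ncol = 2))
  check_topology_1d(s)
  s
}

check_topology_1d <- function(s) {
  x <- seq(s$bounds[1, 1], s$bounds[1, 2], length.out = 4001L)
  v <- s$value(x)
  n <- length(v)
  is_min <- v[2:(n - 1)] < v[1:(n - 2)] & v[2:(n - 1)] < v[3:n]
  is_max <- v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]
  if (sum(is_min) != 2L || sum(is_max) != 1L)
    stop("constructed landscape does not have two minima and one internal ",
         "maximum; reduce the well width or enlarge the center separation")
  invisible(s)
}

#' Two-basin 2D free-energy landscape
#'
#' Two inverted isotropic Gaussian wells at the requested minima joined
#' through a single saddle, on a weak confining quadratic background
#' centered at their midpoint.  Both wells and the background center lie on
#' the line joining the minima, so all stationary points lie on that line;
#' the barrier (saddle minus lower minimum) and the asymmetry (minimum B
#' minus minimum A) are matched exactly by depth calibration.  For a
#' mirror-symmetric instance (asymmetry 0) the saddle is the midpoint.
#'
#' @param minimaA,minimaB Basin centers (d1, d2), A.
#' @param barrier Saddle height above the lower minimum, kcal/mol.
#' @param valley_width Gaussian width sigma of both wells, A.
#' @param asymmetry F(minimum B) - F(minimum A), kcal/mol;
#'   \code{barrier > abs(asymmetry)}.
#' @param bg_k Confining background curvature, kcal/mol/A^2.
#' @param bounds 2 x 2 matrix of domain bounds (rows d1, d2), A; default pads
#'   the bounding box of the minima.
#' @return An \code{analytic_surface}.
#' @export
make_two_ion_surface_2d <- function(minimaA, minimaB, barrier,
                                    valley_width = 1.5, asymmetry = 0,
                                    bg_k = 0.05, bounds = NULL) {
  minimaA <- as.numeric(minimaA); minimaB <- as.numeric(minimaB)
  stopifnot(length(minimaA) == 2, length(minimaB) == 2,
            barrier > 0, valley_width > 0)
  L <- sqrt(sum((minimaB - minimaA)^2))
  if (L < 1e-9) stop("degenerate surface: the two minima coincide")
  if (barrier <= abs(asymmetry))
    stop("barrier must exceed |asymmetry|, otherwise the second well vanishes")
  A <- calibrate_depths(L, valley_width, bg_k, barrier, asymmetry)
  if (is.null(bounds)) {
    pad <- 3 * valley_width + 2
    bounds <- cbind(pmin(minimaA, minimaB) - pad, pmax(minimaA, minimaB) + pad)
  }
  analytic_surface(rbind(minimaA, minimaB), A, rep(valley_width, 2),
                   bg_k = bg_k, bg_center = (minimaA + minimaB) / 2,
                   bounds = bounds)
}
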