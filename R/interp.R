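# Catmull-Rom (cubic convolution, a = -1/2) basis on t in [0, 1] for the
# four stencil nodes p_{-1}, p_0, p_1, p_2.  Interpolates the nodes, is C^1
# across cells and reproduces polynomials up to degree 2 exactly.
cr_weights <- function(t) {
  cbind(-0.5 * t + t^2 - 0.5 * t^3,
        1 - 2.5 * t^2 + 1.5 * t^3,
        0.5 * t + 2 * t^2 - 1.5 * t^3,
        -0.5 * t^2 + 0.5 * t^3)
}

cr_dweights <- function(t) {
  cbind(-0.5 + 2 * t - 1.5 * t^2,
        -5 * t + 4.5 * t^2,
        0.5 + 4 * t - 4.5 * t^2,
        -t + 1.5 * t^2)
}

# Fill NA holes by repeated nearest-neighbour dilation (mean of valid
# 8-neighbours), then pad by 2 ghost rows/cols of linear extrapolation.
# The fill only provides stencil support near the mask boundary; queries
# over unmasked cells are still rejected.
fill_and_pad <- function(V) {
  n1 <- nrow(V); n2 <- ncol(V)
  guard <- 0
  while (anyNA(V) && guard < n1 + n2) {
    guard <- guard + 1
    holes <- which(is.na(V), arr.ind = TRUE)
    upd <- rep(NA_real_, nrow(holes))
    for (r in seq_len(nrow(holes))) {
      i <- holes[r, 1]; j <- holes[r, 2]
      nb <- V[max(1, i - 1):min(n1, i + 1), max(1, j - 1):min(n2, j + 1)]
      if (any(!is.na(nb))) upd[r] <- mean(nb, na.rm = TRUE)
    }
    V[holes] <- upd
  }
  if (anyNA(V)) stop("grid has no valid values to interpolate")
  P <- matrix(NA_real_, n1 + 4, n2 + 4)
  P[3:(n1 + 2), 3:(n2 + 2)] <- V
  for (k in 1:2) {
    P[3 - k, ] <- 2 * P[4 - k, ] - P[5 - k, ]
    P[n1 + 2 + k, ] <- 2 * P[n1 + 1 + k, ] - P[n1 + k, ]
    P[, 3 - k] <- 2 * P[, 4 - k] - P[, 5 - k]
    P[, n2 + 2 + k] <- 2 * P[, n2 + 1 + k] - P[, n2 + k]
  }
  P
}

#' Continuous C1 interpolant of a 2D PMF grid
#'
#' Piecewise-cubic (Catmull-Rom tensor product) interpolation of the masked
#' free-energy values with analytic gradients, as required by the string
#' method's gradient descent.  Values at bin centers are reproduced
#' exactly; queries in cells whose four corner bins are not all masked-in
#' raise an error.  A bilinear scheme is available as a fallback.
#'
#' @param p A 2D \code{pmf_grid} (or any list with \code{centers},
#'   \code{values}, \code{mask}).
#' @param scheme "cubic" (default) or "bilinear".
#' @return An \code{interp_surface} with elements \code{value(x)},
#'   \code{grad(x)} (both vectorized over rows of a matrix),
#'   \code{is_inside(x)}, \code{centers}, \code{bin_width}, \code{mask}.
#' @export
interpolate_surface <- function(p, scheme = c("cubic", "bilinear")) {
  scheme <- match.arg(scheme)
  if (!is.matrix(p$values) || !isTRUE(p$dim == 2L))
    stop("interpolate_surface requires a 2D grid")
  cx <- p$centers[[1]]; cy <- p$centers[[2]]
  hx <- cx[2] - cx[1]; hy <- cy[2] - cy[1]
  V <- p$values
  V[!p$mask] <- NA_real_
  P <- fill_and_pad(V)     # indices shifted by +2
  mask <- p$mask
  n1 <- length(cx); n2 <- length(cy)

  locate <- function(X) {
    i <- pmin(pmax(findInterval(X[, 1], cx), 1L), n1 - 1L)
    j <- pmin(pmax(findInterval(X[, 2], cy), 1L), n2 - 1L)
    list(i = i, j = j,
         u = (X[, 1] - cx[i]) / hx, v = (X[, 2] - cy[j]) / hy)
  }
  check_inside <- function(X, loc) {
    ok <- X[, 1] >= cx[1] & X[, 1] <= cx[n1] &
      X[, 2] >= cy[1] & X[, 2] <= cy[n2]
    ok <- ok & mask[cbind(loc$i, loc$j)] & mask[cbind(loc$i + 1L, loc$j)] &
      mask[cbind(loc$i, loc$j + 1L)] & mask[cbind(loc$i + 1L, loc$j + 1L)]
    ok
  }

  eval_cells <- function(X, deriv = FALSE) {
    X <- as_point_matrix(X, 2L)
    loc <- locate(X)
    ok <- check_inside(X, loc)
    if (!all(ok)) {
      bad <- which(!ok)[1]
      stop(sprintf(
        "query point (%.4g, %.4g) is outside the masked region",
        X[bad, 1], X[bad, 2]))
    }
    n <- nrow(X)
    if (scheme == "bilinear") {
      u <- loc$u; v <- loc$v
      g00 <- P[cbind(loc$i + 2L, loc$j + 2L)]
      g10 <- P[cbind(loc$i + 3L, loc$j + 2L)]
      g01 <- P[cbind(loc$i + 2L, loc$j + 3L)]
      g11 <- P[cbind(loc$i + 3L, loc$j + 3L)]
      val <- (1 - u) * (1 - v) * g00 + u * (1 - v) * g10 +
        (1 - u) * v * g01 + u * v * g11
      if (!deriv) return(val)
      gx <- ((1 - v) * (g10 - g00) + v * (g11 - g01)) / hx
      gy <- ((1 - u) * (g01 - g00) + u * (g11 - g10)) / hy
      return(cbind(gx, gy))
    }
    wu <- cr_weights(loc$u); wv <- cr_weights(loc$v)
    if (deriv) { du <- cr_dweights(loc$u); dv <- cr_dweights(loc$v) }
    val <- numeric(n); gx <- numeric(n); gy <- numeric(n)
    for (a in 1:4) for (b in 1:4) {
      g <- P[cbind(loc$i + a, loc$j + b)]   # stencil node (i-1..i+2)+2 offset
      if (deriv) {
        gx <- gx + du[, a] * wv[, b] * g
        gy <- gy + wu[, a] * dv[, b] * g
      } else {
        val <- val + wu[, a] * wv[, b] * g
      }
    }
    if (deriv) cbind(gx / hx, gy / hy) else val
  }

  structure(list(
    centers = p$centers, bin_width = c(hx, hy), mask = mask,
    scheme = scheme,
    value = function(x) eval_cells(x, deriv = FALSE),
    grad = function(x) eval_cells(x, deriv = TRUE),
    is_inside = function(x) {
      X <- as_point_matrix(x, 2L)
      check_inside(X, locate(X))
    }), class = "interp_surface")
}

# connected component (4-neighbour) of masked bins containing a bin index
mask_component <- function(mask, start) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  comp <- matrix(FALSE, n1, n2)
  if (!mask[start[1], start[2]]) return(comp)
  queue <- matrix(start, ncol = 2)
  comp[start[1], start[2]] <- TRUE
  while (nrow(queue) > 0) {
    cur <- queue
    queue <- matrix(integer(0), ncol = 2)
    for (s in seq_len(nrow(cur))) {
      i <- cur[s, 1]; j <- cur[s, 2]
      for (dd in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        a <- i + dd[1]; b <- j + dd[2]
        if (a >= 1 && a <= n1 && b >= 1 && b <= n2 &&
            mask[a, b] && !comp[a, b]) {
          comp[a, b] <- TRUE
          queue <- rbind(queue, c(a, b))
        }
      }
    }
  }
  comp
}
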