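#' Histogram umbrella windows on a common grid
#'
#' Builds half-open bins [edge_i, edge_{i+1}) of the requested width on a
#' common grid spanning the union of all window samples, padded by one bin
#' on each side.  A sample exactly on an interior edge is assigned to the
#' bin on its right.
#'
#' @param windows List of \code{umbrella_window} (same dimensionality; the
#'   equilibration period should already be discarded).
#' @param bin_width Bin width per dimension, A (recycled; defaults 0.1 for
#'   1D and 0.25 for 2D).
#' @param temperature Temperature, K; defaults to the windows' common value.
#' @return A \code{histogram_set}: bin \code{edges}/\code{centers} per
#'   dimension, a bins x windows \code{counts} matrix (d1-major flattening
#'   in 2D), per-window totals \code{N}, the aligned \code{biases} and the
#'   temperature.
#' @export
histogram_windows <- function(windows, bin_width = NULL, temperature = NULL) {
  stopifnot(length(windows) >= 1)
  if (inherits(windows, "umbrella_window")) windows <- list(windows)
  d <- windows[[1]]$bias$dim
  if (!all(vapply(windows, function(w) w$bias$dim, integer(1)) == d))
    stop("all windows must share the same dimensionality")
  if (is.null(bin_width)) bin_width <- if (d == 1L) 0.1 else 0.25
  bin_width <- rep_len(as.numeric(bin_width), d)
  stopifnot(all(bin_width > 0))
  if (is.null(temperature)) {
    temps <- unique(vapply(windows, function(w) w$temperature, numeric(1)))
    if (length(temps) > 1) stop("windows carry different temperatures; ",
                                "pass `temperature` explicitly")
    temperature <- temps
  }

  edges <- lapply(seq_len(d), function(k) {
    v <- unlist(lapply(windows, function(w) w$samples[, k]))
    w <- bin_width[k]
    lo <- (floor(min(v) / w) - 1) * w
    hi <- (ceiling(max(v) / w) + 1) * w
    seq(lo, hi, by = w)
  })
  nb <- vapply(edges, length, integer(1)) - 1L
  nbins <- prod(nb)

  bin_index <- function(S) {
    idx <- matrix(0L, nrow(S), d)
    for (k in seq_len(d)) {
      e <- edges[[k]]
      i <- floor((S[, k] - e[1]) / bin_width[k]) + 1
      idx[, k] <- as.integer(pmin(pmax(i, 1), nb[k]))
    }
    if (d == 1L) idx[, 1] else (idx[, 1] - 1L) * nb[2] + idx[, 2]
  }

  counts <- matrix(0, nbins, length(windows))
  for (i in seq_along(windows)) {
    t <- tabulate(bin_index(windows[[i]]$samples), nbins = nbins)
    counts[, i] <- t
  }
  structure(list(dim = d, edges = edges,
                 centers = lapply(edges, function(e)
                   (e[-1] + e[-length(e)]) / 2),
                 nb = nb, bin_width = bin_width, counts = counts,
                 N = colSums(counts), biases = lapply(windows, `[[`, "bias"),
                 temperature = temperature),
            class = "histogram_set")
}

# bin centers as an nbins x d matrix in the d1-major flattening used above
grid_points <- function(h) {
  if (h$dim == 1L) return(matrix(h$centers[[1]], ncol = 1))
  as.matrix(expand.grid(d2 = h$centers[[2]], d1 = h$centers[[1]]))[, c("d1", "d2")]
}

#' Solve the self-consistent WHAM equations
#'
#' Iterates the standard coupled equations for the unbiased bin
#' probabilities p_j and per-window free-energy constants f_i,
#' \deqn{p_j = \frac{\sum_i H_{ij}}{\sum_i N_i e^{(f_i - U_i(x_j))/kT}},
#'       \quad e^{-f_i/kT} = \sum_j p_j e^{-U_i(x_j)/kT},}
#' with bias energies evaluated at bin centers, until the largest change in
#' any f_i drops below \code{tol}.  The result is
#' F(bin) = -kT ln p(bin), shifted so the minimum over masked bins is 0.
#'
#' @param h A \code{histogram_set}.
#' @param tol Convergence tolerance on max |delta f_i|, kcal/mol.
#' @param max_iter Maximum number of iterations.
#' @param min_counts Bins with fewer total counts are masked out (never
#'   extrapolated).
#' @return A \code{pmf_grid}: bin \code{centers}, free-energy \code{values}
#'   (vector in 1D, d1 x d2 matrix in 2D; NA outside the mask),
#'   \code{mask}, total counts, window constants \code{f}, iteration count
#'   and final residual.
#' @export
solve_wham <- function(h, tol = 1e-7, max_iter = 100000, min_counts = 1) {
  stopifnot(inherits(h, "histogram_set"))
  M <- rowSums(h$counts)
  if (!any(M > 0)) stop("histogram contains no counts")
  comps <- window_components(h)
  if (length(comps) > 1)
    stop("window coverage is disconnected; components: ",
         paste(vapply(comps, function(x) paste(x, collapse = ","),
                      character(1)), collapse = " | "))
  kT <- kT_kcal(h$temperature)
  occ <- which(M > 0)
  X <- grid_points(h)[occ, , drop = FALSE]
  U <- vapply(h$biases, function(b) bias_energy(b, X),
              numeric(length(occ)))          # occ-bins x windows
  B <- exp(-U / kT)
  N <- h$N
  Mo <- M[occ]
  f <- numeric(length(h$biases))
  residual <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- B %*% (N * exp(f / kT))
    p <- Mo / denom
    zi <- crossprod(B, p)                    # sum_j p_j exp(-U_ij/kT)
    f_new <- -kT * log(as.numeric(zi))
    f_new <- f_new - f_new[1]
    residual <- max(abs(f_new - f))
    f <- f_new
    if (residual < tol) break
    if (iter >= max_iter)
      stop(sprintf(
        "WHAM did not converge in %d iterations (last residual %.3g kcal/mol)",
        max_iter, residual))
  }
  p <- as.numeric(Mo / (B %*% (N * exp(f / kT))))
  Fv <- rep(NA_real_, length(M))
  Fv[occ] <- -kT * log(p)
  mask <- M >= min_counts & M > 0
  Fv[!mask] <- NA_real_
  g <- pmf_grid(h, Fv, mask, M, f = f, iterations = iter,
                residual = residual)
  align_pmf(g, "min-zero")
}

window_components <- function(h) {
  nw <- ncol(h$counts)
  parent <- seq_len(nw)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  occ <- h$counts > 0
  multi <- which(rowSums(occ) > 1)
  for (j in multi) {
    ws <- which(occ[j, ])
    r <- find(ws[1])
    for (w in ws[-1]) {
      rw <- find(w)
      if (rw != r) parent[rw] <- r
    }
  }
  comp <- vapply(seq_len(nw), find, integer(1))
  unname(split(seq_len(nw), comp))
}

pmf_grid <- function(h, values, mask, counts_total, f = NULL,
                     iterations = NA_integer_, residual = NA_real_,
                     zero = "min-zero") {
  if (h$dim == 2L) {
    values <- matrix(values, nrow = h$nb[1], ncol = h$nb[2], byrow = TRUE)
    mask <- matrix(mask, nrow = h$nb[1], ncol = h$nb[2], byrow = TRUE)
    counts_total <- matrix(counts_total, nrow = h$nb[1], ncol = h$nb[2],
                           byrow = TRUE)
  }
  structure(list(dim = h$dim, centers = h$centers, bin_width = h$bin_width,
                 values = values, mask = mask, counts = counts_total,
                 temperature = h$temperature, zero = zero, f = f,
                 iterations = iterations, residual = residual),
            class = "pmf_grid")
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat(sprintf(
    "PMF grid (%dD): %s bins of %s A, %d masked-in, zero convention '%s', T = %g K\n",
    x$dim, paste(vapply(x$centers, length, integer(1)), collapse = " x "),
    paste(signif(x$bin_width, 3), collapse = " x "), sum(x$mask), x$zero,
    x$temperature))
  if (!is.na(x$iterations))
    cat(sprintf("  WHAM: %d iterations, final residual %.3g kcal/mol\n",
                x$iterations, x$residual))
  invisible(x)
}

#' Shift a PMF to a zero convention
#'
#' @param p A \code{pmf_grid}.
#' @param convention "min-zero" (minimum over masked bins becomes 0) or
#'   "anchor" (the given bin becomes 0).
#' @param anchor Bin index (scalar in 1D, c(i, j) in 2D) for "anchor".
#' @return The shifted \code{pmf_grid}.
#' @export
align_pmf <- function(p, convention = c("min-zero", "anchor"),
                      anchor = NULL) {
  stopifnot(inherits(p, "pmf_grid"))
  convention <- match.arg(convention)
  if (!any(p$mask)) stop("PMF has no masked-in bins")
  if (convention == "min-zero") {
    shift <- min(p$values[p$mask], na.rm = TRUE)
  } else {
    if (is.null(anchor)) stop("anchor bin required for convention 'anchor'")
    val <- if (p$dim == 1L) p$values[anchor] else p$values[anchor[1], anchor[2]]
    ok <- if (p$dim == 1L) p$mask[anchor] else p$mask[anchor[1], anchor[2]]
    if (!isTRUE(ok)) stop("anchor bin is not masked-in")
    shift <- val
  }
  p$values <- p$values - shift
  p$zero <- convention
  p
}

#' Bin index of the grid bin nearest a coordinate
#'
#' @param p A \code{pmf_grid}.
#' @param x Coordinate (scalar in 1D, length-2 in 2D), A.
#' @return Bin index (scalar or c(i, j)).
#' @export
pmf_bin_at <- function(p, x) {
  stopifnot(inherits(p, "pmf_grid"))
  x <- as.numeric(x)
  stopifnot(length(x) == p$dim)
  vapply(seq_len(p$dim), function(k)
    which.min(abs(p$centers[[k]] - x[k])), integer(1))
}

#' Free-energy difference between two bins
#'
#' F(A) - F(B); independent of the zero convention.  Both bins must be
#' masked-in.
#'
#' @param p A \code{pmf_grid}.
#' @param binA,binB Bin indices (scalar in 1D, c(i, j) in 2D).
#' @return Difference in kcal/mol.
#' @export
pmf_difference <- function(p, binA, binB) {
  stopifnot(inherits(p, "pmf_grid"))
  get <- function(b) {
    ok <- if (p$dim == 1L) p$mask[b] else p$mask[b[1], b[2]]
    if (!isTRUE(ok)) stop("bin (", paste(b, collapse = ","),
                          ") is not masked-in")
    if (p$dim == 1L) p$values[b] else p$values[b[1], b[2]]
  }
  get(binA) - get(binB)
}
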