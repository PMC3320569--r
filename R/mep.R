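path_arc_length <- function(nodes) {
  seg <- sqrt(rowSums((nodes[-1, , drop = FALSE] -
                         nodes[-nrow(nodes), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

# place n points at equal arc length along the polyline; repeated until the
# spacing measured on the new polyline is uniform to high relative accuracy
reparametrize_path <- function(nodes, n = nrow(nodes), rel_tol = 1e-9,
                               max_pass = 25L) {
  for (pass in seq_len(max_pass)) {
    arc <- path_arc_length(nodes)
    total <- arc[length(arc)]
    if (total == 0) return(nodes[rep(1L, n), , drop = FALSE])
    target <- seq(0, total, length.out = n)
    nodes <- cbind(stats::approx(arc, nodes[, 1], xout = target)$y,
                   stats::approx(arc, nodes[, 2], xout = target)$y)
    gaps <- diff(path_arc_length(nodes))
    if (max(abs(gaps - mean(gaps))) <= rel_tol * mean(gaps)) break
  }
  nodes
}

# gradient descent to the nearest local minimum of the interpolated surface,
# with step halving when a proposal leaves the masked region
descend_to_minimum <- function(s, x, step_frac = 0.2, max_iter = 2000L) {
  h <- min(s$bin_width)
  fx <- s$value(x)
  for (i in seq_len(max_iter)) {
    g <- s$grad(x)
    gn <- sqrt(sum(g^2))
    if (gn < 1e-9) break
    eta <- step_frac * h / gn
    accepted <- FALSE
    while (eta * gn > 1e-11) {         # backtracking on the value
      xn <- as.numeric(x - eta * g)
      if (s$is_inside(xn)) {
        fn <- s$value(xn)
        if (fn < fx) { x <- xn; fx <- fn; accepted <- TRUE; break }
      }
      eta <- eta / 2
    }
    if (!accepted) break
  }
  as.numeric(x)
}

#' Minimum energy path on a 2D free-energy surface by the string method
#'
#' Simplified string iteration: the discretized path (default 200 equally
#' spaced points) first connects the two basin minima nearest the requested
#' endpoints (endpoints relaxed by gradient descent, then clamped); each
#' iteration moves every interior node against the free-energy gradient
#' with an adaptive step (largest node displacement at most 0.2 bin widths)
#' and reparametrizes the string to equal arc length.  Iteration stops when
#' the root mean square displacement between two successive iterations
#' falls below \code{tol} (default 1e-3 A).
#'
#' @param s An \code{interp_surface} (see \code{\link{interpolate_surface}}),
#'   or an \code{analytic_surface} (used directly with its exact gradient).
#' @param start,end Path endpoints (d1, d2), A; must lie in one connected
#'   masked component.
#' @param n_points Number of path nodes.
#' @param tol Convergence threshold on RMS node displacement, A.
#' @param max_iter Iteration cap.
#' @param relax_endpoints Relax endpoints to the nearest local minima before
#'   clamping (default TRUE).
#' @return A \code{minimum_energy_path}: \code{nodes} (n x 2), \code{arc}
#'   (cumulative arc length, A), \code{F} (kcal/mol at nodes),
#'   \code{iterations}, \code{rms} (final RMS displacement, A),
#'   \code{converged}.
#' @export
string_mep <- function(s, start, end, n_points = 200, tol = 1e-3,
                       max_iter = 10000, relax_endpoints = TRUE) {
  s <- as_interp_like(s)
  start <- as.numeric(start); end <- as.numeric(end)
  stopifnot(length(start) == 2, length(end) == 2, n_points >= 3)
  if (!s$is_inside(start)) stop("start point is outside the masked region")
  if (!s$is_inside(end)) stop("end point is outside the masked region")
  check_same_component(s, start, end)
  if (relax_endpoints) {
    start <- descend_to_minimum(s, start)
    end <- descend_to_minimum(s, end)
  }
  nodes <- cbind(seq(start[1], end[1], length.out = n_points),
                 seq(start[2], end[2], length.out = n_points))
  h <- min(s$bin_width)
  rms <- Inf
  iter <- 0L
  interior <- 2:(n_points - 1)
  while (iter < max_iter) {
    iter <- iter + 1L
    G <- s$grad(nodes[interior, , drop = FALSE])
    gmax <- max(sqrt(rowSums(G^2)), 1e-12)
    eta <- 0.2 * h / gmax
    prop <- nodes
    repeat {
      prop[interior, ] <- nodes[interior, ] - eta * G
      ok <- tryCatch(all(s$is_inside(prop[interior, , drop = FALSE])),
                     error = function(e) FALSE)
      if (ok) break
      eta <- eta / 2
      if (eta * gmax < 1e-12) {
        bad <- which(!s$is_inside(prop[interior, , drop = FALSE]))[1]
        stop("string node ", interior[bad],
             " cannot move without exiting the masked region")
      }
    }
    new_nodes <- reparametrize_path(prop)
    rms <- sqrt(mean(rowSums((new_nodes - nodes)^2)))
    nodes <- new_nodes
    if (rms < tol) break
  }
  if (rms >= tol)
    warning(sprintf(
      "string method did not converge in %d iterations (RMS %.3g A)",
      max_iter, rms))
  structure(list(nodes = nodes, arc = path_arc_length(nodes),
                 F = s$value(nodes), iterations = iter, rms = rms,
                 tol = tol, converged = rms < tol),
            class = "minimum_energy_path")
}

as_interp_like <- function(s) {
  if (inherits(s, "interp_surface")) return(s)
  if (inherits(s, "analytic_surface")) {
    stopifnot(s$dim == 2L)
    lo <- s$bounds[, 1]; up <- s$bounds[, 2]
    return(structure(list(
      centers = list(seq(lo[1], up[1], length.out = 2),
                     seq(lo[2], up[2], length.out = 2)),
      bin_width = c(0.25, 0.25), mask = matrix(TRUE, 1, 1),
      scheme = "analytic",
      value = s$value, grad = s$grad,
      is_inside = function(x) {
        X <- as_point_matrix(x, 2L)
        X[, 1] >= lo[1] & X[, 1] <= up[1] & X[, 2] >= lo[2] & X[, 2] <= up[2]
      }), class = "interp_surface"))
  }
  if (inherits(s, "pmf_grid")) return(interpolate_surface(s))
  stop("cannot interpret surface object")
}

check_same_component <- function(s, start, end) {
  if (s$scheme == "analytic") return(invisible(TRUE))
  bin_of <- function(x) c(which.min(abs(s$centers[[1]] - x[1])),
                          which.min(abs(s$centers[[2]] - x[2])))
  comp <- mask_component(s$mask, bin_of(start))
  e <- bin_of(end)
  if (!comp[e[1], e[2]])
    stop("start and end points lie in disconnected masked components")
  invisible(TRUE)
}

#' @export
print.minimum_energy_path <- function(x, ...) {
  cat(sprintf(
    "Minimum energy path: %d nodes, length %.3g A, %d iterations, final RMS displacement %.3g A (%s)\n",
    nrow(x$nodes), max(x$arc), x$iterations, x$rms,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Free-energy profile along a path
#'
#' @param s Surface (\code{interp_surface}, \code{pmf_grid} or
#'   \code{analytic_surface}).
#' @param path A \code{minimum_energy_path} or an n x 2 matrix of nodes.
#' @return Data frame with columns \code{index}, \code{d1}, \code{d2},
#'   \code{arc} (cumulative arc length, A) and \code{F} (kcal/mol).
#' @export
profile_along_path <- function(s, path) {
  s <- as_interp_like(s)
  nodes <- if (inherits(path, "minimum_energy_path")) path$nodes
           else as_point_matrix(path, 2L)
  data.frame(index = seq_len(nrow(nodes)), d1 = nodes[, 1], d2 = nodes[, 2],
             arc = path_arc_length(nodes), F = s$value(nodes))
}

find_profile_minima <- function(F, prominence) {
  n <- length(F)
  cand <- integer(0)
  if (n >= 2 && F[1] < F[2]) cand <- c(cand, 1L)
  if (n >= 3)
    cand <- c(cand, 1L + which(F[2:(n - 1)] < F[1:(n - 2)] &
                                 F[2:(n - 1)] <= F[3:n]))
  if (n >= 2 && F[n] < F[n - 1]) cand <- c(cand, n)
  cand <- sort(unique(cand))
  # merge minima separated by excursions smaller than the prominence
  repeat {
    if (length(cand) < 2) break
    merged <- FALSE
    for (k in seq_len(length(cand) - 1)) {
      a <- cand[k]; b <- cand[k + 1]
      sep <- max(F[a:b])
      if (sep - max(F[a], F[b]) < prominence) {
        drop <- if (F[a] <= F[b]) k + 1 else k
        cand <- cand[-drop]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  cand
}

#' Locate minima and barriers along a free-energy profile
#'
#' Local minima are nodes lower than both neighbors (profile ends count if
#' lower than their single neighbor), merged when the excursion separating
#' two minima is smaller than \code{prominence}.  For each adjacent pair
#' (A before B): forward barrier = max F between them - F(A), backward
#' barrier = same max - F(B), and the free-energy difference is computed as
#' forward - backward so the identity holds exactly.
#'
#' @param profile Output of \code{\link{profile_along_path}} (or a numeric
#'   free-energy series).
#' @param prominence Minimum excursion for a feature to count, kcal/mol.
#' @return A \code{barrier_report}: data frames \code{minima} (index,
#'   d1, d2, F) and \code{pairs} (from, to, forward, backward, dG,
#'   barrier_index).
#' @export
find_minima_and_barriers <- function(profile, prominence = 0.25) {
  if (is.numeric(profile))
    profile <- data.frame(index = seq_along(profile), d1 = NA_real_,
                          d2 = NA_real_, arc = NA_real_, F = profile)
  F <- profile$F
  stopifnot(length(F) >= 3)
  idx <- find_profile_minima(F, prominence)
  minima <- profile[idx, c("index", "d1", "d2", "F")]
  rownames(minima) <- NULL
  pairs <- NULL
  if (length(idx) >= 2) {
    pairs <- do.call(rbind, lapply(seq_len(length(idx) - 1), function(k) {
      a <- idx[k]; b <- idx[k + 1]
      seg <- a:b
      mi <- seg[which.max(F[seg])]
      fwd <- F[mi] - F[a]
      bwd <- F[mi] - F[b]
      data.frame(from = a, to = b, forward = fwd, backward = bwd,
                 dG = fwd - bwd, barrier_index = mi)
    }))
  } else {
    pairs <- data.frame(from = integer(0), to = integer(0),
                        forward = numeric(0), backward = numeric(0),
                        dG = numeric(0), barrier_index = integer(0))
  }
  structure(list(minima = minima, pairs = pairs, prominence = prominence),
            class = "barrier_report")
}

#' @export
print.barrier_report <- function(x, ...) {
  cat("Barrier report:", nrow(x$minima), "minima,", nrow(x$pairs),
      "adjacent pair(s)\n")
  if (nrow(x$minima)) {
    cat("  minima (kcal/mol):\n")
    print(x$minima, row.names = FALSE)
  }
  if (nrow(x$pairs)) {
    cat("  barriers (kcal/mol): forward / backward / dG\n")
    print(x$pairs, row.names = FALSE)
  }
  invisible(x)
}
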