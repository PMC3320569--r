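#' Harmonic bias potential
#'
#' The restraint applied to the reaction coordinate(s) in one umbrella
#' window, \eqn{U(x) = \frac{1}{2} k \sum_i (x_i - c_i)^2}, with the same
#' force constant on every component.  The protocol default is
#' k = 10 kcal/mol/A^2.
#'
#' @param center Bias center, 1 or 2 components, A.
#' @param k Force constant, kcal/mol/A^2 (> 0).
#' @return A \code{bias_potential}.
#' @export
bias_potential <- function(center, k = 10) {
  center <- as.numeric(center)
  # k = 0 is admitted so an unbiased window can enter the WHAM equations
  stopifnot(length(center) %in% c(1L, 2L), k >= 0, all(is.finite(center)))
  structure(list(center = center, k = k, dim = length(center)),
            class = "bias_potential")
}

#' Bias energy at a position
#'
#' @param bias A \code{bias_potential}.
#' @param x A position (vector) or matrix of positions (one per row), A.
#' @return Energy 0.5 * k * sum((x - c)^2), kcal/mol (vectorized over rows).
#' @export
bias_energy <- function(bias, x) {
  stopifnot(inherits(bias, "bias_potential"))
  X <- as_point_matrix(x, bias$dim)
  dx <- sweep(X, 2, bias$center)
  0.5 * bias$k * rowSums(dx * dx)
}

#' Build a 1D ladder of umbrella windows
#'
#' Bias centers form the arithmetic sequence start, start + spacing, ...
#' up to the largest value not exceeding the end of the range, i.e.
#' floor((end - start)/spacing) + 1 windows.  The protocol moves centers in
#' 1.0 A steps with k = 10 kcal/mol/A^2.
#'
#' @param range_start,range_end Extent of the ladder, A.
#' @param spacing Center spacing, A.
#' @param k Force constant, kcal/mol/A^2.
#' @return Ordered list of \code{bias_potential}.
#' @export
build_windows_1d <- function(range_start, range_end, spacing = 1, k = 10) {
  stopifnot(range_end >= range_start, spacing > 0)
  n <- floor((range_end - range_start) / spacing + 1e-9) + 1L
  lapply(range_start + (seq_len(n) - 1L) * spacing,
         function(c1) bias_potential(c1, k))
}

#' Build a 2D grid of umbrella windows
#'
#' Cartesian grid of bias centers at the given spacing over the two
#' coordinate ranges, in deterministic d1-major order, optionally filtered
#' by a region predicate.
#'
#' @param d1_range,d2_range Length-2 ranges c(start, end), A.
#' @param spacing Center spacing in both coordinates, A.
#' @param k Force constant, kcal/mol/A^2.
#' @param mask Optional predicate \code{function(d1, d2)} returning TRUE for
#'   centers to keep.
#' @return List of \code{bias_potential} (d1-major order).
#' @export
build_windows_2d <- function(d1_range, d2_range, spacing = 1, k = 10,
                             mask = NULL) {
  stopifnot(length(d1_range) == 2, length(d2_range) == 2, spacing > 0)
  c1 <- vapply(build_windows_1d(d1_range[1], d1_range[2], spacing, k),
               function(b) b$center, numeric(1))
  c2 <- vapply(build_windows_1d(d2_range[1], d2_range[2], spacing, k),
               function(b) b$center, numeric(1))
  out <- list()
  for (a in c1) for (b in c2) {
    if (is.null(mask) || isTRUE(mask(a, b)))
      out[[length(out) + 1L]] <- bias_potential(c(a, b), k)
  }
  if (length(out) == 0L) stop("mask removed every window center")
  out
}

#' Umbrella window: a bias plus the sample series collected under it
#'
#' @param bias A \code{bias_potential}.
#' @param samples Numeric matrix (samples x dimensionality) of reaction
#'   coordinates, A; a vector is accepted for 1D.
#' @param times Sample times, ps (fixed stride).
#' @param temperature Temperature of the sampling, K.
#' @param equilibration Duration already discarded from the front, ps.
#' @param label Optional window label.
#' @return An \code{umbrella_window}; \code{$stride} is the sample stride and
#'   \code{$total_ps} the total simulated duration including any discarded
#'   equilibration period.
#' @export
umbrella_window <- function(bias, samples, times, temperature = 300,
                            equilibration = 0, label = NULL) {
  stopifnot(inherits(bias, "bias_potential"))
  samples <- as_point_matrix(samples, bias$dim)
  times <- as.numeric(times)
  stopifnot(nrow(samples) == length(times), nrow(samples) >= 1)
  stride <- if (length(times) > 1) times[2] - times[1] else 1
  if (length(times) > 2 &&
      max(abs(diff(times) - stride)) > 1e-6 * max(stride, 1))
    stop("sample times must be on a fixed stride")
  structure(list(bias = bias, samples = samples, times = times,
                 stride = stride, temperature = temperature,
                 equilibration = equilibration,
                 total_ps = equilibration + nrow(samples) * stride,
                 label = if (is.null(label)) "" else label),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf(
    "Umbrella window %s: center (%s) A, k = %g kcal/mol/A^2, %d samples, stride %g ps, %g ps total (%g ps equilibration discarded)\n",
    x$label, paste(signif(x$bias$center, 6), collapse = ", "), x$bias$k,
    nrow(x$samples), x$stride, x$total_ps, x$equilibration))
  invisible(x)
}

#' Discard the equilibration period of a window
#'
#' Removes samples with time < \code{t_equil} (protocol default: the first
#' 50 ps of each 0.5 ns window).  Idempotent for the same \code{t_equil}.
#'
#' @param window An \code{umbrella_window}.
#' @param t_equil Equilibration duration, ps.
#' @return The trimmed \code{umbrella_window}.
#' @export
discard_equilibration <- function(window, t_equil = 50) {
  stopifnot(inherits(window, "umbrella_window"), t_equil >= 0)
  if (t_equil >= window$total_ps)
    stop("equilibration period (", t_equil, " ps) is not shorter than the ",
         "window duration (", window$total_ps, " ps)")
  keep <- window$times >= t_equil
  if (!any(keep)) stop("no samples left after discarding equilibration")
  umbrella_window(window$bias, window$samples[keep, , drop = FALSE],
                  window$times[keep], temperature = window$temperature,
                  equilibration = max(window$equilibration, t_equil),
                  label = window$label)
}

#' Reaction-coordinate definition
#'
#' The axial (z) distance between a tagged ion and the center of a ring of
#' backbone carbonyl oxygens.  The inner ion is referenced to the Thr175
#' ring (d1) and the outer ion to the Leu176 ring (d2); positive values are
#' extracellular to the ring.
#'
#' @param ion_id Identifier of the ion atom in the frame.
#' @param ref_residue Residue tag of the reference carbonyl ring,
#'   e.g. "THR175".
#' @return An \code{rc_def}.
#' @export
rc_def <- function(ion_id, ref_residue) {
  structure(list(ion_id = as.character(ion_id),
                 ref_residue = as.character(ref_residue)),
            class = "rc_def")
}

#' Evaluate reaction coordinates on a snapshot
#'
#' Each coordinate is the ion's z minus the mean z of the backbone carbonyl
#' oxygens of the reference residue; multiple definitions are evaluated
#' independently (e.g. bottom ion vs Thr175, top ion vs Leu176).
#'
#' @param frame An \code{ion_frame}.
#' @param defs A single \code{rc_def} or a list of them.
#' @return Named numeric vector (d1[, d2, ...]).
#' @export
compute_reaction_coordinates <- function(frame, defs) {
  stopifnot(inherits(frame, "ion_frame"))
  if (inherits(defs, "rc_def")) defs <- list(defs)
  out <- vapply(defs, function(def) {
    ion <- frame[frame$id == def$ion_id & frame$role == "ion", , drop = FALSE]
    if (nrow(ion) != 1L) stop("ion '", def$ion_id, "' not found in frame")
    ring <- frame[frame$role == "backbone-O" &
                    frame$residue == def$ref_residue, , drop = FALSE]
    if (nrow(ring) < 1L)
      stop("reference ring '", def$ref_residue, "' resolves to no atoms")
    ion$z - mean(ring$z)
  }, numeric(1))
  names(out) <- paste0("d", seq_along(out))
  out
}
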