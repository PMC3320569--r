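ion_cutoffs <- c(Na = 2.8, K = 3.2)

#' Source-partitioned coordination shell of an ion
#'
#' Counts oxygen atoms strictly closer than the species cutoff (2.8 A for
#' Na+, 3.2 A for K+, per "closer than") to the ion, partitioned by source:
#' water, protein backbone carbonyls, and side-chain oxygens per residue
#' (e.g. Glu177, Ser178).
#'
#' @param frame An \code{ion_frame}.
#' @param ion_id Identifier of the ion.
#' @param cutoff Optional cutoff override, A.
#' @return A \code{coordination_profile}: \code{total}, \code{water},
#'   \code{backbone}, \code{sidechain} (named by residue; possibly empty),
#'   \code{cutoff}, \code{species}, \code{ion_id}.
#' @export
coordination_shell <- function(frame, ion_id, cutoff = NULL) {
  stopifnot(inherits(frame, "ion_frame"))
  ion <- frame[frame$id == ion_id & frame$role == "ion", , drop = FALSE]
  if (nrow(ion) != 1L) stop("ion '", ion_id, "' not found in frame")
  if (is.null(cutoff)) {
    if (!ion$species %in% names(ion_cutoffs))
      stop("no coordination cutoff defined for species '", ion$species, "'")
    cutoff <- ion_cutoffs[[ion$species]]
  }
  ox <- frame[frame$role %in% c("water-O", "backbone-O", "sidechain-O"), ,
              drop = FALSE]
  d <- sqrt((ox$x - ion$x)^2 + (ox$y - ion$y)^2 + (ox$z - ion$z)^2)
  shell <- ox[d < cutoff, , drop = FALSE]          # strict inequality
  sidechain <- table(shell$residue[shell$role == "sidechain-O"])
  sidechain <- stats::setNames(as.integer(sidechain), names(sidechain))
  out <- list(total = nrow(shell),
              water = sum(shell$role == "water-O"),
              backbone = sum(shell$role == "backbone-O"),
              sidechain = sidechain,
              cutoff = cutoff, species = ion$species, ion_id = ion_id)
  class(out) <- "coordination_profile"
  out
}

#' @export
print.coordination_profile <- function(x, ...) {
  sc <- if (length(x$sidechain))
    paste(sprintf("%s %d", names(x$sidechain), x$sidechain), collapse = ", ")
  else "none"
  cat(sprintf(
    "Coordination of %s (%s+, cutoff %.1f A): total %d = water %d + backbone %d + sidechain (%s)\n",
    x$ion_id, x$species, x$cutoff, x$total, x$water, x$backbone, sc))
  invisible(x)
}

#' Axial band specification
#'
#' Ordered, contiguous, non-overlapping intervals along the pore axis, each
#' bounded by two landmarks; a landmark is the mean z of a residue's
#' backbone or side-chain oxygens plus an optional offset in A.  The
#' default reproduces the four bands used for the off-axis displacement
#' analysis: (A) Thr175 carbonyls to Leu176 carbonyls, (B) Leu176 carbonyls
#' to 3 A above, (C) from there to 1 A below the Glu177 side-chain oxygens,
#' (D) 1 A below to 1 A above the Glu177 side-chain oxygens.
#'
#' @param bands Named list; each element is
#'   \code{list(lower = landmark, upper = landmark)} with a landmark being
#'   \code{list(residue =, role =, offset =)}.
#' @return An \code{axial_band_spec}.
#' @export
axial_band_spec <- function(bands) {
  stopifnot(is.list(bands), length(bands) >= 1, !is.null(names(bands)))
  structure(list(bands = bands), class = "axial_band_spec")
}

landmark <- function(residue, role = "backbone-O", offset = 0)
  list(residue = residue, role = role, offset = offset)

#' @rdname axial_band_spec
#' @export
default_band_spec <- function() {
  axial_band_spec(list(
    A = list(lower = landmark("THR175"), upper = landmark("LEU176")),
    B = list(lower = landmark("LEU176"),
             upper = landmark("LEU176", offset = 3)),
    C = list(lower = landmark("LEU176", offset = 3),
             upper = landmark("GLU177", "sidechain-O", offset = -1)),
    D = list(lower = landmark("GLU177", "sidechain-O", offset = -1),
             upper = landmark("GLU177", "sidechain-O", offset = 1))))
}

resolve_landmark <- function(frame, lm) {
  sel <- frame$role == lm$role & frame$residue == lm$residue
  sel[is.na(sel)] <- FALSE
  if (!any(sel))
    stop("band landmark ", lm$residue, "/", lm$role,
         " resolves to no atoms in the frame")
  mean(frame$z[sel]) + lm$offset
}

#' Resolve band boundaries on a frame
#'
#' @param frame An \code{ion_frame}.
#' @param spec An \code{axial_band_spec}.
#' @return Data frame with columns \code{band}, \code{lower}, \code{upper}
#'   (A); errors if the resolved bands are not contiguous and ordered.
#' @export
resolve_bands <- function(frame, spec = default_band_spec()) {
  stopifnot(inherits(spec, "axial_band_spec"))
  rows <- lapply(names(spec$bands), function(nm) {
    b <- spec$bands[[nm]]
    data.frame(band = nm, lower = resolve_landmark(frame, b$lower),
               upper = resolve_landmark(frame, b$upper))
  })
  out <- do.call(rbind, rows)
  if (any(out$upper <= out$lower))
    stop("band(s) with non-positive extent: ",
         paste(out$band[out$upper <= out$lower], collapse = ", "))
  if (nrow(out) > 1 &&
      max(abs(out$lower[-1] - out$upper[-nrow(out)])) > 1e-9)
    stop("bands are not contiguous")
  out
}

#' Off-axis displacement of an ion, with axial band label
#'
#' Radial distance of the ion from the pore axis in the x-y plane, and the
#' axial band its z falls into (half-open [lower, upper), the last band
#' closed above; "outside" if in none).  The default pore axis is the z
#' line through the centroid of all backbone carbonyl oxygens.
#'
#' @param frame An \code{ion_frame}.
#' @param ion_id Ion identifier.
#' @param axis Axis reference point c(x0, y0); default the backbone-O
#'   centroid.
#' @param bands An \code{axial_band_spec} (or NULL to skip banding).
#' @return List with \code{r} (A), \code{band} (label or "outside") and
#'   \code{axis}.
#' @export
xy_displacement <- function(frame, ion_id, axis = NULL,
                            bands = default_band_spec()) {
  stopifnot(inherits(frame, "ion_frame"))
  ion <- frame[frame$id == ion_id & frame$role == "ion", , drop = FALSE]
  if (nrow(ion) != 1L) stop("ion '", ion_id, "' not found in frame")
  if (is.null(axis)) {
    bb <- frame$role == "backbone-O"
    if (!any(bb)) stop("no backbone carbonyl oxygens to define the pore axis")
    axis <- c(mean(frame$x[bb]), mean(frame$y[bb]))
  }
  r <- sqrt((ion$x - axis[1])^2 + (ion$y - axis[2])^2)
  band <- NA_character_
  if (!is.null(bands)) {
    tb <- resolve_bands(frame, bands)
    inb <- ion$z >= tb$lower & (ion$z < tb$upper |
                                  (seq_len(nrow(tb)) == nrow(tb) &
                                     ion$z <= tb$upper))
    band <- if (any(inb)) tb$band[which(inb)[1]] else "outside"
  }
  list(r = r, band = band, axis = axis)
}

#' Count water molecules in a cavity region
#'
#' Number of water oxygens with z inside the axial slab and radial distance
#' from the pore axis strictly below the cutoff.  The default region is the
#' slab from 8 A below the Thr175 carbonyl ring up to the ring, with a 6 A
#' radial cutoff (the equilibrium cavity occupancy of the channel is about
#' 45 waters on this definition).
#'
#' @param frame An \code{ion_frame}.
#' @param zlim Slab c(lower, upper), A; default derived from the Thr175
#'   ring.
#' @param radial_cutoff Radial cutoff, A.
#' @param axis Axis reference c(x0, y0); default the backbone-O centroid.
#' @return Integer count.
#' @export
cavity_water_count <- function(frame, zlim = NULL, radial_cutoff = 6,
                               axis = NULL) {
  stopifnot(inherits(frame, "ion_frame"), radial_cutoff > 0)
  if (nrow(frame) == 0L) return(0L)
  if (is.null(axis)) {
    bb <- frame$role == "backbone-O"
    axis <- if (any(bb)) c(mean(frame$x[bb]), mean(frame$y[bb])) else c(0, 0)
  }
  if (is.null(zlim)) {
    ring <- frame$role == "backbone-O" & frame$residue == "THR175"
    ring[is.na(ring)] <- FALSE
    if (!any(ring)) stop("no Thr175 ring to derive the default cavity slab")
    top <- mean(frame$z[ring])
    zlim <- c(top - 8, top)
  }
  w <- frame$role == "water-O"
  r <- sqrt((frame$x - axis[1])^2 + (frame$y - axis[2])^2)
  sum(w & frame$z >= zlim[1] & frame$z <= zlim[2] & r < radial_cutoff)
}

#' Subsample a frame series at a fixed stride
#'
#' Picks the frame nearest each target time t_start, t_start + stride, ...
#' (within half the native frame spacing), the snapshot convention of
#' one frame every 20 ps after the equilibration period.
#'
#' @param trajectory List of \code{ion_frame} with increasing times.
#' @param stride Target stride, ps.
#' @param t_start First target time, ps.
#' @return List of selected frames.
#' @export
subsample_frames <- function(trajectory, stride = 20, t_start = 50) {
  stopifnot(stride > 0, length(trajectory) >= 1)
  times <- vapply(trajectory, frame_time, numeric(1))
  if (t_start > max(times))
    stop("t_start (", t_start, " ps) is beyond the last frame (",
         max(times), " ps)")
  native <- if (length(times) > 1) stats::median(diff(times)) else stride
  targets <- seq(t_start, max(times), by = stride)
  picks <- integer(0)
  for (tt in targets) {
    k <- which.min(abs(times - tt))
    if (abs(times[k] - tt) <= native / 2) picks <- c(picks, k)
  }
  picks <- unique(picks)
  if (length(picks) == 0L) stop("no frames matched the requested stride")
  trajectory[picks]
}
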