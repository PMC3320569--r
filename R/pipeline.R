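#' Resolved pipeline configuration
#'
#' All defaults equal the umbrella-sampling protocol of the analysis:
#' 300 K, harmonic force constant 10 kcal/mol/A^2, bias centers moved in
#' 1.0 A steps, 0.5 ns per window with the first 50 ps discarded as
#' equilibration, WHAM bins of 0.1 A (1D) / 0.25 A (2D), a 200-node string
#' with a 1e-3 A RMS-displacement stop, error bars from 3 consecutive
#' blocks of 150 ps, coordination cutoffs 2.8 A (Na+) / 3.2 A (K+) and a
#' 20 ps snapshot stride.  The synthetic double-well / two-basin study
#' landscapes and window layouts (20 windows on [-5, 14] A in 1D; the
#' 18 x 15 = 270-window grid on [0, 17] x [0, 14] A in 2D) are part of the
#' configuration so every run records them.
#'
#' @param ... Overrides of the default entries (named as in the returned
#'   list, e.g. \code{seed = 7}, \code{wham.tol = 1e-8}).
#' @return Named list of resolved settings.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    temperature = 300,            # K
    force_constant = 10,          # kcal/mol/A^2
    window_spacing = 1.0,         # A
    window_duration = 500,        # ps
    equilibration = 50,           # ps
    sample_stride = 1,            # ps
    diffusion = 0.1,              # A^2/ps
    dt = 0.01,                    # ps
    seed = 2012,
    # synthetic study landscapes
    range_1d = c(-5, 14),
    wells_1d = c(0, 6),
    barrier_1d = 3.0,             # kcal/mol
    asymmetry_1d = 1.0,           # kcal/mol
    width_1d = 1.2,               # A
    bounds_1d = c(-7, 16),
    d1_range = c(0, 17),
    d2_range = c(0, 14),
    minimaA = c(4, 4),
    minimaB = c(12, 10),
    barrier_2d = 3.5,             # kcal/mol
    asymmetry_2d = 1.2,           # kcal/mol
    valley_width = 1.5,           # A
    bounds_2d = rbind(c(-2, 19), c(-2, 16)),
    bg_k = 0.05,                  # kcal/mol/A^2
    # analysis settings
    wham.bin_width_1d = 0.1,      # A
    wham.bin_width_2d = 0.25,     # A
    wham.tol = 1e-7,              # kcal/mol
    wham.max_iter = 100000,
    wham.min_counts = 1,
    string.n_points = 200,
    string.tol = 1e-3,            # A
    string.max_iter = 10000,
    string.prominence = 0.25,     # kcal/mol
    blocks.n = 3,
    cutoff_Na = 2.8,              # A
    cutoff_K = 3.2,               # A
    snapshot_stride = 20)         # ps
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

log_config <- function(cfg, stage = "config") {
  for (k in names(cfg)) {
    v <- cfg[[k]]
    log_stage(stage, "%s = %s", k,
              paste(vapply(as.numeric(v), num, character(1)),
                    collapse = ", "))
  }
}

#' Study landscape and window ladder for the 1D protocol
#'
#' @param cfg A \code{\link{pipeline_config}}.
#' @return List with \code{surface} (double well) and \code{windows}
#'   (20 biases at 1.0 A spacing by default).
#' @export
study_protocol_1d <- function(cfg = pipeline_config()) {
  list(surface = make_double_well_1d(cfg$wells_1d, cfg$barrier_1d,
                                     cfg$asymmetry_1d, cfg$width_1d,
                                     bg_k = cfg$bg_k, bounds = cfg$bounds_1d),
       windows = build_windows_1d(cfg$range_1d[1], cfg$range_1d[2],
                                  cfg$window_spacing, cfg$force_constant))
}

#' Study landscape and window grid for the 2D protocol
#'
#' @param cfg A \code{\link{pipeline_config}}.
#' @return List with \code{surface} (two-basin) and \code{windows}
#'   (18 x 15 = 270 biases by default).
#' @export
study_protocol_2d <- function(cfg = pipeline_config()) {
  list(surface = make_two_ion_surface_2d(cfg$minimaA, cfg$minimaB,
                                         cfg$barrier_2d, cfg$valley_width,
                                         cfg$asymmetry_2d, bg_k = cfg$bg_k,
                                         bounds = cfg$bounds_2d),
       windows = build_windows_2d(cfg$d1_range, cfg$d2_range,
                                  cfg$window_spacing, cfg$force_constant))
}

#' Sample every window of a protocol
#'
#' Runs the Langevin sampler over a list of biases with per-window seeds
#' derived from the base seed (seed + window index), then discards the
#' equilibration period.
#'
#' @param surface An \code{analytic_surface}.
#' @param windows List of \code{bias_potential}.
#' @param cfg A \code{\link{pipeline_config}}.
#' @param discard Discard the equilibration period (default TRUE).
#' @return List of \code{umbrella_window}.
#' @export
sample_protocol <- function(surface, windows, cfg = pipeline_config(),
                            discard = TRUE) {
  n_samples <- round(cfg$window_duration / cfg$sample_stride)
  lapply(seq_along(windows), function(i) {
    sc <- sampler_config(temperature = cfg$temperature,
                         diffusion = cfg$diffusion, dt = cfg$dt,
                         n_samples = n_samples, stride = cfg$sample_stride,
                         seed = cfg$seed + i)
    w <- sample_window(surface, windows[[i]], sc)
    if (discard) discard_equilibration(w, cfg$equilibration) else w
  })
}

#' Generate a synthetic umbrella-sampling data set on disk
#'
#' Writes one window file per bias center plus the analytic ground-truth
#' surface parameters; deterministic under the configured seed.
#'
#' @param cfg A \code{\link{pipeline_config}}.
#' @param out_dir Output directory.
#' @param dim 1 or 2 (which study protocol to generate).
#' @param force Overwrite an existing output directory.
#' @return Invisibly, the vector of written window file paths.
#' @export
cmd_generate <- function(cfg = pipeline_config(), out_dir, dim = 1,
                         force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stop("output directory ", out_dir, " exists; use force = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_config(cfg)
  proto <- if (dim == 1) study_protocol_1d(cfg) else study_protocol_2d(cfg)
  log_stage("generate", "sampling %d windows (%dD protocol, seed %d)",
            length(proto$windows), dim, cfg$seed)
  wins <- sample_protocol(proto$surface, proto$windows, cfg, discard = FALSE)
  files <- vapply(seq_along(wins), function(i) {
    f <- file.path(out_dir, sprintf("window_%03d.dat", i))
    write_window(wins[[i]], f)
    f
  }, character(1))
  write_surface(proto$surface, file.path(out_dir, "surface_truth.dat"))
  log_stage("generate", "wrote %d window files to %s", length(files),
            out_dir)
  invisible(files)
}

#' Run WHAM over window files
#'
#' Parses the window files, discards the equilibration period, histograms
#' and solves the WHAM equations, and writes the PMF file.
#'
#' @param window_files Paths of window files.
#' @param out_file PMF output path.
#' @param cfg A \code{\link{pipeline_config}}.
#' @return The \code{pmf_grid}, invisibly.
#' @export
cmd_wham <- function(window_files, out_file, cfg = pipeline_config()) {
  wins <- lapply(window_files, read_window)
  wins <- lapply(wins, function(w)
    if (w$equilibration >= cfg$equilibration) w
    else discard_equilibration(w, cfg$equilibration))
  d <- wins[[1]]$bias$dim
  bw <- if (d == 1L) cfg$wham.bin_width_1d else cfg$wham.bin_width_2d
  h <- histogram_windows(wins, bw, temperature = cfg$temperature)
  log_stage("wham", "%d windows, %s bins", length(wins),
            paste(h$nb, collapse = " x "))
  p <- solve_wham(h, tol = cfg$wham.tol, max_iter = cfg$wham.max_iter,
                  min_counts = cfg$wham.min_counts)
  log_stage("wham", "converged in %d iterations (residual %.3g kcal/mol)",
            p$iterations, p$residual)
  write_pmf(p, out_file)
  invisible(p)
}

#' Compute the minimum energy path on a 2D PMF file
#'
#' @param pmf_file PMF path (2D).
#' @param start,end Path endpoints (d1, d2), A.
#' @param out_path Path-file output location.
#' @param out_report Barrier-report output location (optional).
#' @param cfg A \code{\link{pipeline_config}}.
#' @return List with the \code{minimum_energy_path} and the
#'   \code{barrier_report}, invisibly.
#' @export
cmd_mep <- function(pmf_file, start, end, out_path, out_report = NULL,
                    cfg = pipeline_config()) {
  p <- read_pmf(pmf_file)
  if (p$dim != 2L) stop("minimum energy paths require a 2D PMF")
  s <- interpolate_surface(p)
  mep <- string_mep(s, start, end, n_points = cfg$string.n_points,
                    tol = cfg$string.tol, max_iter = cfg$string.max_iter)
  log_stage("mep", "%d iterations, final RMS %.3g A", mep$iterations,
            mep$rms)
  write_path(mep, out_path)
  prof <- profile_along_path(s, mep)
  rep_ <- find_minima_and_barriers(prof, cfg$string.prominence)
  if (!is.null(out_report)) {
    est <- lapply(seq_len(nrow(rep_$pairs)), function(k) {
      structure(list(label = sprintf("barrier_pair_%d", k),
                     full = rep_$pairs$forward[k],
                     blocks = rep(NA_real_, cfg$blocks.n),
                     mean = NA_real_, sd = NA_real_,
                     n_blocks = cfg$blocks.n, errors = character(0)),
                class = "block_estimate")
    })
    if (length(est)) write_report(est, out_report)
  }
  invisible(list(path = mep, report = rep_))
}

#' Block-error analysis over window files
#'
#' Re-runs the full WHAM reconstruction per consecutive block and writes
#' the report table for the requested free-energy differences.
#'
#' @param window_files Paths of window files.
#' @param quantities Named list; each element is c(A, B) coordinates (A) of
#'   a free-energy difference F(A) - F(B) to evaluate (scalars in 1D,
#'   length-2 vectors in 2D as list(A =, B =)).
#' @param out_file Report output path.
#' @param cfg A \code{\link{pipeline_config}}.
#' @return List of \code{block_estimate}, invisibly.
#' @export
cmd_errors <- function(window_files, quantities, out_file,
                       cfg = pipeline_config()) {
  wins <- lapply(window_files, read_window)
  wins <- lapply(wins, function(w)
    if (w$equilibration >= cfg$equilibration) w
    else discard_equilibration(w, cfg$equilibration))
  d <- wins[[1]]$bias$dim
  bw <- if (d == 1L) cfg$wham.bin_width_1d else cfg$wham.bin_width_2d
  ests <- lapply(names(quantities), function(nm) {
    q <- quantities[[nm]]
    extractor <- function(ws) {
      h <- histogram_windows(ws, bw, temperature = cfg$temperature)
      p <- solve_wham(h, tol = cfg$wham.tol, max_iter = cfg$wham.max_iter,
                      min_counts = cfg$wham.min_counts)
      pmf_difference(p, pmf_bin_at(p, q$A), pmf_bin_at(p, q$B))
    }
    est <- estimate_with_errors(wins, extractor, cfg$blocks.n, label = nm)
    log_stage("errors", "%s = %s", nm, format_pm(est$full, est$sd))
    est
  })
  write_report(ests, out_file)
  invisible(ests)
}

#' Contour levels for a free-energy map
#'
#' Isolines are drawn every \code{spacing} kcal/mol from 0 up to the masked
#' maximum, the convention of two-ion free-energy maps.
#'
#' @param p A \code{pmf_grid}.
#' @param spacing Isoline spacing, kcal/mol.
#' @return Numeric vector of levels {0, spacing, 2 spacing, ...}.
#' @export
contour_levels <- function(p, spacing = 1) {
  stopifnot(inherits(p, "pmf_grid"), spacing > 0)
  seq(0, ceiling(max(p$values[p$mask], na.rm = TRUE) / spacing) * spacing,
      by = spacing)
}

#' Plot a PMF (with optional path overlay)
#'
#' 1D: free energy versus the reaction coordinate.  2D: filled contour map
#' with isolines every 1 kcal/mol and the minimum energy path overlaid as
#' a black line.  Figures are written as PDF.
#'
#' @param pmf_file PMF path.
#' @param out_file Figure path (.pdf).
#' @param path_file Optional path file to overlay (2D only).
#' @param contour_spacing Isoline spacing, kcal/mol.
#' @return \code{out_file}, invisibly.
#' @export
cmd_plot <- function(pmf_file, out_file, path_file = NULL,
                     contour_spacing = 1) {
  p <- read_pmf(pmf_file)
  if (p$dim == 1L && !is.null(path_file))
    stop("a path overlay requires a 2D PMF")
  grDevices::pdf(out_file, width = 6, height = 5)
  on.exit(grDevices::dev.off())
  if (p$dim == 1L) {
    graphics::plot(p$centers[[1]], p$values, type = "l", lwd = 2,
                   xlab = "d1 (A)", ylab = "free energy (kcal/mol)")
  } else {
    z <- p$values
    levels <- contour_levels(p, contour_spacing)
    graphics::image(p$centers[[1]], p$centers[[2]], z,
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "d1 (A)", ylab = "d2 (A)")
    graphics::contour(p$centers[[1]], p$centers[[2]], z, levels = levels,
                      add = TRUE, col = "grey20")
    if (!is.null(path_file)) {
      mep <- read_path(path_file)
      graphics::lines(mep$nodes[, 1], mep$nodes[, 2], lwd = 2, col = "black")
    }
  }
  invisible(out_file)
}

#' Along-path free-energy profile figure
#'
#' F versus node arc length with d1/d2 annotations, the companion figure
#' to a 2D map with its minimum energy path.
#'
#' @param path_file Path file.
#' @param out_file Figure path (.pdf).
#' @return \code{out_file}, invisibly.
#' @export
cmd_plot_profile <- function(path_file, out_file) {
  mep <- read_path(path_file)
  grDevices::pdf(out_file, width = 6, height = 4)
  on.exit(grDevices::dev.off())
  graphics::plot(mep$arc, mep$F, type = "l", lwd = 2,
                 xlab = "arc length (A)", ylab = "free energy (kcal/mol)")
  ticks <- pretty(seq_len(nrow(mep$nodes)), 6)
  ticks <- ticks[ticks >= 1 & ticks <= nrow(mep$nodes)]
  graphics::axis(3, at = mep$arc[ticks],
                 labels = sprintf("(%.1f, %.1f)", mep$nodes[ticks, 1],
                                  mep$nodes[ticks, 2]), cex.axis = 0.6)
  invisible(out_file)
}

#' Coordination analysis over a frame series
#'
#' Subsamples a trajectory of role-tagged frames at the snapshot stride and
#' tabulates each ion's source-partitioned coordination counts.
#'
#' @param frames List of \code{ion_frame}.
#' @param ion_id Ion identifier.
#' @param cfg A \code{\link{pipeline_config}}.
#' @param out_file Optional TSV output path.
#' @return Data frame keyed by frame time with columns total, water,
#'   backbone, sidechain counts.
#' @export
cmd_coord <- function(frames, ion_id, cfg = pipeline_config(),
                      out_file = NULL) {
  picked <- subsample_frames(frames, cfg$snapshot_stride,
                             t_start = cfg$equilibration)
  rows <- lapply(picked, function(fr) {
    cp <- coordination_shell(fr, ion_id)
    data.frame(time = frame_time(fr), total = cp$total, water = cp$water,
               backbone = cp$backbone, sidechain = sum(cp$sidechain))
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_file))
    utils::write.table(out, out_file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  out
}
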