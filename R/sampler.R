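#' Configuration for the overdamped Langevin umbrella sampler
#'
#' Defaults emulate the umbrella-sampling protocol the analysis expects:
#' 300 K, windows of 500 samples recorded every 1 ps (0.5 ns per window, of
#' which the first 50 ps are later discarded as equilibration, leaving 450
#' retained samples).
#'
#' @param temperature Temperature in K.
#' @param diffusion Diffusion coefficient D, A^2/ps.
#' @param dt Integration time step, ps.
#' @param n_samples Recorded samples per window.
#' @param stride Time between recorded samples, ps.
#' @param seed Integer seed for R's RNG.
#' @param t0 Time of the first recorded sample, ps.
#' @param margin Allowed excursion beyond the domain before the integrator
#'   aborts (signals an unstable time step), A.
#' @return A \code{sampler_config} list; element \code{kT} holds
#'   k_B * T = 0.0019872041 * T kcal/mol (about 0.596 kcal/mol at 300 K).
#' @export
sampler_config <- function(temperature = 300, diffusion = 0.1, dt = 0.01,
                           n_samples = 500, stride = 1, seed = 2012,
                           t0 = 0, margin = 2) {
  stopifnot(temperature > 0, diffusion > 0, dt > 0, n_samples >= 1,
            stride > 0, margin > 0)
  if (stride / dt < 1 - 1e-9) stop("stride must be at least one time step")
  structure(list(temperature = temperature, diffusion = diffusion, dt = dt,
                 n_samples = as.integer(n_samples), stride = stride,
                 seed = as.integer(seed), t0 = t0, margin = margin,
                 kT = kT_kcal(temperature)),
            class = "sampler_config")
}

#' Sample one umbrella window by overdamped Langevin dynamics
#'
#' Euler--Maruyama integration of
#' \deqn{dx = -(D/kT)\,\nabla(F + U)\,dt + \sqrt{2 D dt}\,\xi}
#' on the analytic landscape F plus the harmonic bias U, with reflecting
#' walls at the domain bounds.  Positions are recorded every \code{stride}
#' ps starting from the bias center at \code{t0}.  The series is a pure
#' function of (surface, bias, config): the seed is applied with
#' \code{set.seed} before integration, so identical inputs give
#' bit-identical output.
#'
#' @param surface An \code{analytic_surface}.
#' @param bias A \code{bias_potential} of the same dimensionality with its
#'   center inside the domain.
#' @param cfg A \code{sampler_config}.
#' @return An \code{umbrella_window}.
#' @export
sample_window <- function(surface, bias, cfg = sampler_config()) {
  stopifnot(inherits(surface, "analytic_surface"),
            inherits(bias, "bias_potential"),
            inherits(cfg, "sampler_config"))
  if (bias$dim != surface$dim)
    stop("bias dimensionality (", bias$dim, ") does not match the surface (",
         surface$dim, ")")
  lo <- surface$bounds[, 1]; up <- surface$bounds[, 2]
  if (any(bias$center < lo) || any(bias$center > up))
    stop("bias center lies outside the surface domain")
  steps <- as.integer(round(cfg$stride / cfg$dt))
  p <- surface$params
  set.seed(cfg$seed)
  samples <- cpp_sample_window(
    as.numeric(bias$center), p$centers, p$depths, p$widths, p$bg_k,
    p$bg_center, p$offset, as.numeric(bias$center), bias$k, cfg$kT,
    cfg$diffusion, cfg$dt, cfg$n_samples, steps, lo, up, cfg$margin)
  umbrella_window(bias, samples,
                  times = cfg$t0 + (seq_len(cfg$n_samples) - 1L) * cfg$stride,
                  temperature = cfg$temperature,
                  label = sprintf("w_%s",
                                  paste(signif(bias$center, 6), collapse = "_")))
}
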