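#' Split windows into consecutive time blocks
#'
#' Every window's retained samples are divided into \code{n_blocks}
#' consecutive, non-overlapping slices of equal length (protocol default:
#' 3 blocks of 150 ps from 450 retained ps).  A remainder shorter than
#' \code{n_blocks} strides is dropped from the end and recorded in the
#' \code{dropped} attribute.
#'
#' @param windows List of \code{umbrella_window} (equilibration already
#'   discarded).
#' @param n_blocks Number of blocks.
#' @return List of length \code{n_blocks}; element b is the list of windows
#'   restricted to their b-th time slice.
#' @export
split_blocks <- function(windows, n_blocks = 3) {
  stopifnot(n_blocks >= 1)
  if (inherits(windows, "umbrella_window")) windows <- list(windows)
  per <- vapply(windows, function(w) nrow(w$samples), integer(1))
  if (any(per < n_blocks))
    stop("window(s) ", paste(which(per < n_blocks), collapse = ", "),
         " have fewer samples than blocks")
  dropped <- 0L
  blocks <- lapply(seq_len(n_blocks), function(b) {
    lapply(windows, function(w) {
      n <- nrow(w$samples)
      len <- n %/% n_blocks
      sel <- ((b - 1L) * len + 1L):(b * len)
      umbrella_window(w$bias, w$samples[sel, , drop = FALSE], w$times[sel],
                      temperature = w$temperature,
                      equilibration = w$equilibration, label = w$label)
    })
  })
  dropped <- sum(per %% n_blocks)
  attr(blocks, "dropped") <- dropped
  if (dropped > 0)
    message(dropped, " trailing sample(s) dropped to equalize block lengths")
  blocks
}

#' Mean and standard deviation over block values
#'
#' Arithmetic mean and the sample (n - 1 denominator) standard deviation,
#' the small-n convention used for 3-block error bars.
#'
#' @param values Per-block values (length >= 2).
#' @return List with \code{mean} and \code{sd}.
#' @export
block_statistics <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 block values")
  list(mean = mean(values), sd = stats::sd(values))
}

#' Block-repeat error estimate of a derived free-energy quantity
#'
#' Runs the supplied extractor (typically a full WHAM, or WHAM + string
#' method, pipeline ending in a free-energy difference or barrier readout)
#' once on the complete window set and once per consecutive time block,
#' and reports the full-data value as the headline estimate with the
#' standard deviation among block values as its uncertainty.
#'
#' @param windows List of \code{umbrella_window}.
#' @param extractor \code{function(windows) -> numeric(1)}.
#' @param n_blocks Number of consecutive blocks.
#' @param label Quantity label for reporting.
#' @return A \code{block_estimate}: \code{label}, \code{full} (full-data
#'   value), \code{blocks} (per-block values, NA where a block's
#'   reconstruction failed), \code{mean}, \code{sd}, \code{n_blocks},
#'   \code{errors} (per-block failure messages, if any).
#' @export
estimate_with_errors <- function(windows, extractor, n_blocks = 3,
                                 label = "quantity") {
  stopifnot(is.function(extractor))
  full <- extractor(windows)
  blocks <- split_blocks(windows, n_blocks)
  errors <- character(0)
  vals <- vapply(seq_along(blocks), function(b) {
    tryCatch(as.numeric(extractor(blocks[[b]])), error = function(e) {
      errors <<- c(errors, sprintf("block %d: %s", b, conditionMessage(e)))
      NA_real_
    })
  }, numeric(1))
  ok <- !is.na(vals)
  st <- if (sum(ok) >= 2) block_statistics(vals[ok])
        else list(mean = NA_real_, sd = NA_real_)
  structure(list(label = label, full = as.numeric(full), blocks = vals,
                 mean = st$mean, sd = st$sd, n_blocks = n_blocks,
                 errors = errors),
            class = "block_estimate")
}

#' @export
print.block_estimate <- function(x, ...) {
  cat(format_pm(x$full, x$sd), " [", x$label, "]\n", sep = "")
  cat(sprintf("  blocks (%d): %s; block mean %.4g\n", x$n_blocks,
              paste(signif(x$blocks, 4), collapse = ", "), x$mean))
  if (length(x$errors)) cat("  failures:", paste(x$errors, collapse = "; "),
                            "\n")
  invisible(x)
}

#' Render a value with its uncertainty as "x±y kcal/mol"
#'
#' @param value,sd Value and uncertainty, kcal/mol.
#' @param digits Decimal places (default 1, the convention of free-energy
#'   tables such as "4.3±0.4 kcal/mol").
#' @return Character scalar.
#' @export
format_pm <- function(value, sd, digits = 1) {
  sprintf("%.*f±%.*f kcal/mol", digits, value, digits, sd)
}

#' Parse a "x±y kcal/mol" string
#'
#' @param text Output of \code{\link{format_pm}}.
#' @return List with \code{value} and \code{sd}.
#' @export
parse_pm <- function(text) {
  m <- regmatches(text, regexec(
    "^\\s*(-?[0-9.]+)±(-?[0-9.]+)( kcal/mol)?\\s*$", text))[[1]]
  if (length(m) < 3) stop("cannot parse value±sd string: ", text)
  list(value = as.numeric(m[2]), sd = as.numeric(m[3]))
}

#' Feature-matched free-energy readouts on a 1D PMF
#'
#' Block reconstructions are noisier than the full-data surface and their
#' features drift, so quantities are read at the local feature nearest a
#' reference position located on the full-data surface: a well value is the
#' minimum over masked bins within \code{window} of the reference, and a
#' barrier is the maximum over masked bins between the two matched wells.
#'
#' @param p A 1D \code{pmf_grid}.
#' @param x0 Reference coordinate of the well, A.
#' @param window Matching half-width, A.
#' @return \code{pmf_well_value}: list with \code{value} (kcal/mol),
#'   \code{x} (matched position) and \code{bin}.
#' @export
pmf_well_value <- function(p, x0, window = 1.5) {
  stopifnot(inherits(p, "pmf_grid"), p$dim == 1L)
  cc <- p$centers[[1]]
  sel <- which(abs(cc - x0) <= window & p$mask)
  if (!length(sel)) stop(sprintf("no masked bins within %.3g A of %.3g",
                                 window, x0))
  b <- sel[which.min(p$values[sel])]
  list(value = p$values[b], x = cc[b], bin = b)
}

#' @rdname pmf_well_value
#' @param xA,xB Reference coordinates of the two wells enclosing the
#'   barrier, A.
#' @return \code{pmf_barrier_value}: list with \code{top} (maximum between
#'   the matched wells), \code{forward} (top - F(well A)), \code{backward}
#'   (top - F(well B)) and \code{dG} (forward - backward).
#' @export
pmf_barrier_value <- function(p, xA, xB, window = 1.5) {
  wa <- pmf_well_value(p, xA, window)
  wb <- pmf_well_value(p, xB, window)
  cc <- p$centers[[1]]
  span <- which(cc >= min(wa$x, wb$x) & cc <= max(wa$x, wb$x) & p$mask)
  if (!length(span)) stop("no masked bins between the matched wells")
  top <- max(p$values[span])
  fwd <- top - wa$value
  bwd <- top - wb$value
  list(top = top, forward = fwd, backward = bwd, dG = fwd - bwd)
}

#' Nearest local minimum of a profile to a reference position
#'
#' Used when reading a block's (noisier) reconstruction at a feature
#' located on the full-data surface: the local minimum nearest the
#' reference arc/coordinate position within \code{window} is used.
#'
#' @param profile Profile data frame (see
#'   \code{\link{profile_along_path}}) or numeric series.
#' @param position Reference position on the \code{by} axis.
#' @param by Axis to match on: "arc", "d1", "d2" or "index".
#' @param window Maximum allowed distance from the reference, A (or index
#'   units for \code{by = "index"}).
#' @param prominence Passed to \code{\link{find_minima_and_barriers}}.
#' @return Row of the minima table (index, d1, d2, F), or an error if no
#'   minimum lies within the window.
#' @export
nearest_minimum <- function(profile, position, by = "arc", window = 1.5,
                            prominence = 0.25) {
  rep_ <- find_minima_and_barriers(profile, prominence)
  minima <- rep_$minima
  if (nrow(minima) == 0) stop("profile has no local minima")
  axis <- if (is.numeric(profile)) minima$index
          else profile[[by]][minima$index]
  dist <- abs(axis - position)
  k <- which.min(dist)
  if (dist[k] > window)
    stop(sprintf("no local minimum within %.3g of position %.4g", window,
                 position))
  minima[k, ]
}
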