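num <- function(x) sprintf("%.10g", x)

#' Write an umbrella window time series
#'
#' Plain-text collective-variable trace: a commented header carrying the
#' bias center, force constant, stride, start time, temperature and
#' equilibration already discarded, then whitespace-separated
#' "time value [value2]" rows ('.' decimal, no locale).  Writing, reading
#' and re-writing is byte-identical.
#'
#' @param window An \code{umbrella_window}.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
write_window <- function(window, file) {
  stopifnot(inherits(window, "umbrella_window"))
  hdr <- c("# ionpmf window file v1",
           paste0("# label=", window$label),
           paste0("# dim=", window$bias$dim),
           paste0("# center=", paste(num(window$bias$center),
                                     collapse = ",")),
           paste0("# k=", num(window$bias$k)),
           paste0("# stride_ps=", num(window$stride)),
           paste0("# t0_ps=", num(window$times[1])),
           paste0("# temperature_K=", num(window$temperature)),
           paste0("# equilibration_ps=", num(window$equilibration)),
           paste0("# columns=time ",
                  paste0("d", seq_len(window$bias$dim), collapse = " ")))
  rows <- apply(cbind(window$times, window$samples), 1,
                function(r) paste(num(r), collapse = " "))
  writeLines(c(hdr, rows), file)
  invisible(file)
}

parse_header <- function(lines, file) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z0-9_]+)=(.*)$", hdr))
  kv <- kv[vapply(kv, length, integer(1)) == 3]
  stats::setNames(lapply(kv, `[`, 3), vapply(kv, `[`, character(1), 2))
}

#' Read an umbrella window time series
#'
#' @param file Path written by \code{\link{write_window}}.
#' @return An \code{umbrella_window}.
#' @export
read_window <- function(file) {
  lines <- readLines(file)
  h <- parse_header(lines, file)
  for (need in c("center", "k", "dim"))
    if (is.null(h[[need]]))
      stop("window file ", file, ": missing '", need, "' header")
  dim <- as.integer(h$dim)
  center <- as.numeric(strsplit(h$center, ",")[[1]])
  if (length(center) != dim) stop("window file ", file,
                                  ": center/dim mismatch")
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(body) == 0) stop("window file ", file, ": no samples")
  fields <- strsplit(trimws(lines[body]), "[[:space:]]+")
  nf <- vapply(fields, length, integer(1))
  if (any(nf != dim + 1L))
    stop("window file ", file, ": malformed row at line ",
         body[which(nf != dim + 1L)[1]])
  M <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = dim + 1L, byrow = TRUE)
  if (anyNA(M))
    stop("window file ", file, ": non-numeric value at line ",
         body[which(rowSums(is.na(M)) > 0)[1]])
  umbrella_window(
    bias_potential(center, as.numeric(h$k)),
    M[, -1, drop = FALSE], M[, 1],
    temperature = if (is.null(h$temperature_K)) 300
                  else as.numeric(h$temperature_K),
    equilibration = if (is.null(h$equilibration_ps)) 0
                    else as.numeric(h$equilibration_ps),
    label = if (is.null(h$label)) "" else h$label)
}

#' Write a PMF grid
#'
#' 1D: "x F" rows; 2D: a dense d1 x d2 matrix (one row per d1 bin) with NaN
#' for masked-out bins, followed by the total-counts matrix.  The header
#' records axes, bin widths, temperature and zero convention.
#'
#' @param p A \code{pmf_grid}.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
write_pmf <- function(p, file) {
  stopifnot(inherits(p, "pmf_grid"))
  hdr <- c("# ionpmf pmf file v1",
           paste0("# dim=", p$dim),
           paste0("# temperature_K=", num(p$temperature)),
           paste0("# zero=", p$zero),
           paste0("# bin_width=", paste(num(p$bin_width), collapse = ",")),
           paste0("# axis1=", paste(num(range(p$centers[[1]])),
                                    collapse = ",")),
           if (p$dim == 2L)
             paste0("# axis2=", paste(num(range(p$centers[[2]])),
                                      collapse = ",")))
  fm <- function(v) ifelse(is.na(v), "NaN", num(v))
  if (p$dim == 1L) {
    rows <- paste(num(p$centers[[1]]), fm(p$values),
                  format(p$counts, trim = TRUE, scientific = FALSE))
    writeLines(c(hdr, "# columns=x F counts", rows), file)
  } else {
    vals <- apply(p$values, 1, function(r) paste(fm(r), collapse = " "))
    cnts <- apply(p$counts, 1, function(r)
      paste(format(r, trim = TRUE, scientific = FALSE), collapse = " "))
    writeLines(c(hdr, "# matrix=F (rows: d1 bins; cols: d2 bins; NaN = unsampled)",
                 vals, "# matrix=counts", cnts), file)
  }
  invisible(file)
}

#' Read a PMF grid
#'
#' @param file Path written by \code{\link{write_pmf}}.
#' @return A \code{pmf_grid}.
#' @export
read_pmf <- function(file) {
  lines <- readLines(file)
  h <- parse_header(lines, file)
  dim <- as.integer(h$dim)
  bw <- as.numeric(strsplit(h$bin_width, ",")[[1]])
  a1 <- as.numeric(strsplit(h$axis1, ",")[[1]])
  centers <- list(seq(a1[1], a1[2], by = bw[1]))
  if (dim == 2L) {
    a2 <- as.numeric(strsplit(h$axis2, ",")[[1]])
    centers <- c(centers, list(seq(a2[1], a2[2], by = bw[2])))
  }
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (dim == 1L) {
    M <- do.call(rbind, lapply(strsplit(trimws(lines[body]),
                                        "[[:space:]]+"), as.numeric))
    values <- M[, 2]; counts <- M[, 3]
    mask <- !is.na(values)
  } else {
    n1 <- length(centers[[1]])
    if (length(body) != 2 * n1)
      stop("PMF file ", file, ": expected ", 2 * n1, " matrix rows, found ",
           length(body))
    parse_m <- function(ix) do.call(rbind, lapply(
      strsplit(trimws(lines[ix]), "[[:space:]]+"), as.numeric))
    values <- parse_m(body[seq_len(n1)])
    counts <- parse_m(body[n1 + seq_len(n1)])
    mask <- !is.na(values)
  }
  structure(list(dim = dim, centers = centers, bin_width = bw,
                 values = values, mask = mask, counts = counts,
                 temperature = as.numeric(h$temperature_K), zero = h$zero,
                 f = NULL, iterations = NA_integer_, residual = NA_real_),
            class = "pmf_grid")
}

#' Write a minimum energy path
#'
#' Plain-text columns: index, d1, d2, cumulative arc length, F.
#'
#' @param path A \code{minimum_energy_path}.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
write_path <- function(path, file) {
  stopifnot(inherits(path, "minimum_energy_path"))
  hdr <- c("# ionpmf path file v1",
           paste0("# n_points=", nrow(path$nodes)),
           paste0("# iterations=", path$iterations),
           paste0("# rms_A=", num(path$rms)),
           paste0("# converged=", ifelse(path$converged, "yes", "no")),
           "# columns=index d1 d2 arc F")
  rows <- sprintf("%d %s %s %s %s", seq_len(nrow(path$nodes)),
                  num(path$nodes[, 1]), num(path$nodes[, 2]),
                  num(path$arc), num(path$F))
  writeLines(c(hdr, rows), file)
  invisible(file)
}

#' Read a minimum energy path
#'
#' @param file Path written by \code{\link{write_path}}.
#' @return A \code{minimum_energy_path}.
#' @export
read_path <- function(file) {
  lines <- readLines(file)
  h <- parse_header(lines, file)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  M <- do.call(rbind, lapply(strsplit(trimws(lines[body]), "[[:space:]]+"),
                             as.numeric))
  structure(list(nodes = M[, 2:3, drop = FALSE], arc = M[, 4], F = M[, 5],
                 iterations = as.integer(h$iterations),
                 rms = as.numeric(h$rms_A), tol = NA_real_,
                 converged = identical(h$converged, "yes")),
            class = "minimum_energy_path")
}

#' Write a block-error report table
#'
#' Plain-text table: one row per quantity with the full-data value, the
#' per-block values, their mean and standard deviation, plus the rendered
#' "x±y kcal/mol" form.
#'
#' @param estimates List of \code{block_estimate}.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
write_report <- function(estimates, file) {
  if (inherits(estimates, "block_estimate")) estimates <- list(estimates)
  nb <- estimates[[1]]$n_blocks
  hdr <- c("# ionpmf block report v1",
           paste0("# columns=quantity full ",
                  paste0("block", seq_len(nb), collapse = " "),
                  " mean sd pm"))
  rows <- vapply(estimates, function(e) {
    paste(c(gsub("[[:space:]]+", "_", e$label), num(e$full),
            num(e$blocks), num(e$mean), num(e$sd),
            gsub(" ", "_", format_pm(e$full, e$sd))), collapse = " ")
  }, character(1))
  writeLines(c(hdr, rows), file)
  invisible(file)
}

#' Read a block-error report table
#'
#' @param file Path written by \code{\link{write_report}}.
#' @return List of \code{block_estimate}.
#' @export
read_report <- function(file) {
  lines <- readLines(file)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  lapply(strsplit(trimws(lines[body]), "[[:space:]]+"), function(f) {
    nb <- length(f) - 5L
    structure(list(label = f[1], full = as.numeric(f[2]),
                   blocks = as.numeric(f[2 + seq_len(nb)]),
                   mean = as.numeric(f[nb + 3L]), sd = as.numeric(f[nb + 4L]),
                   n_blocks = nb, errors = character(0)),
              class = "block_estimate")
  })
}

#' Write the analytic-surface parameter record
#'
#' Ground-truth bookkeeping for synthetic experiments: well centers,
#' depths, widths, background and domain, as a commented key=value file.
#'
#' @param surface An \code{analytic_surface}.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
write_surface <- function(surface, file) {
  stopifnot(inherits(surface, "analytic_surface"))
  p <- surface$params
  writeLines(c(
    "# ionpmf analytic surface v1",
    paste0("# dim=", surface$dim),
    paste0("# centers=", paste(apply(p$centers, 1, function(r)
      paste(num(r), collapse = ",")), collapse = ";")),
    paste0("# depths=", paste(num(p$depths), collapse = ",")),
    paste0("# widths=", paste(num(p$widths), collapse = ",")),
    paste0("# bg_k=", num(p$bg_k)),
    paste0("# bg_center=", paste(num(p$bg_center), collapse = ",")),
    paste0("# bounds=", paste(apply(surface$bounds, 1, function(r)
      paste(num(r), collapse = ",")), collapse = ";"))), file)
  invisible(file)
}

#' Read an analytic-surface parameter record
#'
#' @param file Path written by \code{\link{write_surface}}.
#' @return An \code{analytic_surface} (re-normalized on construction).
#' @export
read_surface <- function(file) {
  h <- parse_header(readLines(file), file)
  parse_rows <- function(s) do.call(rbind, lapply(
    strsplit(strsplit(s, ";")[[1]], ","), as.numeric))
  analytic_surface(parse_rows(h$centers),
                   as.numeric(strsplit(h$depths, ",")[[1]]),
                   as.numeric(strsplit(h$widths, ",")[[1]]),
                   bg_k = as.numeric(h$bg_k),
                   bg_center = as.numeric(strsplit(h$bg_center, ",")[[1]]),
                   bounds = parse_rows(h$bounds))
}

#' Read a plain-text key = value configuration file
#'
#' Sections in square brackets prefix their keys ("section.key"); values
#' are parsed as numbers where possible.  Keys mirror
#' \code{\link{pipeline_config}}.
#'
#' @param file Config path.
#' @return Named list.
#' @export
read_config <- function(file) {
  lines <- readLines(file)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- ""
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      if (nzchar(section)) key <- paste(section, key, sep = ".")
      val <- trimws(paste(kv[-1], collapse = "="))
      nval <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
      out[[key]] <- if (anyNA(nval)) val else nval
    } else {
      stop("cannot parse config line: ", ln)
    }
  }
  out
}
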