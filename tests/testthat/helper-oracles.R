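# Independent oracles used against the package's own implementations.

# Direct minimization of the multinomial WHAM likelihood over the unbiased
# bin probabilities (softmax parametrization), independent of the
# self-consistent iteration in solve_wham.
wham_likelihood_oracle <- function(h) {
  kT <- kT_kcal(h$temperature)
  M <- rowSums(h$counts)
  occ <- which(M > 0)
  X <- if (h$dim == 1L) matrix(h$centers[[1]][occ], ncol = 1) else {
    G <- as.matrix(expand.grid(d2 = h$centers[[2]],
                               d1 = h$centers[[1]]))[, c("d1", "d2")]
    G[occ, , drop = FALSE]
  }
  U <- vapply(h$biases, function(b) bias_energy(b, X), numeric(length(occ)))
  U <- matrix(U, nrow = length(occ))
  H <- h$counts[occ, , drop = FALSE]
  N <- h$N
  negll <- function(q) {
    p <- exp(q - max(q)); p <- p / sum(p)
    lw <- -U / kT + log(p)              # log(c_ij p_j), bins x windows
    lz <- apply(lw, 2, function(col) {  # log sum_j c_ij p_j per window
      m <- max(col); m + log(sum(exp(col - m)))
    })
    -(sum(H * lw) - sum(N * lz))
  }
  negll_grad <- function(q) {
    p <- exp(q - max(q)); p <- p / sum(p)
    C <- exp(-U / kT)
    z <- as.numeric(crossprod(C, p))    # sum_j c_ij p_j per window
    dLdp <- -rowSums(H) / p + as.numeric(C %*% (N / z))
    p * (dLdp - sum(p * dLdp))          # softmax chain rule
  }
  q0 <- log(M[occ] / sum(M[occ]))
  opt <- stats::optim(q0, negll, gr = negll_grad, method = "BFGS",
                      control = list(maxit = 10000, reltol = 1e-15))
  p <- exp(opt$par - max(opt$par)); p <- p / sum(p)
  Fv <- -kT * log(p)
  list(occ = occ, F = Fv - min(Fv), value = opt$value)
}

# residual of the self-consistent WHAM equations at a given PMF solution
wham_selfconsistency_residual <- function(h, pmf) {
  kT <- kT_kcal(h$temperature)
  M <- rowSums(h$counts)
  occ <- which(M > 0)
  X <- if (h$dim == 1L) matrix(h$centers[[1]][occ], ncol = 1) else {
    G <- as.matrix(expand.grid(d2 = h$centers[[2]],
                               d1 = h$centers[[1]]))[, c("d1", "d2")]
    G[occ, , drop = FALSE]
  }
  U <- matrix(vapply(h$biases, function(b) bias_energy(b, X),
                     numeric(length(occ))), nrow = length(occ))
  vals <- if (pmf$dim == 1L) pmf$values else as.numeric(t(pmf$values))
  Fv <- vals[occ]
  p <- exp(-Fv / kT)
  f <- -kT * log(colSums(p * exp(-U / kT)))
  p2 <- M[occ] / (exp(-U / kT) %*% (h$N * exp(f / kT)))
  f2 <- -kT * log(colSums(as.numeric(p2) * exp(-U / kT)))
  max(abs((f2 - f2[1]) - (f - f[1])))
}

# Brute-force minimax (widest-path) saddle between two basins on a dense
# grid: activate cells in order of increasing free energy, union-find the
# 4-neighbour graph, and report the activation level at which the basin
# cells first connect.
minimax_saddle_oracle <- function(value_fn, bounds, a, b, h = 0.05) {
  xs <- seq(bounds[1, 1], bounds[1, 2], by = h)
  ys <- seq(bounds[2, 1], bounds[2, 2], by = h)
  n1 <- length(xs); n2 <- length(ys)
  G <- as.matrix(expand.grid(x = xs, y = ys))
  Fv <- value_fn(G)
  id_of <- function(pt) {
    i <- which.min(abs(xs - pt[1])); j <- which.min(abs(ys - pt[2]))
    (j - 1L) * n1 + i
  }
  a_id <- id_of(a); b_id <- id_of(b)
  ord <- order(Fv)
  parent <- seq_len(n1 * n2)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  active <- logical(n1 * n2)
  for (cell in ord) {
    active[cell] <- TRUE
    i <- (cell - 1L) %% n1 + 1L
    j <- (cell - 1L) %/% n1 + 1L
    for (nb in c(if (i > 1) cell - 1L, if (i < n1) cell + 1L,
                 if (j > 1) cell - n1, if (j < n2) cell + n1)) {
      if (active[nb]) {
        ra <- find(cell); rb <- find(nb)
        if (ra != rb) parent[ra] <- rb
      }
    }
    if (active[a_id] && active[b_id] && find(a_id) == find(b_id))
      return(Fv[cell])
  }
  stop("basins never connected")
}

# central finite differences of a 1D/2D scalar field closure
fd_gradient <- function(fn, X, h = 1e-4) {
  X <- as.matrix(X)
  d <- ncol(X)
  out <- matrix(0, nrow(X), d)
  for (k in seq_len(d)) {
    Xp <- X; Xp[, k] <- Xp[, k] + h
    Xm <- X; Xm[, k] <- Xm[, k] - h
    out[, k] <- (fn(Xp) - fn(Xm)) / (2 * h)
  }
  out
}

# dense fully-masked grid of x^2 + y^2, a known-analytic interpolation target
quad_grid <- function(bw = 0.25) {
  cx <- seq(-2, 2, bw); cy <- seq(-1, 3, bw)
  structure(list(dim = 2L, centers = list(cx, cy), bin_width = c(bw, bw),
                 values = outer(cx, cy, function(x, y) x^2 + y^2),
                 mask = matrix(TRUE, length(cx), length(cy)),
                 counts = matrix(10, length(cx), length(cy)),
                 temperature = 300, zero = "min-zero"),
            class = "pmf_grid")
}

# small, fast 1D study set shared by several tests
quick_protocol_1d <- function(seed = 2012, duration = 500) {
  cfg <- pipeline_config(seed = seed, window_duration = duration)
  proto <- study_protocol_1d(cfg)
  list(cfg = cfg, surface = proto$surface, windows = proto$windows,
       sampled = sample_protocol(proto$surface, proto$windows, cfg))
}
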