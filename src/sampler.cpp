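#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Analytic landscape: sum of inverted isotropic Gaussian wells on a weak
// confining quadratic background,
//   F(x) = sum_m -A_m exp(-|x - c_m|^2 / (2 s_m^2)) + b |x - x0|^2 - offset
// with offset chosen by the R-side constructor so min over the domain is 0.

static double well_value(const double *x, int d,
                         const double *centers, int m,
                         const double *depths, const double *widths,
                         double bg_k, const double *bg_center,
                         double offset) {
  double v = 0.0;
  for (int w = 0; w < m; ++w) {
    double r2 = 0.0;
    for (int k = 0; k < d; ++k) {
      double dx = x[k] - centers[w + m * k];
      r2 += dx * dx;
    }
    v -= depths[w] * std::exp(-r2 / (2.0 * widths[w] * widths[w]));
  }
  double b2 = 0.0;
  for (int k = 0; k < d; ++k) {
    double dx = x[k] - bg_center[k];
    b2 += dx * dx;
  }
  return v + bg_k * b2 - offset;
}

static void well_grad(const double *x, int d,
                      const double *centers, int m,
                      const double *depths, const double *widths,
                      double bg_k, const double *bg_center,
                      double *g) {
  for (int k = 0; k < d; ++k) g[k] = 0.0;
  for (int w = 0; w < m; ++w) {
    double r2 = 0.0;
    for (int k = 0; k < d; ++k) {
      double dx = x[k] - centers[w + m * k];
      r2 += dx * dx;
    }
    double s2 = widths[w] * widths[w];
    double e = depths[w] * std::exp(-r2 / (2.0 * s2)) / s2;
    for (int k = 0; k < d; ++k) {
      double dx = x[k] - centers[w + m * k];
      g[k] += e * dx;  // d/dx of -A exp(.) is +A/s^2 dx exp(.)
    }
  }
  for (int k = 0; k < d; ++k) g[k] += 2.0 * bg_k * (x[k] - bg_center[k]);
}

// [[Rcpp::export]]
NumericVector cpp_surface_value(NumericMatrix X, NumericMatrix centers,
                                NumericVector depths, NumericVector widths,
                                double bg_k, NumericVector bg_center,
                                double offset) {
  int n = X.nrow(), d = X.ncol(), m = centers.nrow();
  NumericVector out(n);
  std::vector<double> x(d);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < d; ++k) x[k] = X(i, k);
    out[i] = well_value(x.data(), d, centers.begin(), m, depths.begin(),
                        widths.begin(), bg_k, bg_center.begin(), offset);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_surface_grad(NumericMatrix X, NumericMatrix centers,
                               NumericVector depths, NumericVector widths,
                               double bg_k, NumericVector bg_center) {
  int n = X.nrow(), d = X.ncol(), m = centers.nrow();
  NumericMatrix out(n, d);
  std::vector<double> x(d), g(d);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < d; ++k) x[k] = X(i, k);
    well_grad(x.data(), d, centers.begin(), m, depths.begin(), widths.begin(),
              bg_k, bg_center.begin(), g.data());
    for (int k = 0; k < d; ++k) out(i, k) = g[k];
  }
  return out;
}

// Overdamped Langevin (Euler-Maruyama) on surface + harmonic bias:
//   dx = -(D/kT) grad(F + U) dt + sqrt(2 D dt) xi,  U = 0.5 k |x - c|^2
// Reflecting walls at the domain bounds; an excursion beyond bounds by more
// than `margin` before reflection signals an unstable time step and aborts.
// Draws come from R's RNG (RNGScope via Rcpp attributes), so results are a
// pure function of set.seed() state and the arguments.

// [[Rcpp::export]]
NumericMatrix cpp_sample_window(NumericVector x0, NumericMatrix centers,
                                NumericVector depths, NumericVector widths,
                                double bg_k, NumericVector bg_center,
                                double offset, NumericVector bias_center,
                                double bias_k, double kT, double D, double dt,
                                int n_samples, int steps_per_sample,
                                NumericVector lower, NumericVector upper,
                                double margin) {
  int d = x0.size(), m = centers.nrow();
  NumericMatrix out(n_samples, d);
  std::vector<double> x(d), g(d);
  for (int k = 0; k < d; ++k) x[k] = x0[k];
  double mob = D / kT;           // mobility (A^2 / ps / (kcal/mol))
  double noise = std::sqrt(2.0 * D * dt);
  for (int i = 0; i < n_samples; ++i) {
    if (i > 0) {
      for (int s = 0; s < steps_per_sample; ++s) {
        well_grad(x.data(), d, centers.begin(), m, depths.begin(),
                  widths.begin(), bg_k, bg_center.begin(), g.data());
        for (int k = 0; k < d; ++k) {
          double f = g[k] + bias_k * (x[k] - bias_center[k]);
          double xn = x[k] - mob * f * dt + noise * norm_rand();
          if (xn < lower[k] - margin || xn > upper[k] + margin)
            stop("sampler left the domain by more than the margin at step %d; "
                 "the time step is unstable for this landscape", s);
          // reflecting walls
          int guard = 0;
          while ((xn < lower[k] || xn > upper[k]) && guard++ < 64) {
            if (xn < lower[k]) xn = 2.0 * lower[k] - xn;
            if (xn > upper[k]) xn = 2.0 * upper[k] - xn;
          }
          x[k] = xn;
        }
      }
    }
    for (int k = 0; k < d; ++k) out(i, k) = x[k];
  }
  return out;
}
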