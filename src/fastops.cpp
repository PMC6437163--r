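#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Inverse-variance weighted median of each row of a ratio matrix:
// order the ratios, interpolate the standardized cumulative weight
// midpoints at 0.5. Used for the parametric-bootstrap SE, where this is
// evaluated for thousands of redrawn (theta, weight) rows.
// [[Rcpp::export]]
NumericVector weighted_median_batch(NumericMatrix theta, NumericMatrix w) {
  const int n = theta.nrow(), J = theta.ncol();
  if (w.nrow() != n || w.ncol() != J)
    stop("theta and w must have identical dimensions");
  NumericVector out(n);
  std::vector<int> idx(J);
  std::vector<double> th(J), wt(J);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < J; ++j) idx[j] = j;
    NumericMatrix::Row ti = theta(i, _);
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return ti[a] < ti[b]; });
    double total = 0.0;
    for (int j = 0; j < J; ++j) {
      th[j] = theta(i, idx[j]);
      wt[j] = w(i, idx[j]);
      total += wt[j];
    }
    double cum = 0.0, s_prev = 0.0, res = th[J - 1];
    bool done = false;
    for (int j = 0; j < J; ++j) {
      double s = (cum + wt[j] / 2.0) / total;  // midpoint of this ratio
      if (s >= 0.5) {
        if (j == 0) res = th[0];
        else {
          double t = (0.5 - s_prev) / (s - s_prev);
          res = th[j - 1] + t * (th[j] - th[j - 1]);
        }
        done = true;
        break;
      }
      cum += wt[j];
      s_prev = s;
    }
    if (!done) res = th[J - 1];
    out[i] = res;
  }
  return out;
}

static double median_of(std::vector<double>& x) {
  const size_t n = x.size();
  std::nth_element(x.begin(), x.begin() + n / 2, x.end());
  double hi = x[n / 2];
  if (n % 2 == 1) return hi;
  std::nth_element(x.begin(), x.begin() + n / 2 - 1, x.end());
  return 0.5 * (x[n / 2 - 1] + hi);
}

// Mode of the weighted normal-kernel density of each row, located on a
// regular grid centred robustly (median +/- span * scaled MAD): bootstrap
// redraws can produce near-zero exposure effects and hence extreme ratios,
// which would wreck mean/SD grid placement while carrying negligible
// weight. Grid resolution is a caller choice (the point estimate refines
// its grid mode separately; the bootstrap uses the grid mode as-is).
// [[Rcpp::export]]
NumericVector kernel_mode_batch(NumericMatrix theta, NumericMatrix w,
                                NumericVector h, int grid_n, double span) {
  const int n = theta.nrow(), J = theta.ncol();
  if (w.nrow() != n || w.ncol() != J)
    stop("theta and w must have identical dimensions");
  if (h.size() != n) stop("h must have one bandwidth per row");
  if (grid_n < 2) stop("grid_n must be >= 2");
  NumericVector out(n);
  std::vector<double> buf(J), dev(J);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < J; ++j) buf[j] = theta(i, j);
    const double med = median_of(buf);
    for (int j = 0; j < J; ++j) dev[j] = std::fabs(theta(i, j) - med);
    double scale = 1.4826 * median_of(dev);
    if (scale <= 0.0) {
      double m = 0.0;
      for (int j = 0; j < J; ++j) m += theta(i, j);
      m /= J;
      double v = 0.0;
      for (int j = 0; j < J; ++j) {
        const double d = theta(i, j) - m;
        v += d * d;
      }
      scale = std::sqrt(v / (J - 1));
    }
    const double bw = h[i];
    if (scale <= 0.0 || bw <= 0.0) {
      out[i] = theta(i, 0);
      continue;
    }
    const double lo = med - span * scale;
    const double step = 2.0 * span * scale / (grid_n - 1);
    const double inv2h2 = 1.0 / (2.0 * bw * bw);
    double best_f = -1.0, best_x = lo;
    for (int g = 0; g < grid_n; ++g) {
      const double x = lo + g * step;
      double f = 0.0;
      for (int j = 0; j < J; ++j) {
        const double d = x - theta(i, j);
        f += w(i, j) * std::exp(-d * d * inv2h2);
      }
      if (f > best_f) {
        best_f = f;
        best_x = x;
      }
    }
    out[i] = best_x;
  }
  return out;
}
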