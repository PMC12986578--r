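#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Local maxima of p with exact plateaus collapsed to their right edge
// (zero slopes are nudged positive, matching the R-side convention).
static void find_maxima(const std::vector<double>& p, std::vector<int>& out,
                        bool negate) {
  int n = p.size();
  out.clear();
  if (n < 3) return;
  double eps = std::numeric_limits<double>::epsilon();
  double prev = 0.0;
  bool have_prev = false;
  for (int i = 1; i < n; ++i) {
    double d = negate ? (p[i - 1] - p[i]) : (p[i] - p[i - 1]);
    if (d == 0.0) d = eps;
    if (have_prev && prev > 0.0 && d < 0.0) out.push_back(i - 1); // 0-based peak
    prev = d;
    have_prev = true;
  }
}

// Natural cubic spline through (xs, ys), evaluated at 1..n (1-based grid),
// accumulated into acc (and the envelope returned in env).
static void spline_env(const std::vector<double>& xs,
                       const std::vector<double>& ys,
                       int n, std::vector<double>& env) {
  int m = xs.size();
  env.assign(n, 0.0);
  if (m == 2) { // linear fallback
    double slope = (ys[1] - ys[0]) / (xs[1] - xs[0]);
    for (int t = 0; t < n; ++t) env[t] = ys[0] + slope * ((t + 1) - xs[0]);
    return;
  }
  std::vector<double> h(m - 1), alpha(m, 0.0), l(m), mu(m), z(m), M(m);
  for (int i = 0; i < m - 1; ++i) h[i] = xs[i + 1] - xs[i];
  for (int i = 1; i < m - 1; ++i)
    alpha[i] = 6.0 * ((ys[i + 1] - ys[i]) / h[i] - (ys[i] - ys[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < m - 1; ++i) {
    l[i] = 2.0 * (xs[i + 1] - xs[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  M[m - 1] = 0.0;
  for (int i = m - 2; i >= 0; --i) M[i] = z[i] - mu[i] * M[i + 1];
  int seg = 0;
  for (int t = 0; t < n; ++t) {
    double x = t + 1;
    while (seg < m - 2 && xs[seg + 1] < x) ++seg;
    double hi = h[seg];
    double a = (xs[seg + 1] - x) / hi, b = (x - xs[seg]) / hi;
    env[t] = a * ys[seg] + b * ys[seg + 1] +
      ((a * a * a - a) * M[seg] + (b * b * b - b) * M[seg + 1]) * (hi * hi) / 6.0;
  }
}

// Build mirrored knot sequence (two extrema reflected beyond each edge).
static void mirror_knots(const std::vector<int>& idx, int n,
                         std::vector<double>& xs, std::vector<int>& rows) {
  int m = idx.size();
  std::vector<double> raw_x;
  std::vector<int> raw_r;
  int nl = std::min(2, m);
  for (int k = nl - 1; k >= 0; --k) { // left mirror about sample 1
    raw_x.push_back(2.0 - (idx[k] + 1));
    raw_r.push_back(idx[k]);
  }
  for (int k = 0; k < m; ++k) { raw_x.push_back(idx[k] + 1); raw_r.push_back(idx[k]); }
  for (int k = 0; k < std::min(2, m); ++k) { // right mirror about sample n
    raw_x.push_back(2.0 * n - (idx[m - 1 - k] + 1));
    raw_r.push_back(idx[m - 1 - k]);
  }
  xs.clear(); rows.clear();
  for (size_t k = 0; k < raw_x.size(); ++k) {
    if (!xs.empty() && raw_x[k] <= xs.back()) continue; // drop non-increasing dups
    xs.push_back(raw_x[k]);
    rows.push_back(raw_r[k]);
  }
}

// Direction-averaged local mean and amplitude for one MEMD sifting
// iteration: project onto each direction, spline-interpolate the
// multivariate signal at the projection's maxima / minima, average.
// [[Rcpp::export]]
List memd_envelope_mean(NumericMatrix X, NumericMatrix dirs) {
  int n = X.nrow(), nch = X.ncol(), K = dirs.nrow();
  NumericMatrix acc(n, nch);
  NumericVector amp(n);
  int n_good = 0;
  std::vector<double> p(n), xs, ys, env_hi, env_lo;
  std::vector<int> imax, imin, rows;
  std::vector<double> emax(n * nch), emin(n * nch);
  for (int q = 0; q < K; ++q) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < nch; ++j) s += X(i, j) * dirs(q, j);
      p[i] = s;
    }
    find_maxima(p, imax, false);
    find_maxima(p, imin, true);
    if (imax.size() < 2 || imin.size() < 2) continue;
    // upper envelope
    mirror_knots(imax, n, xs, rows);
    for (int j = 0; j < nch; ++j) {
      ys.resize(xs.size());
      for (size_t k = 0; k < xs.size(); ++k) ys[k] = X(rows[k], j);
      spline_env(xs, ys, n, env_hi);
      for (int t = 0; t < n; ++t) emax[j * n + t] = env_hi[t];
    }
    // lower envelope
    mirror_knots(imin, n, xs, rows);
    for (int j = 0; j < nch; ++j) {
      ys.resize(xs.size());
      for (size_t k = 0; k < xs.size(); ++k) ys[k] = X(rows[k], j);
      spline_env(xs, ys, n, env_lo);
      for (int t = 0; t < n; ++t) emin[j * n + t] = env_lo[t];
    }
    for (int t = 0; t < n; ++t) {
      double ss = 0.0;
      for (int j = 0; j < nch; ++j) {
        double hi = emax[j * n + t], lo = emin[j * n + t];
        acc(t, j) += 0.5 * (hi + lo);
        double d = hi - lo;
        ss += d * d;
      }
      amp[t] += 0.5 * std::sqrt(ss);
    }
    ++n_good;
  }
  return List::create(_["mean"] = acc, _["amp"] = amp, _["n_good"] = n_good);
}

// Count of projection extrema across directions until proven decomposable.
// [[Rcpp::export]]
bool memd_has_extrema(NumericMatrix X, NumericMatrix dirs) {
  int n = X.nrow(), nch = X.ncol(), K = dirs.nrow();
  std::vector<double> p(n);
  std::vector<int> imax, imin;
  for (int q = 0; q < K; ++q) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < nch; ++j) s += X(i, j) * dirs(q, j);
      p[i] = s;
    }
    find_maxima(p, imax, false);
    find_maxima(p, imin, true);
    if ((int)(imax.size() + imin.size()) >= 3) return true;
  }
  return false;
}
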