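#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Truncated separable Gaussian smoothing with mask-aware renormalisation.
// values: matrix with masked/out-of-range cells set to 0; indicator: 1 for
// cells that participate, 0 otherwise. Returns K*values / K*indicator where
// K is the 2-D Gaussian of bandwidth h truncated at +/-3h. Cells outside the
// matrix (and masked cells) are excluded from numerator and denominator
// alike; where the denominator is 0 the output is NA.
// [[Rcpp::export]]
NumericMatrix cpp_kde_smooth(const NumericMatrix& values,
                             const NumericMatrix& indicator, int h) {
  const int n = values.nrow(), m = values.ncol();
  const int r = 3 * h;
  std::vector<double> k(2 * r + 1);
  for (int t = -r; t <= r; ++t)
    k[t + r] = std::exp(-(double)(t * t) / (2.0 * h * h));

  // pass 1: convolve along rows within each column (contiguous memory)
  std::vector<double> nv(n * m), ni(n * m);
  const double* V = values.begin();
  const double* I = indicator.begin();
  for (int j = 0; j < m; ++j) {
    const double* vj = V + (size_t)j * n;
    const double* ij = I + (size_t)j * n;
    double* nvj = nv.data() + (size_t)j * n;
    double* nij = ni.data() + (size_t)j * n;
    for (int i = 0; i < n; ++i) {
      double sv = 0.0, si = 0.0;
      const int lo = std::max(0, i - r), hi = std::min(n - 1, i + r);
      const double* kk = k.data() + (lo - i + r);
      for (int a = lo; a <= hi; ++a, ++kk) {
        sv += *kk * vj[a];
        si += *kk * ij[a];
      }
      nvj[i] = sv;
      nij[i] = si;
    }
  }
  // transpose so pass 2 also walks contiguous memory
  std::vector<double> tv(n * m), ti(n * m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) {
      tv[(size_t)i * m + j] = nv[(size_t)j * n + i];
      ti[(size_t)i * m + j] = ni[(size_t)j * n + i];
    }
  NumericMatrix out(n, m);
  for (int i = 0; i < n; ++i) {
    const double* vi = tv.data() + (size_t)i * m;
    const double* ii = ti.data() + (size_t)i * m;
    for (int j = 0; j < m; ++j) {
      double sv = 0.0, si = 0.0;
      const int lo = std::max(0, j - r), hi = std::min(m - 1, j + r);
      const double* kk = k.data() + (lo - j + r);
      for (int b = lo; b <= hi; ++b, ++kk) {
        sv += *kk * vi[b];
        si += *kk * ii[b];
      }
      out(i, j) = (si > 0.0) ? sv / si : NA_REAL;
    }
  }
  return out;
}

// Window coverage via a 0-padded prefix-sum matrix (cum has n+1 rows/cols,
// cum(i,j) = sum of rc[0..i-1, 0..j-1]). Indices clamp to the matrix edge.
static inline double cov_query(const NumericMatrix& cum, int n, int i, int j,
                               int r) {
  const int r1 = std::max(0, i - r), r2 = std::min(n - 1, i + r);
  const int c1 = std::max(0, j - r), c2 = std::min(n - 1, j + r);
  return cum(r2 + 1, c2 + 1) - cum(r2 + 1, c1) - cum(r1, c2 + 1) + cum(r1, c1);
}

// Smallest integer bandwidth h in [1, hMax] whose (6h+1)^2 window (clipped to
// the matrix) holds at least min_count raw reads; hMax where never reached.
// [[Rcpp::export]]
IntegerMatrix cpp_adaptive_bandwidth(const NumericMatrix& cum, int n,
                                     double min_count, int h_max) {
  IntegerMatrix h(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      int hv = h_max;
      for (int t = 1; t <= h_max; ++t) {
        if (cov_query(cum, n, i, j, 3 * t) >= min_count) { hv = t; break; }
      }
      h(i, j) = hv;
    }
  }
  return h;
}

// Raw-read coverage of the +/-3h window around every cell, for a fixed h.
// [[Rcpp::export]]
NumericMatrix cpp_window_coverage(const NumericMatrix& cum, int n, int h) {
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      out(i, j) = cov_query(cum, n, i, j, 3 * h);
  return out;
}

// Brute-force truncated-Gaussian KDE evaluated only at the requested cells
// (0-based row/col indices). Same edge/mask contract as cpp_kde_smooth;
// cheaper than a full-matrix pass when few cells need a given bandwidth.
// [[Rcpp::export]]
NumericVector cpp_kde_at_cells(const NumericMatrix& values,
                               const NumericMatrix& indicator, int h,
                               const IntegerVector& rows,
                               const IntegerVector& cols) {
  const int n = values.nrow(), m = values.ncol();
  const int r = 3 * h;
  std::vector<double> k(2 * r + 1);
  for (int t = -r; t <= r; ++t)
    k[t + r] = std::exp(-(double)(t * t) / (2.0 * h * h));
  const int nc = rows.size();
  NumericVector out(nc);
  const double* V = values.begin();
  const double* I = indicator.begin();
  for (int c = 0; c < nc; ++c) {
    const int i = rows[c], j = cols[c];
    const int alo = std::max(0, i - r), ahi = std::min(n - 1, i + r);
    const int blo = std::max(0, j - r), bhi = std::min(m - 1, j + r);
    double sv = 0.0, si = 0.0;
    for (int b = blo; b <= bhi; ++b) {     // columns: contiguous inner loop
      const double wb = k[b - j + r];
      const double* vb = V + (size_t)b * n;
      const double* ib = I + (size_t)b * n;
      double rv = 0.0, ri = 0.0;
      const double* kk = k.data() + (alo - i + r);
      for (int a = alo; a <= ahi; ++a, ++kk) {
        rv += *kk * vb[a];
        ri += *kk * ib[a];
      }
      sv += wb * rv;
      si += wb * ri;
    }
    out[c] = (si > 0.0) ? sv / si : NA_REAL;
  }
  return out;
}

// two-sample Kolmogorov-Smirnov D for equal-length small samples
static double ks_d(std::vector<double>& x, std::vector<double>& y) {
  std::sort(x.begin(), x.end());
  std::sort(y.begin(), y.end());
  const int nx = x.size(), ny = y.size();
  int ix = 0, iy = 0;
  double d = 0.0;
  while (ix < nx && iy < ny) {
    const double z = std::min(x[ix], y[iy]);
    while (ix < nx && x[ix] <= z) ++ix;
    while (iy < ny && y[iy] <= z) ++iy;
    const double diff = std::fabs((double)ix / nx - (double)iy / ny);
    if (diff > d) d = diff;
  }
  return d;
}

// Scaled KS statistics D * sqrt(n*m/(n+m)) between adjacent rows over all
// sliding column segments of length seg_len. Entry (i, j) (0-based) is the
// statistic between rows i and i+1 on columns j .. j+seg_len-1.
// [[Rcpp::export]]
NumericMatrix cpp_ks_segment_stats(const NumericMatrix& mat, int seg_len) {
  const int n = mat.nrow(), m = mat.ncol();
  const int ns = m - seg_len + 1;
  NumericMatrix out(n - 1, ns);
  std::vector<double> x(seg_len), y(seg_len);
  const double scale = std::sqrt((double)seg_len * seg_len / (2.0 * seg_len));
  for (int i = 0; i + 1 < n; ++i) {
    for (int j = 0; j < ns; ++j) {
      for (int t = 0; t < seg_len; ++t) {
        x[t] = mat(i, j + t);
        y[t] = mat(i + 1, j + t);
      }
      out(i, j) = scale * ks_d(x, y);
    }
  }
  return out;
}
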