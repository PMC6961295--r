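#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Markov-random-field estimator: log-normal neighbourhood prior centred on
// the boundary-respecting median of the eight neighbours, Poisson (or
// negative-binomial) read-count likelihood, optimised by iterated
// conditional modes over a grid of multiplicative update factors.
//
// The matrix is symmetric, so ICM updates the unordered pair {(i,j),(j,i)}
// jointly; the local objective collects every joint-probability term that
// depends on the pair's value (both cells' priors and likelihoods plus the
// priors of all neighbours of either cell), which makes the joint log
// probability exactly non-decreasing across updates.

static const double IF_EPS = 1e-12;   // floor on IF values inside logs
static const double MED_EPS = 1e-6;   // regulariser inside log(MedNeigh)
static const double SIG2_MIN = 0.01;  // floor on the prior variance

struct MrfState {
  const NumericMatrix& F;      // current IF estimate (normalized scale)
  const NumericMatrix& RC;     // raw counts
  const NumericVector& bias;   // fragment biases
  const LogicalVector& fmask;  // masked fragments
  const LogicalMatrix& hb;     // hb(i,c): boundary between rows i,i+1 at col c
  const LogicalMatrix& vb;     // vb(r,j): boundary between cols j,j+1 at row r
  double alpha;
  double vmult;                // NB variance multiplier; <= 1 means Poisson
  int n;
};

static inline bool cell_ok(const MrfState& s, int i, int j) {
  return !s.fmask[i] && !s.fmask[j];
}

// May neighbour (a,b) contribute to the neighbourhood of (i,j)? Excluded when
// the step crosses a detected transition boundary (tested at both the source
// and destination row/column, so the relation is symmetric).
static inline bool neighbor_ok(const MrfState& s, int i, int j, int a, int b) {
  if (a < 0 || b < 0 || a >= s.n || b >= s.n) return false;
  if (!cell_ok(s, a, b)) return false;
  if (a != i) {
    const int r = std::min(i, a);
    if (s.hb(r, j) || s.hb(r, b)) return false;
  }
  if (b != j) {
    const int c = std::min(j, b);
    if (s.vb(i, c) || s.vb(a, c)) return false;
  }
  return true;
}

// value at (a,b) with the symmetric pair {(ui,uj),(uj,ui)} overridden to ov
static inline double val_at(const MrfState& s, int a, int b, int ui, int uj,
                            double ov) {
  if (ui >= 0 && ((a == ui && b == uj) || (a == uj && b == ui))) return ov;
  return s.F(a, b);
}

// median of the usable neighbours of (i,j) under the override; -1 if none
static double med_neigh(const MrfState& s, int i, int j, int ui, int uj,
                        double ov) {
  double v[8];
  int k = 0;
  for (int di = -1; di <= 1; ++di) {
    for (int dj = -1; dj <= 1; ++dj) {
      if (di == 0 && dj == 0) continue;
      const int a = i + di, b = j + dj;
      if (!neighbor_ok(s, i, j, a, b)) continue;
      v[k++] = val_at(s, a, b, ui, uj, ov);
    }
  }
  if (k == 0) return -1.0;
  std::sort(v, v + k);
  return (k % 2 == 1) ? v[k / 2] : 0.5 * (v[k / 2 - 1] + v[k / 2]);
}

// log prior density of value x at a cell whose neighbourhood median is med
static inline double log_prior(const MrfState& s, double x, double med) {
  if (med < 0.0) return 0.0;  // no usable neighbour: prior skipped
  const double mu = std::log(med + MED_EPS);
  const double sig2 = std::max(s.alpha * mu, SIG2_MIN);
  const double z = std::log(std::max(x, IF_EPS)) - mu;
  return -0.5 * std::log(2.0 * M_PI * sig2) - z * z / (2.0 * sig2);
}

// log likelihood of count RC(i,j) given IF value x
static inline double log_lik(const MrfState& s, int i, int j, double x) {
  const double lam = std::max(x * s.bias[i] * s.bias[j], IF_EPS);
  const double rc = s.RC(i, j);
  if (s.vmult <= 1.0) {
    return rc * std::log(lam) - lam - std::lgamma(rc + 1.0);
  }
  const double r = lam / (s.vmult - 1.0);  // NB size giving variance vmult*lam
  return std::lgamma(rc + r) - std::lgamma(r) - std::lgamma(rc + 1.0) +
         r * std::log(r / (r + lam)) + rc * std::log(lam / (r + lam));
}

// Precomputed description of the cells affected by updating the pair
// {(i,j),(j,i)}: for each such cell, its usable-neighbour values excluding
// the updated pair (sorted) plus how many of its neighbours ARE the pair.
struct AffectedCell {
  int a, b;
  bool is_updated;
  double base[8];  // sorted neighbour values, pair members excluded
  int nb;          // how many base values
  int npair;       // usable neighbours that are the updated pair (0..2)
};

struct AffectedSet {
  AffectedCell cells[20];
  int n;
};

static void collect_affected(const MrfState& s, int i, int j, AffectedSet& A) {
  int ai[20], aj[20];
  int na = 0;
  auto add = [&](int a, int b) {
    if (a < 0 || b < 0 || a >= s.n || b >= s.n || !cell_ok(s, a, b)) return;
    for (int t = 0; t < na; ++t)
      if (ai[t] == a && aj[t] == b) return;
    ai[na] = a;
    aj[na] = b;
    ++na;
  };
  add(i, j);
  add(j, i);
  for (int di = -1; di <= 1; ++di) {
    for (int dj = -1; dj <= 1; ++dj) {
      if (di == 0 && dj == 0) continue;
      add(i + di, j + dj);
      add(j + di, i + dj);
    }
  }
  A.n = na;
  for (int t = 0; t < na; ++t) {
    AffectedCell& c = A.cells[t];
    c.a = ai[t];
    c.b = aj[t];
    c.is_updated = (c.a == i && c.b == j) || (c.a == j && c.b == i);
    c.nb = 0;
    c.npair = 0;
    for (int di = -1; di <= 1; ++di) {
      for (int dj = -1; dj <= 1; ++dj) {
        if (di == 0 && dj == 0) continue;
        const int p = c.a + di, q = c.b + dj;
        if (!neighbor_ok(s, c.a, c.b, p, q)) continue;
        if ((p == i && q == j) || (p == j && q == i)) {
          ++c.npair;
        } else {
          c.base[c.nb++] = s.F(p, q);
        }
      }
    }
    std::sort(c.base, c.base + c.nb);
  }
}

// rank-r element (0-based) of sorted base merged with npair copies of x
static inline double merged_at(const double* base, int nb, double x, int npair,
                               int r) {
  int ins = 0;
  while (ins < nb && base[ins] < x) ++ins;
  if (r < ins) return base[r];
  if (r < ins + npair) return x;
  return base[r - npair];
}

// all joint-probability terms that depend on the pair value, evaluated at
// candidate x using the precomputed affected set
static double affected_objective(const MrfState& s, const AffectedSet& A,
                                 double x) {
  double obj = 0.0;
  for (int t = 0; t < A.n; ++t) {
    const AffectedCell& c = A.cells[t];
    const int m = c.nb + c.npair;
    double med;
    if (m == 0) {
      med = -1.0;
    } else if (m % 2 == 1) {
      med = merged_at(c.base, c.nb, x, c.npair, m / 2);
    } else {
      med = 0.5 * (merged_at(c.base, c.nb, x, c.npair, m / 2 - 1) +
                   merged_at(c.base, c.nb, x, c.npair, m / 2));
    }
    const double v = c.is_updated ? x : s.F(c.a, c.b);
    obj += log_prior(s, v, med);
    if (c.is_updated) obj += log_lik(s, c.a, c.b, v);
  }
  return obj;
}

static double local_objective(const MrfState& s, int i, int j, double x) {
  AffectedSet A;
  collect_affected(s, i, j, A);
  return affected_objective(s, A, x);
}

static double joint_logp(const MrfState& s) {
  double lp = 0.0;
  for (int i = 0; i < s.n; ++i) {
    for (int j = 0; j < s.n; ++j) {
      if (!cell_ok(s, i, j)) continue;
      lp += log_prior(s, s.F(i, j), med_neigh(s, i, j, -1, -1, 0.0)) +
            log_lik(s, i, j, s.F(i, j));
    }
  }
  return lp;
}

// [[Rcpp::export]]
double cpp_mrf_local_objective(const NumericMatrix& F, const NumericMatrix& RC,
                               const NumericVector& bias,
                               const LogicalVector& fmask,
                               const LogicalMatrix& hb, const LogicalMatrix& vb,
                               int i, int j, double value, double alpha,
                               double vmult) {
  MrfState s{F, RC, bias, fmask, hb, vb, alpha, vmult, F.nrow()};
  return local_objective(s, i, j, value);
}

// [[Rcpp::export]]
double cpp_mrf_joint_logp(const NumericMatrix& F, const NumericMatrix& RC,
                          const NumericVector& bias,
                          const LogicalVector& fmask, const LogicalMatrix& hb,
                          const LogicalMatrix& vb, double alpha, double vmult) {
  MrfState s{F, RC, bias, fmask, hb, vb, alpha, vmult, F.nrow()};
  return joint_logp(s);
}

// [[Rcpp::export]]
List cpp_mrf_icm(NumericMatrix F, const NumericMatrix& RC,
                 const NumericVector& bias, const LogicalVector& fmask,
                 const LogicalMatrix& hb, const LogicalMatrix& vb,
                 const LogicalMatrix& updatable, const NumericVector& factors,
                 double alpha, double vmult, double tol, int max_iter,
                 const IntegerVector& order) {
  const int n = F.nrow();
  MrfState s{F, RC, bias, fmask, hb, vb, alpha, vmult, n};
  const int nf = factors.size();
  std::vector<double> logp;
  logp.push_back(joint_logp(s));
  int sweeps = 0;
  int skipped = 0;
  // Dirty-cell bookkeeping: a pair's objective landscape only depends on
  // values within Chebyshev distance 2 of either mirror cell, so a pair
  // whose dependency window saw no change in the previous sweep or so far in
  // the current one selects the same (unchanged) value again and can be
  // skipped exactly.
  std::vector<unsigned char> changed_prev((size_t)n * n, 1);
  std::vector<unsigned char> changed_cur((size_t)n * n, 0);
  auto window_dirty = [&](const std::vector<unsigned char>& flag, int i,
                          int j) {
    const int alo = std::max(0, i - 2), ahi = std::min(n - 1, i + 2);
    const int blo = std::max(0, j - 2), bhi = std::min(n - 1, j + 2);
    for (int b = blo; b <= bhi; ++b) {
      const unsigned char* col = flag.data() + (size_t)b * n;
      for (int a = alo; a <= ahi; ++a)
        if (col[a]) return true;
    }
    return false;
  };
  for (int it = 0; it < max_iter; ++it) {
    double delta = 0.0;
    std::fill(changed_cur.begin(), changed_cur.end(), 0);
    for (int k = 0; k < (int)order.size(); ++k) {
      const int cell = order[k];          // 0-based column-major linear index
      const int j = cell / n, i = cell % n;
      if (j < i) continue;                // one update per unordered pair
      if (!cell_ok(s, i, j) || !updatable(i, j)) continue;
      if (!window_dirty(changed_prev, i, j) &&
          !window_dirty(changed_cur, i, j) &&
          (i == j || (!window_dirty(changed_prev, j, i) &&
                      !window_dirty(changed_cur, j, i)))) {
        continue;  // objective unchanged since the cell's last evaluation
      }
      const double cur = F(i, j);
      AffectedSet A;
      collect_affected(s, i, j, A);
      const double cur_obj = affected_objective(s, A, cur);
      double best = cur, best_obj = cur_obj;
      for (int f = 0; f < nf; ++f) {
        if (factors[f] == 1.0) continue;
        const double cand = cur * factors[f];
        const double obj = affected_objective(s, A, cand);
        if (R_finite(obj) && obj > best_obj) {
          best_obj = obj;
          best = cand;
        }
      }
      if (!R_finite(cur_obj) && !R_finite(best_obj)) {
        ++skipped;  // non-finite everywhere: leave the cell alone
        continue;
      }
      if (best != cur) {
        F(i, j) = best;
        changed_cur[(size_t)j * n + i] = 1;
        if (i != j) {
          F(j, i) = best;
          changed_cur[(size_t)i * n + j] = 1;
        }
        delta += best_obj - cur_obj;  // all other joint terms are untouched
      }
    }
    ++sweeps;
    const double prev = logp.back();
    logp.push_back(prev + delta);
    changed_prev.swap(changed_cur);
    if (delta < tol * (std::fabs(prev) + 1e-12)) break;
  }
  return List::create(_["values"] = F, _["sweeps"] = sweeps,
                      _["skipped"] = skipped,
                      _["logp"] = NumericVector(logp.begin(), logp.end()),
                      _["final_logp"] = joint_logp(s));
}
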