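#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Sum-over-paths (Forward) computations for the two local pair-HMM
// topologies, in scaled linear arithmetic.  All quantities are probability
// ratios relative to the null alignment, built from the primed factors
// S' = exp(S/t), a' = exp(a/t), b' = exp(b/t).  Each dynamic-programming
// row is stored divided by exp(L_i); when a row's maximum exceeds 2^256 the
// row is renormalized and L grows.  Per-row totals are combined by
// log-sum-exp, so the returned log total is accurate even when the plain
// total overflows.

static const double RESCALE_AT = 1.157920892373162e77;  // 2^256

static double log_sum_exp(const std::vector<double>& v) {
  double mx = R_NegInf;
  for (double x : v) if (x > mx) mx = x;
  if (!std::isfinite(mx)) return mx;
  double s = 0.0;
  for (double x : v) if (std::isfinite(x)) s += std::exp(x - mx);
  return mx + std::log(s);
}

static inline double safe_log(double x) {
  return x > 0 ? std::log(x) : R_NegInf;
}

// Forward, topology A.  Matches feed from W = X + Y + Z + 1 (the +1 being a
// fresh local start at that cell); gap openings (a') feed from W, so either
// gap kind may follow the other and a run may be re-opened mid-run; gap
// extensions (b') feed from the same gap table.  The total over all
// distinguishable paths, relative to the null alignment, is sum_ij W'_ij.
// Returns log W' and log X' tables plus the log total.
// [[Rcpp::export]]
List cpp_forward_A(IntegerVector r, IntegerVector q, NumericMatrix Sp,
                   double apD, double bpD, double apI, double bpI) {
  const int m = r.size(), n = q.size();
  NumericMatrix lW(m + 1, n + 1), lX(m + 1, n + 1);
  std::vector<double> Wp(n + 1, 0.0), Yp(n + 1, 0.0);  // row i - 1
  std::vector<double> Wc(n + 1), Yc(n + 1), Zc(n + 1), Xc(n + 1);
  std::vector<double> rowlogs;
  double L = 0.0;                                      // row log-scale

  for (int i = 0; i <= m; ++i) {
    const double one = std::exp(-L);                   // scaled "+1"
    for (int j = 0; j <= n; ++j) {
      double x = 0.0, y = 0.0, z = 0.0;
      if (i >= 1)
        y = Wp[j] * apD + Yp[j] * bpD;
      if (j >= 1) {
        z = Wc[j - 1] * apI + Zc[j - 1] * bpI;
        if (i >= 1)
          x = Wp[j - 1] * Sp(r[i - 1] - 1, q[j - 1] - 1);
      }
      const double w = x + y + z + one;
      if (!std::isfinite(w))
        stop("numeric overflow in Forward at cell (%d, %d)", i, j);
      Xc[j] = x; Yc[j] = y; Zc[j] = z; Wc[j] = w;
      lW(i, j) = L + safe_log(w);
      lX(i, j) = L + safe_log(x);
    }
    double rowsum = 0.0, rowmax = 0.0;
    for (int j = 0; j <= n; ++j) {
      rowsum += Wc[j];
      if (Wc[j] > rowmax) rowmax = Wc[j];
    }
    rowlogs.push_back(L + safe_log(rowsum));
    if (rowmax > RESCALE_AT) {
      for (int j = 0; j <= n; ++j) { Wc[j] /= rowmax; Yc[j] /= rowmax; }
      L += std::log(rowmax);
    }
    std::swap(Wp, Wc); std::swap(Yp, Yc);
  }
  return List::create(_["log_total"] = log_sum_exp(rowlogs),
                      _["lW"] = lW, _["lX"] = lX);
}

// Adjoint (backward) pass mirroring the topology-A Forward: bW[i][j] is the
// summed ratio of every path suffix proceeding from cell (i, j) -- ending
// there (the 1 term), aligning the next pair, or opening either gap -- so
// that the summed ratio of all paths whose core aligns R_i with Q_j is
// X'[i][j] * bW[i][j].  Same per-row scaling, run bottom-right to top-left.
// Returns the log bW table.
// [[Rcpp::export]]
NumericMatrix cpp_backward_A(IntegerVector r, IntegerVector q,
                             NumericMatrix Sp, double apD, double bpD,
                             double apI, double bpI) {
  const int m = r.size(), n = q.size();
  NumericMatrix lbW(m + 1, n + 1);
  std::vector<double> Wn(n + 1, 0.0), Yn(n + 1, 0.0);  // row i + 1
  std::vector<double> Wc(n + 1), Yc(n + 1), Zc(n + 1);
  double L = 0.0;

  for (int i = m; i >= 0; --i) {
    const double one = std::exp(-L);
    for (int j = n; j >= 0; --j) {
      double w = one;
      if (i < m && j < n)
        w += Sp(r[i] - 1, q[j] - 1) * Wn[j + 1];       // bX == bW
      if (i < m)
        w += apD * Yn[j];
      if (j < n)
        w += apI * Zc[j + 1];
      if (!std::isfinite(w))
        stop("numeric overflow in Backward at cell (%d, %d)", i, j);
      Wc[j] = w;
      Yc[j] = w + (i < m ? bpD * Yn[j] : 0.0);
      Zc[j] = w + (j < n ? bpI * Zc[j + 1] : 0.0);
      lbW(i, j) = L + safe_log(w);
    }
    double rowmax = 0.0;
    for (int j = 0; j <= n; ++j) {
      double mx = std::max(Wc[j], std::max(Yc[j], Zc[j]));
      if (mx > rowmax) rowmax = mx;
    }
    if (rowmax > RESCALE_AT) {
      for (int j = 0; j <= n; ++j) { Wc[j] /= rowmax; Yc[j] /= rowmax; }
      L += std::log(rowmax);
    }
    std::swap(Wn, Wc); std::swap(Yn, Yc);
  }
  return lbW;
}

// Forward, topology B: the sum-product counterpart of the three-table
// maximum-score variant.  Local paths begin and end with an aligned pair
// (the fresh-start +1 enters the match recurrence), a deletion may follow
// only a match or a deletion, an insertion may follow anything, and a gap
// run extends only with b' (no mid-run re-opening) -- so exactly one path
// corresponds to one alignment.  Total = 1 (null) + sum_ij X'_ij.
// [[Rcpp::export]]
List cpp_forward_B(IntegerVector r, IntegerVector q, NumericMatrix Sp,
                   double apD, double bpD, double apI, double bpI) {
  const int m = r.size(), n = q.size();
  NumericMatrix lX(m + 1, n + 1);
  std::vector<double> Xp(n + 1, 0.0), Yp(n + 1, 0.0), Zp(n + 1, 0.0);
  std::vector<double> Xc(n + 1), Yc(n + 1), Zc(n + 1);
  std::vector<double> rowlogs;
  rowlogs.push_back(0.0);                              // the null path
  double L = 0.0;

  for (int i = 0; i <= m; ++i) {
    const double one = std::exp(-L);
    for (int j = 0; j <= n; ++j) {
      double x = 0.0, y = 0.0, z = 0.0;
      if (i >= 1)
        y = Xp[j] * apD + Yp[j] * bpD;
      if (j >= 1) {
        z = (Xc[j - 1] + Yc[j - 1]) * apI + Zc[j - 1] * bpI;
        if (i >= 1)
          x = (Xp[j - 1] + Yp[j - 1] + Zp[j - 1] + one) *
              Sp(r[i - 1] - 1, q[j - 1] - 1);
      }
      if (!std::isfinite(x) || !std::isfinite(y) || !std::isfinite(z))
        stop("numeric overflow in Forward at cell (%d, %d)", i, j);
      Xc[j] = x; Yc[j] = y; Zc[j] = z;
      lX(i, j) = L + safe_log(x);
    }
    double rowsum = 0.0, rowmax = 0.0;
    for (int j = 0; j <= n; ++j) {
      rowsum += Xc[j];
      double mx = std::max(Xc[j], std::max(Yc[j], Zc[j]));
      if (mx > rowmax) rowmax = mx;
    }
    rowlogs.push_back(L + safe_log(rowsum));
    if (rowmax > RESCALE_AT) {
      for (int j = 0; j <= n; ++j) {
        Xc[j] /= rowmax; Yc[j] /= rowmax; Zc[j] /= rowmax;
      }
      L += std::log(rowmax);
    }
    std::swap(Xp, Xc); std::swap(Yp, Yc); std::swap(Zp, Zc);
  }
  return List::create(_["log_total"] = log_sum_exp(rowlogs),
                      _["lX"] = lX);
}
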