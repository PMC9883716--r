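#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Maximum-score local alignment, variant with three tables X/Y/Z where X
// holds the best score for prefixes ending in an aligned pair.  Insertions
// may follow deletions but not vice versa (the two orders always score the
// same, so one suffices).  Gap convention: a + b*(k-1) for a length-k gap.
// r, q are 1-based alphabet indices; S is the substitution matrix.
// [[Rcpp::export]]
List cpp_align_algI(IntegerVector r, IntegerVector q, NumericMatrix S,
                    double aD, double bD, double aI, double bI) {
  const int m = r.size(), n = q.size();
  const double NI = R_NegInf;
  NumericMatrix X(m + 1, n + 1), Y(m + 1, n + 1), Z(m + 1, n + 1);
  for (int i = 0; i <= m; ++i) { X(i, 0) = 0; Y(i, 0) = NI; Z(i, 0) = NI; }
  for (int j = 0; j <= n; ++j) { X(0, j) = 0; Y(0, j) = NI; Z(0, j) = NI; }
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const double s = S(r[i - 1] - 1, q[j - 1] - 1);
      double d = std::max(std::max(X(i - 1, j - 1), Y(i - 1, j - 1)),
                          std::max(Z(i - 1, j - 1), 0.0));
      X(i, j) = d + s;
      Y(i, j) = std::max(X(i - 1, j) + aD, Y(i - 1, j) + bD);
      Z(i, j) = std::max(std::max(X(i, j - 1) + aI, Y(i, j - 1) + aI),
                         Z(i, j - 1) + bI);
      if (X(i, j) > best) best = X(i, j);
    }
  }
  return List::create(_["X"] = X, _["Y"] = Y, _["Z"] = Z,
                      _["best_score"] = best);
}

// Variant folding W = max(X, Y, Z, 0) into one table.  Identical optima to
// the X/Y/Z variant whenever aD <= bD and aI <= bI; when a > b this variant
// permits splitting one gap into several.
// [[Rcpp::export]]
List cpp_align_algII(IntegerVector r, IntegerVector q, NumericMatrix S,
                     double aD, double bD, double aI, double bI) {
  const int m = r.size(), n = q.size();
  const double NI = R_NegInf;
  NumericMatrix W(m + 1, n + 1), Y(m + 1, n + 1), Z(m + 1, n + 1);
  for (int i = 0; i <= m; ++i) { W(i, 0) = 0; Z(i, 0) = NI; Y(i, 0) = NI; }
  for (int j = 0; j <= n; ++j) { W(0, j) = 0; Y(0, j) = NI; Z(0, j) = NI; }
  // Y has entries in column 0 and Z in row 0 (gaps before any letter of the
  // other sequence); they never improve W but complete the tables
  for (int i = 1; i <= m; ++i)
    Y(i, 0) = std::max(W(i - 1, 0) + aD, Y(i - 1, 0) + bD);
  for (int j = 1; j <= n; ++j)
    Z(0, j) = std::max(W(0, j - 1) + aI, Z(0, j - 1) + bI);
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const double s = S(r[i - 1] - 1, q[j - 1] - 1);
      Y(i, j) = std::max(W(i - 1, j) + aD, Y(i - 1, j) + bD);
      Z(i, j) = std::max(W(i, j - 1) + aI, Z(i, j - 1) + bI);
      double w = std::max(std::max(W(i - 1, j - 1) + s, Y(i, j)),
                          std::max(Z(i, j), 0.0));
      W(i, j) = w;
      if (w > best) best = w;
    }
  }
  return List::create(_["W"] = W, _["Y"] = Y, _["Z"] = Z,
                      _["best_score"] = best);
}

// End-to-end affine-gap alignment, same a + b*(k-1) gap convention.
// Deletions and insertions may abut in either order; abutting gaps are
// separate gaps (each pays the first-gap score a).
// [[Rcpp::export]]
List cpp_align_global(IntegerVector r, IntegerVector q, NumericMatrix S,
                      double aD, double bD, double aI, double bI) {
  const int m = r.size(), n = q.size();
  const double NI = R_NegInf;
  NumericMatrix X(m + 1, n + 1), Y(m + 1, n + 1), Z(m + 1, n + 1);
  X(0, 0) = 0; Y(0, 0) = NI; Z(0, 0) = NI;
  for (int i = 1; i <= m; ++i) {
    X(i, 0) = NI; Z(i, 0) = NI;
    Y(i, 0) = aD + bD * (i - 1);
  }
  for (int j = 1; j <= n; ++j) {
    X(0, j) = NI; Y(0, j) = NI;
    Z(0, j) = aI + bI * (j - 1);
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const double s = S(r[i - 1] - 1, q[j - 1] - 1);
      X(i, j) = std::max(std::max(X(i - 1, j - 1), Y(i - 1, j - 1)),
                         Z(i - 1, j - 1)) + s;
      Y(i, j) = std::max(std::max(X(i - 1, j) + aD, Y(i - 1, j) + bD),
                         Z(i - 1, j) + aD);
      Z(i, j) = std::max(std::max(X(i, j - 1) + aI, Y(i, j - 1) + aI),
                         Z(i, j - 1) + bI);
    }
  }
  double sc = std::max(std::max(X(m, n), Y(m, n)), Z(m, n));
  return List::create(_["X"] = X, _["Y"] = Y, _["Z"] = Z,
                      _["best_score"] = sc);
}
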