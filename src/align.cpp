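// Dynamic-programming alignment kernels: exact three-state affine
// Needleman-Wunsch for sequence pairs, and the profile-profile merge
// used by the progressive MSA. Residues are passed as 1-based integer
// codes into the substitution matrix; 0 denotes a gap (profiles only).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_nw_affine(IntegerVector a, IntegerVector b, NumericMatrix S,
                   double go, double ge) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e18;
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix PM(n + 1, m + 1), PX(n + 1, m + 1), PY(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = X(i, j) = Y(i, j) = NEG; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) X(i, 0) = go + (i - 1) * ge;
  for (int j = 1; j <= m; ++j) Y(0, j) = go + (j - 1) * ge;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = S(a[i - 1] - 1, b[j - 1] - 1);
      // ties broken M > X > Y (diagonal > up > left)
      double c1 = M(i - 1, j - 1), c2 = X(i - 1, j - 1), c3 = Y(i - 1, j - 1);
      int w = (c2 > c1) ? ((c3 > c2) ? 3 : 2) : ((c3 > c1) ? 3 : 1);
      M(i, j) = ((w == 1) ? c1 : (w == 2) ? c2 : c3) + s;
      PM(i, j) = w;
      c1 = M(i - 1, j) + go; c2 = X(i - 1, j) + ge; c3 = Y(i - 1, j) + go;
      w = (c2 > c1) ? ((c3 > c2) ? 3 : 2) : ((c3 > c1) ? 3 : 1);
      X(i, j) = (w == 1) ? c1 : (w == 2) ? c2 : c3;
      PX(i, j) = w;
      c1 = M(i, j - 1) + go; c2 = X(i, j - 1) + go; c3 = Y(i, j - 1) + ge;
      w = (c2 > c1) ? ((c3 > c2) ? 3 : 2) : ((c3 > c1) ? 3 : 1);
      Y(i, j) = (w == 1) ? c1 : (w == 2) ? c2 : c3;
      PY(i, j) = w;
    }
  }
  double f1 = M(n, m), f2 = X(n, m), f3 = Y(n, m);
  int state = (f2 > f1) ? ((f3 > f2) ? 3 : 2) : ((f3 > f1) ? 3 : 1);
  double score = (state == 1) ? f1 : (state == 2) ? f2 : f3;
  std::vector<int> ops;  // 1 = diag, 2 = up (gap in b), 3 = left (gap in a)
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) { ops.push_back(3); --j; continue; }
    if (j == 0) { ops.push_back(2); --i; continue; }
    int prev = (state == 1) ? PM(i, j) : (state == 2) ? PX(i, j) : PY(i, j);
    if (state == 1) { ops.push_back(1); --i; --j; }
    else if (state == 2) { ops.push_back(2); --i; }
    else { ops.push_back(3); --j; }
    state = prev;
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = score, _["ops"] = wrap(ops));
}

// column score: mean substitution score over all non-gap residue pairs
static inline double col_score(const IntegerMatrix& A, const IntegerMatrix& B,
                               int ca, int cb, const NumericMatrix& S) {
  double tot = 0.0; int np = 0;
  for (int r = 0; r < A.nrow(); ++r) {
    int x = A(r, ca);
    if (x == 0) continue;
    for (int q = 0; q < B.nrow(); ++q) {
      int y = B(q, cb);
      if (y == 0) continue;
      tot += S(x - 1, y - 1); ++np;
    }
  }
  return np ? tot / np : 0.0;
}

// [[Rcpp::export]]
IntegerVector cpp_profile_align(IntegerMatrix A, IntegerMatrix B,
                                NumericMatrix S, double go, double ge) {
  const int n = A.ncol(), m = B.ncol();
  NumericMatrix D(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) { D(i, 0) = go + (i - 1) * ge; P(i, 0) = 2; }
  for (int j = 1; j <= m; ++j) { D(0, j) = go + (j - 1) * ge; P(0, j) = 3; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double gup = (P(i - 1, j) == 2) ? ge : go;
      double glf = (P(i, j - 1) == 3) ? ge : go;
      double c1 = D(i - 1, j - 1) + col_score(A, B, i - 1, j - 1, S);
      double c2 = D(i - 1, j) + gup;
      double c3 = D(i, j - 1) + glf;
      int w = (c2 > c1) ? ((c3 > c2) ? 3 : 2) : ((c3 > c1) ? 3 : 1);
      D(i, j) = (w == 1) ? c1 : (w == 2) ? c2 : c3;
      P(i, j) = w;
    }
  }
  std::vector<int> ops;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int w = (i == 0) ? 3 : (j == 0) ? 2 : P(i, j);
    ops.push_back(w);
    if (w == 1) { --i; --j; } else if (w == 2) { --i; } else { --j; }
  }
  std::reverse(ops.begin(), ops.end());
  return wrap(ops);
}
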