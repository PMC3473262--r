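#include <Rcpp.h>
using namespace Rcpp;

// Global alignment of two column series by affine-gap dynamic programming.
//
// S(i, j) is the (pre-computed) substitution score between column i of the
// first series and column j of the second.  A gap run of length k costs
// open + k * extend.  Ties are broken deterministically: match over a gap in
// the second series ("delete", consumes i) over a gap in the first
// ("insert", consumes j), both in the state choice and in the traceback.
//
// Returns two integer vectors of equal length over the merged columns:
// positive 1-based column indices, 0 where the series contributes a gap.
// [[Rcpp::export]]
List affine_dp_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e100;
  // open + extend is the cost of starting a run of length 1
  const double gop = gap_open + gap_extend, gext = gap_extend;

  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // X: gap in second series (consume i); Y: gap in first (consume j)
  IntegerMatrix tbM(n + 1, m + 1), tbX(n + 1, m + 1), tbY(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -(gap_open + i * gext);
    tbX(i, 0) = 1; // extend from X
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -(gap_open + j * gext);
    tbY(0, j) = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: diagonal move, best predecessor state (prefer M > X > Y)
      double s = S(i - 1, j - 1);
      double bm = M(i - 1, j - 1); int tm = 0;
      if (X(i - 1, j - 1) > bm) { bm = X(i - 1, j - 1); tm = 1; }
      if (Y(i - 1, j - 1) > bm) { bm = Y(i - 1, j - 1); tm = 2; }
      M(i, j) = bm + s; tbM(i, j) = tm;

      // X: consume i, gap in second series; open from M/Y or extend X
      double xo = M(i - 1, j) - gop; int tx = 0;
      if (X(i - 1, j) - gext >= xo) { xo = X(i - 1, j) - gext; tx = 1; }
      if (Y(i - 1, j) - gop > xo)   { xo = Y(i - 1, j) - gop; tx = 2; }
      X(i, j) = xo; tbX(i, j) = tx;

      // Y: consume j, gap in first series
      double yo = M(i, j - 1) - gop; int ty = 0;
      if (X(i, j - 1) - gop > yo)   { yo = X(i, j - 1) - gop; ty = 1; }
      if (Y(i, j - 1) - gext >= yo) { yo = Y(i, j - 1) - gext; ty = 2; }
      Y(i, j) = yo; tbY(i, j) = ty;
    }
  }

  // final state: prefer M > X > Y on ties
  double best = M(n, m); int state = 0;
  if (X(n, m) > best) { best = X(n, m); state = 1; }
  if (Y(n, m) > best) { best = Y(n, m); state = 2; }

  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tbM(i, j);
      ai.push_back(i); bi.push_back(j);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tbX(i, j);
      ai.push_back(i); bi.push_back(0);
      --i; state = prev;
    } else {
      int prev = tbY(i, j);
      ai.push_back(0); bi.push_back(j);
      --j; state = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());

  return List::create(_["score"] = best,
                      _["a"] = IntegerVector(ai.begin(), ai.end()),
                      _["b"] = IntegerVector(bi.begin(), bi.end()));
}
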