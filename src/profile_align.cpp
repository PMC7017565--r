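#include <Rcpp.h>
using namespace Rcpp;

// Gotoh affine-gap alignment of two alignment profiles.
// fa, fb: (nletters x ncol) column frequency matrices (gap rows score 0 via
// the zero rows of `sub`). sub: nletters x nletters expected-score matrix.
// Returns two integer vectors mapping merged columns to source columns
// (1-based; 0 = gap).
// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix fa, NumericMatrix fb, NumericMatrix sub,
                       double gap_open, double gap_extend) {
  const int na = fa.ncol(), nb = fb.ncol(), L = fa.nrow();
  const double NEG = -1e30;

  // expected substitution score for each column pair
  NumericMatrix s(na, nb);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j) {
      double v = 0.0;
      for (int a = 0; a < L; ++a) {
        if (fa(a, i) == 0.0) continue;
        double row = 0.0;
        for (int b = 0; b < L; ++b)
          if (fb(b, j) != 0.0) row += fb(b, j) * sub(a, b);
        v += fa(a, i) * row;
      }
      s(i, j) = v;
    }

  std::vector<std::vector<double>> M(na + 1, std::vector<double>(nb + 1, NEG));
  std::vector<std::vector<double>> X(na + 1, std::vector<double>(nb + 1, NEG));
  std::vector<std::vector<double>> Y(na + 1, std::vector<double>(nb + 1, NEG));
  M[0][0] = 0.0;
  for (int i = 1; i <= na; ++i) X[i][0] = -gap_open - gap_extend * i;
  for (int j = 1; j <= nb; ++j) Y[0][j] = -gap_open - gap_extend * j;

  for (int i = 1; i <= na; ++i) {
    for (int j = 1; j <= nb; ++j) {
      double prev = std::max(M[i - 1][j - 1],
                             std::max(X[i - 1][j - 1], Y[i - 1][j - 1]));
      M[i][j] = prev + s(i - 1, j - 1);
      X[i][j] = std::max(M[i - 1][j] - gap_open - gap_extend,
                         X[i - 1][j] - gap_extend);
      double yfromM = M[i][j - 1] - gap_open - gap_extend;
      Y[i][j] = std::max(yfromM, Y[i][j - 1] - gap_extend);
    }
  }

  // traceback from the best of the three states
  std::vector<int> pa, pb;
  int i = na, j = nb;
  int state; // 0=M,1=X,2=Y
  double best = M[na][nb]; state = 0;
  if (X[na][nb] > best) { best = X[na][nb]; state = 1; }
  if (Y[na][nb] > best) { best = Y[na][nb]; state = 2; }
  double score = best;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) { // boundary: only gap states reach here
        state = (i == 0) ? 2 : 1;
        continue;
      }
      pa.push_back(i); pb.push_back(j);
      double prevM = M[i - 1][j - 1], prevX = X[i - 1][j - 1],
             prevY = Y[i - 1][j - 1];
      double target = M[i][j] - s(i - 1, j - 1);
      --i; --j;
      if (std::fabs(prevM - target) < eps) state = 0;
      else if (std::fabs(prevX - target) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      pa.push_back(i); pb.push_back(0);
      double target = X[i][j];
      bool fromM = std::fabs(M[i - 1][j] - gap_open - gap_extend - target) < eps;
      --i;
      state = fromM ? 0 : 1;
    } else {
      pa.push_back(0); pb.push_back(j);
      double target = Y[i][j];
      bool fromM = std::fabs(M[i][j - 1] - gap_open - gap_extend - target) < eps;
      --j;
      state = fromM ? 0 : 2;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["a"] = wrap(pa), _["b"] = wrap(pb),
                      _["score"] = score);
}
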