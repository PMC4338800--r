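#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh) over a precomputed cell-score matrix,
// with position-specific gap-penalty weights.
//
// S(i, j) holds the score for pairing position i of sequence/profile A with
// position j of B; the caller is responsible for computing it (substitution
// matrix lookup for sequences, frequency-weighted expected score for
// profiles).  A gap of length L over uniform weight w costs
// (gap_open + L * gap_extend) * w (penalties passed as positive numbers).
//
// wA[i] / wB[j] weight the penalty of consuming position i of A / j of B
// opposite a gap.  For plain sequences both are 1 and the recursion is the
// textbook Gotoh.  For profiles the caller passes column occupancies
// (non-gap fractions), which makes gaps cheap inside regions that are
// already gap-rich — the position-specific gap penalties progressive
// aligners use to keep conserved blocks in register.
//
// Traceback tie-breaking is deterministic: on equal scores a
// match/mismatch step is preferred over a gap in A (consume B), which is
// preferred over a gap in B (consume A).  Returned path codes:
//   1 = diagonal (consume A and B)
//   2 = gap in A  (consume B only)
//   3 = gap in B  (consume A only)

// [[Rcpp::export(name = ".gotoh_path")]]
List gotoh_path(NumericMatrix S, double gap_open, double gap_extend,
                NumericVector wA, NumericVector wB) {
  const int n = S.nrow(), m = S.ncol();
  if (wA.size() != n || wB.size() != m)
    stop("gap-weight vectors must match the score matrix dimensions");
  const double NEG = -1e300;
  const double open1 = gap_open + gap_extend;  // first gapped column

  // state 0 = M (diagonal), 1 = X (gap in A), 2 = Y (gap in B)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix tbM(n + 1, m + 1), tbX(n + 1, m + 1), tbY(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; Y(0, j) = NEG;
    X(0, j) = (j == 1 ? 0.0 : X(0, j - 1)) -
      (j == 1 ? open1 : gap_extend) * wB[j - 1];
    tbX(0, j) = 1;
  }
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; X(i, 0) = NEG;
    Y(i, 0) = (i == 1 ? 0.0 : Y(i - 1, 0)) -
      (i == 1 ? open1 : gap_extend) * wA[i - 1];
    tbY(i, 0) = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M from (i-1, j-1); preference M > X > Y on ties
      double best = M(i - 1, j - 1); int arg = 0;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); arg = 1; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); arg = 2; }
      M(i, j) = best + S(i - 1, j - 1); tbM(i, j) = arg;

      // X (gap in A) from (i, j-1), weighted by B's column occupancy
      const double xo = open1 * wB[j - 1], xe = gap_extend * wB[j - 1];
      best = M(i, j - 1) - xo; arg = 0;
      if (X(i, j - 1) - xe > best) { best = X(i, j - 1) - xe; arg = 1; }
      if (Y(i, j - 1) - xo > best) { best = Y(i, j - 1) - xo; arg = 2; }
      X(i, j) = best; tbX(i, j) = arg;

      // Y (gap in B) from (i-1, j), weighted by A's column occupancy
      const double yo = open1 * wA[i - 1], ye = gap_extend * wA[i - 1];
      best = M(i - 1, j) - yo; arg = 0;
      if (X(i - 1, j) - yo > best) { best = X(i - 1, j) - yo; arg = 1; }
      if (Y(i - 1, j) - ye > best) { best = Y(i - 1, j) - ye; arg = 2; }
      Y(i, j) = best; tbY(i, j) = arg;
    }
  }

  double score = M(n, m); int st = 0;
  if (X(n, m) > score) { score = X(n, m); st = 1; }
  if (Y(n, m) > score) { score = Y(n, m); st = 2; }

  std::vector<int> rev;
  rev.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (st == 0)      { rev.push_back(1); st = tbM(i, j); --i; --j; }
    else if (st == 1) { rev.push_back(2); st = tbX(i, j); --j; }
    else              { rev.push_back(3); st = tbY(i, j); --i; }
  }
  IntegerVector path(rev.rbegin(), rev.rend());
  return List::create(_["score"] = score, _["path"] = path);
}
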