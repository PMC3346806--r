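#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap dynamic programming for sequence-to-structure alignment.
//
// Rows: query positions (1..nq). Columns: template positions (1..nt).
// Global in the template (every template column is aligned or gap-penalized),
// semi-global in the query (leading/trailing query residues are free).
// S(i,j) is the profile score for placing query residue i at template
// position j. Ties are broken toward diagonal > up (query-consuming) > left
// (template-consuming), which makes the traceback deterministic.
//
// [[Rcpp::export]]
List cs_align_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int nq = S.nrow(), nt = S.ncol();
  const double NEG = -1e30;
  // state matrices, (nq+1) x (nt+1)
  NumericMatrix M(nq + 1, nt + 1), X(nq + 1, nt + 1), Y(nq + 1, nt + 1);
  IntegerMatrix tbM(nq + 1, nt + 1), tbX(nq + 1, nt + 1), tbY(nq + 1, nt + 1);
  // traceback codes: 0=M, 1=Y(up), 2=X(left), -1 invalid

  for (int i = 0; i <= nq; ++i)
    for (int j = 0; j <= nt; ++j) {
      M(i, j) = X(i, j) = Y(i, j) = NEG;
      tbM(i, j) = tbX(i, j) = tbY(i, j) = -1;
    }
  M(0, 0) = 0.0;
  // leading query overhang: free (column 0)
  for (int i = 1; i <= nq; ++i) { Y(i, 0) = 0.0; tbY(i, 0) = 1; }
  // leading template gap: affine-penalized
  for (int j = 1; j <= nt; ++j) {
    double fromM = M(0, j - 1) - gap_open;
    double fromX = X(0, j - 1) - gap_extend;
    if (fromM >= fromX) { X(0, j) = fromM; tbX(0, j) = 0; }
    else               { X(0, j) = fromX; tbX(0, j) = 2; }
  }

  for (int i = 1; i <= nq; ++i) {
    for (int j = 1; j <= nt; ++j) {
      // M: align i with j; prefer diag source M > Y > X on ties
      double best = M(i - 1, j - 1); int src = 0;
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); src = 1; }
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); src = 2; }
      if (best > NEG / 2) { M(i, j) = best + S(i - 1, j - 1); tbM(i, j) = src; }

      // Y: query i unaligned (gap in template side); free at j == nt
      double yo = (j == nt) ? 0.0 : gap_open;
      double ye = (j == nt) ? 0.0 : gap_extend;
      best = M(i - 1, j) - yo; src = 0;
      if (Y(i - 1, j) - ye > best) { best = Y(i - 1, j) - ye; src = 1; }
      if (X(i - 1, j) - yo > best) { best = X(i - 1, j) - yo; src = 2; }
      if (best > NEG / 2) { Y(i, j) = best; tbY(i, j) = src; }

      // X: template j unaligned; always penalized (template is global)
      best = M(i, j - 1) - gap_open; src = 0;
      if (Y(i, j - 1) - gap_open > best) { best = Y(i, j - 1) - gap_open; src = 1; }
      if (X(i, j - 1) - gap_extend > best) { best = X(i, j - 1) - gap_extend; src = 2; }
      if (best > NEG / 2) { X(i, j) = best; tbX(i, j) = src; }
    }
  }

  // termination: prefer M > Y > X on ties
  double score = M(nq, nt); int state = 0;
  if (Y(nq, nt) > score) { score = Y(nq, nt); state = 1; }
  if (X(nq, nt) > score) { score = X(nq, nt); state = 2; }

  std::vector<int> qpos, tpos;
  int i = nq, j = nt;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int src = tbM(i, j);
      qpos.push_back(i); tpos.push_back(j);
      --i; --j; state = src;
      if (i == 0 && j == 0) break;
    } else if (state == 1) {
      int src = tbY(i, j);
      --i; state = src;
    } else {
      int src = tbX(i, j);
      --j; state = src;
    }
    if (i == 0 && j == 0) break;
  }
  std::reverse(qpos.begin(), qpos.end());
  std::reverse(tpos.begin(), tpos.end());
  return List::create(_["qpos"] = wrap(qpos), _["tpos"] = wrap(tpos),
                      _["score"] = score);
}
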