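#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps (Gotoh) over a
// precomputed column-pair score matrix C (nrow = columns of profile A,
// ncol = columns of profile B). Terminal gaps are penalized. Tie-breaking
// is fixed (match > gap-in-B > gap-in-A) so the traceback is deterministic.
//
// Returns list(score, a_idx, b_idx): 1-based column indices into A and B
// per alignment column, 0 marking a gap.
// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(NumericMatrix C, double gap_open, double gap_ext) {
  const int n = C.nrow(), m = C.ncol();
  const double NEG = -1e30;
  // state 0 = M (match), 1 = Ix (gap in B, consumes A), 2 = Iy (gap in A)
  std::vector<double> M((n + 1) * (m + 1), NEG), Ix(M), Iy(M);
  std::vector<signed char> pM(M.size()), pIx(M.size()), pIy(M.size());
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    Ix[at(i, 0)] = -gap_open - (i - 1) * gap_ext;
    pIx[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Iy[at(0, j)] = -gap_open - (j - 1) * gap_ext;
    pIy[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: diagonal from best of three
      double dM = M[at(i - 1, j - 1)], dIx = Ix[at(i - 1, j - 1)],
             dIy = Iy[at(i - 1, j - 1)];
      double best = dM; signed char p = 0;
      if (dIx > best) { best = dIx; p = 1; }
      if (dIy > best) { best = dIy; p = 2; }
      M[at(i, j)] = best + C(i - 1, j - 1);
      pM[at(i, j)] = p;
      // Ix: consume A column i with a gap in B
      double oM = M[at(i - 1, j)] - gap_open, oIx = Ix[at(i - 1, j)] - gap_ext;
      if (oM >= oIx) { Ix[at(i, j)] = oM; pIx[at(i, j)] = 0; }
      else           { Ix[at(i, j)] = oIx; pIx[at(i, j)] = 1; }
      // Iy: consume B column j with a gap in A
      double qM = M[at(i, j - 1)] - gap_open, qIy = Iy[at(i, j - 1)] - gap_ext;
      if (qM >= qIy) { Iy[at(i, j)] = qM; pIy[at(i, j)] = 0; }
      else           { Iy[at(i, j)] = qIy; pIy[at(i, j)] = 2; }
    }
  }

  double sM = M[at(n, m)], sIx = Ix[at(n, m)], sIy = Iy[at(n, m)];
  double score = sM; int state = 0;
  if (sIx > score) { score = sIx; state = 1; }
  if (sIy > score) { score = sIy; state = 2; }

  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int p = pM[at(i, j)];
      ai.push_back(i); bi.push_back(j);
      --i; --j; state = p;
    } else if (state == 1) {
      int p = pIx[at(i, j)];
      ai.push_back(i); bi.push_back(0);
      --i; state = p;
    } else {
      int p = pIy[at(i, j)];
      ai.push_back(0); bi.push_back(j);
      --j; state = p;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = score,
                      _["a_idx"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_idx"] = IntegerVector(bi.begin(), bi.end()));
}
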