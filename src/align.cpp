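#include <Rcpp.h>
using namespace Rcpp;

// Local (Smith-Waterman) alignment of a residue-coded sequence against a
// position-specific score matrix with affine gaps (Gotoh three-state DP).
// S: 20 x L profile scores (bits); seq: integer codes 1..20.
// A gap run of length k costs open + (k-1) * extend.
// Returns the optimal score and a deterministic traceback: col_map[i] is the
// 1-based profile column aligned to sequence position i (within the local
// window), 0 for an inserted (unaligned-within-window) residue, NA outside
// the window. Ties prefer, in order: diagonal (M), insertion (Ix), deletion
// (Iy); the end cell is the first maximum in row-major order.
// [[Rcpp::export(name = ".gotoh_local")]]
List gotoh_local(NumericMatrix S, IntegerVector seq,
                 double gap_open, double gap_extend) {
  const int n = seq.size();
  const int L = S.ncol();
  const double NEG = -1e30;
  // DP matrices (n+1) x (L+1)
  std::vector<double> M((n + 1) * (L + 1), NEG),
      Ix((n + 1) * (L + 1), NEG), Iy((n + 1) * (L + 1), NEG);
  auto at = [L](int i, int j) { return i * (L + 1) + j; };
  for (int j = 0; j <= L; ++j) { M[at(0, j)] = NEG; }
  double best = 0.0; int bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= L; ++j) {
      double sub = S(seq[i - 1] - 1, j - 1);
      double prev = 0.0;  // local: may start fresh
      if (M[at(i - 1, j - 1)] > prev) prev = M[at(i - 1, j - 1)];
      if (Ix[at(i - 1, j - 1)] > prev) prev = Ix[at(i - 1, j - 1)];
      if (Iy[at(i - 1, j - 1)] > prev) prev = Iy[at(i - 1, j - 1)];
      M[at(i, j)] = prev + sub;
      double ixo = M[at(i - 1, j)] - gap_open;
      double ixe = Ix[at(i - 1, j)] - gap_extend;
      Ix[at(i, j)] = ixo >= ixe ? ixo : ixe;
      double iyo = M[at(i, j - 1)] - gap_open;
      double iye = Iy[at(i, j - 1)] - gap_extend;
      Iy[at(i, j)] = iyo >= iye ? iyo : iye;
      if (M[at(i, j)] > best) { best = M[at(i, j)]; bi = i; bj = j; }
    }
  }
  IntegerVector col_map(n, NA_INTEGER);
  if (bi < 0) {  // nothing scores above 0: empty alignment
    return List::create(_["score"] = 0.0, _["col_map"] = col_map,
                        _["from"] = NA_INTEGER, _["to"] = NA_INTEGER,
                        _["col_from"] = NA_INTEGER, _["col_to"] = NA_INTEGER);
  }
  // traceback from (bi, bj), state M
  int i = bi, j = bj, state = 0;  // 0=M, 1=Ix, 2=Iy
  int from = bi, col_from = bj;
  const double eps = 1e-9;
  while (true) {
    if (state == 0) {
      col_map[i - 1] = j;
      from = i; col_from = j;
      double sub = S(seq[i - 1] - 1, j - 1);
      double need = M[at(i, j)] - sub;  // score carried in from predecessor
      if (need <= eps) break;  // local start
      if (std::abs(M[at(i - 1, j - 1)] - need) <= eps) state = 0;
      else if (std::abs(Ix[at(i - 1, j - 1)] - need) <= eps) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      col_map[i - 1] = 0;  // inserted residue
      if (std::abs(M[at(i - 1, j)] - gap_open - Ix[at(i, j)]) <= eps) state = 0;
      // else stay in Ix
      --i;
    } else {
      if (std::abs(M[at(i, j - 1)] - gap_open - Iy[at(i, j)]) <= eps) state = 0;
      --j;
    }
  }
  return List::create(_["score"] = best, _["col_map"] = col_map,
                      _["from"] = from, _["to"] = bi,
                      _["col_from"] = col_from, _["col_to"] = bj);
}
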