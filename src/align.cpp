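#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman-Gotoh).
// Gap of length L costs gap_open + L * gap_extend.
// a, b: 0-based integer codes indexing rows/cols of S.
// bmask: subject positions (0-based) excluded from any alignment
// (H/E/F forced to 0 there) -- used to report multiple
// non-overlapping alignments by iterative masking.
//
// Tie-breaking is deterministic: the end cell is the first maximum in
// row-major order, and traceback prefers diagonal > up (gap in b) >
// left (gap in a).

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerVector a, IntegerVector b, NumericMatrix S,
              double gap_open, double gap_extend, LogicalVector bmask) {
  const int m = a.size(), n = b.size();
  const double gopen1 = gap_open + gap_extend; // cost of first gapped position
  if (m == 0 || n == 0) {
    return List::create(_["score"] = 0.0,
                        _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0,
                        _["a_idx"] = IntegerVector(0),
                        _["b_idx"] = IntegerVector(0));
  }
  // DP matrices (m+1) x (n+1); trace codes: 0 stop, 1 diag, 2 up(F), 3 left(E)
  std::vector<double> H((m + 1) * (n + 1), 0.0);
  std::vector<double> E((m + 1) * (n + 1), R_NegInf);
  std::vector<double> F((m + 1) * (n + 1), R_NegInf);
  std::vector<unsigned char> TH((m + 1) * (n + 1), 0);
  std::vector<unsigned char> TE((m + 1) * (n + 1), 0); // 1 = opened here
  std::vector<unsigned char> TF((m + 1) * (n + 1), 0);
  const int W = n + 1;
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const int ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int idx = i * W + j;
      if (bmask[j - 1]) { H[idx] = 0.0; E[idx] = F[idx] = R_NegInf; TH[idx] = 0; continue; }
      // E: gap in a (consume b), i.e. move left
      double e_open = H[idx - 1] - gopen1;
      double e_ext  = E[idx - 1] - gap_extend;
      if (e_ext > e_open) { E[idx] = e_ext; TE[idx] = 0; }
      else { E[idx] = e_open; TE[idx] = 1; }
      // F: gap in b (consume a), i.e. move up
      double f_open = H[idx - W] - gopen1;
      double f_ext  = F[idx - W] - gap_extend;
      if (f_ext > f_open) { F[idx] = f_ext; TF[idx] = 0; }
      else { F[idx] = f_open; TF[idx] = 1; }
      double diag = H[idx - W - 1] + S(ai, b[j - 1]);
      // preference on ties: diag > up(F) > left(E) > stop
      double h = 0.0; unsigned char t = 0;
      if (E[idx] > h) { h = E[idx]; t = 3; }
      if (F[idx] >= h && F[idx] > 0.0) { h = F[idx]; t = 2; }
      if (diag >= h && diag > 0.0) { h = diag; t = 1; }
      H[idx] = h; TH[idx] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0,
                        _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0,
                        _["a_idx"] = IntegerVector(0),
                        _["b_idx"] = IntegerVector(0));
  }
  // traceback
  std::vector<int> ai_idx, bi_idx;
  int i = bi, j = bj;
  int state = 0; // 0 in H, 2 in F, 3 in E
  while (i > 0 && j > 0) {
    const int idx = i * W + j;
    if (state == 0) {
      unsigned char t = TH[idx];
      if (t == 0) break;
      if (t == 1) { ai_idx.push_back(i); bi_idx.push_back(j); --i; --j; }
      else state = t;
    } else if (state == 2) { // gap in b: consume a
      ai_idx.push_back(i); bi_idx.push_back(NA_INTEGER);
      unsigned char t = TF[idx]; --i;
      if (t == 1) state = 0;
    } else { // state == 3, gap in a: consume b
      ai_idx.push_back(NA_INTEGER); bi_idx.push_back(j);
      unsigned char t = TE[idx]; --j;
      if (t == 1) state = 0;
    }
  }
  std::reverse(ai_idx.begin(), ai_idx.end());
  std::reverse(bi_idx.begin(), bi_idx.end());
  int a_start = 0, b_start = 0;
  for (size_t k = 0; k < ai_idx.size(); ++k)
    if (ai_idx[k] != NA_INTEGER) { a_start = ai_idx[k]; break; }
  for (size_t k = 0; k < bi_idx.size(); ++k)
    if (bi_idx[k] != NA_INTEGER) { b_start = bi_idx[k]; break; }
  return List::create(_["score"] = best,
                      _["a_start"] = a_start, _["a_end"] = bi,
                      _["b_start"] = b_start, _["b_end"] = bj,
                      _["a_idx"] = wrap(ai_idx),
                      _["b_idx"] = wrap(bi_idx));
}
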