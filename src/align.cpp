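#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Ends-free (overlap) global alignment of two masked sequences over
// {A,C,G,T,N,R} with Gotoh affine gaps: match +1, base-base mismatch 0,
// N identical-or-not 0, R aligns only to R (large negative vs anything
// else), gap open/extension penalties as given. Returns the number of
// identical aligned positions (A/C/G/T/R matches; N-N is not counted) and
// the aligned span in each sequence, from which identity and coverage
// fractions are computed by the caller.

static inline int sub_score(char x, char y) {
  if (x == 'R' || y == 'R') return x == y ? 1 : -1000000;
  if (x == y && x != 'N') return 1;
  return 0;
}

// [[Rcpp::export]]
List masked_align(std::string a, std::string b, double gap_open,
                  double gap_ext) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0, _["matches"] = 0,
                        _["a_start"] = 1, _["a_end"] = 0,
                        _["b_start"] = 1, _["b_end"] = 0);
  const double NEG = -1e15;
  // H, E (gap in a: move along b), F (gap in b: move along a)
  std::vector<double> Hp(m + 1), H(m + 1), Ep(m + 1), E(m + 1),
      Fp(m + 1), F(m + 1);
  // traceback: 2 bits per matrix entry. th: 0 diag,1 from E,2 from F,
  // te: came from H(0)/E(1); tf: came from H(0)/F(1)
  std::vector<unsigned char> th((n + 1) * (m + 1)), te((n + 1) * (m + 1)),
      tf((n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) { Hp[j] = 0; Ep[j] = NEG; Fp[j] = NEG; }
  double best = NEG;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    H[0] = 0; E[0] = NEG; F[0] = NEG;
    const char ai = a[i - 1];
    unsigned char *thi = &th[(size_t)i * (m + 1)];
    unsigned char *tei = &te[(size_t)i * (m + 1)];
    unsigned char *tfi = &tf[(size_t)i * (m + 1)];
    for (int j = 1; j <= m; ++j) {
      // E: gap in a (consume b[j])
      double eh = H[j - 1] - gap_open, ee = E[j - 1] - gap_ext;
      if (ee > eh) { E[j] = ee; tei[j] = 1; } else { E[j] = eh; tei[j] = 0; }
      // F: gap in b (consume a[i])
      double fh = Hp[j] - gap_open, ff = Fp[j] - gap_ext;
      if (ff > fh) { F[j] = ff; tfi[j] = 1; } else { F[j] = fh; tfi[j] = 0; }
      double d = Hp[j - 1] + sub_score(ai, b[j - 1]);
      double h = d; unsigned char t = 0;
      if (E[j] > h) { h = E[j]; t = 1; }
      if (F[j] > h) { h = F[j]; t = 2; }
      H[j] = h; thi[j] = t;
    }
    if (H[m] > best) { best = H[m]; bi = i; bj = m; }
    std::swap(H, Hp); std::swap(E, Ep); std::swap(F, Fp);
  }
  for (int j = 0; j <= m; ++j)
    if (Hp[j] > best) { best = Hp[j]; bi = n; bj = j; }
  // traceback from (bi, bj) in state H until a free end
  int i = bi, j = bj, matches = 0, state = 0;
  int ai_end = bi, bj_end = bj, ai_start = bi + 1, bj_start = bj + 1;
  while (i > 0 && j > 0) {
    if (state == 0) {
      unsigned char t = th[(size_t)i * (m + 1) + j];
      if (t == 0) {
        if (sub_score(a[i - 1], b[j - 1]) == 1) ++matches;
        ai_start = i; bj_start = j;
        --i; --j;
      } else {
        state = (t == 1) ? 1 : 2;
      }
    } else if (state == 1) {
      unsigned char t = te[(size_t)i * (m + 1) + j];
      bj_start = j;
      --j;
      if (t == 0) state = 0;
    } else {
      unsigned char t = tf[(size_t)i * (m + 1) + j];
      ai_start = i;
      --i;
      if (t == 0) state = 0;
    }
  }
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["a_start"] = ai_start, _["a_end"] = ai_end,
                      _["b_start"] = bj_start, _["b_end"] = bj_end);
}
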