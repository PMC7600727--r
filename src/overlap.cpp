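#include <Rcpp.h>
using namespace Rcpp;

// Mismatch counts for every candidate innie overlap between the 3' end of
// read 1 and the 5' end of the reverse-complemented mate.
//
// a, b: integer-encoded bases (A=1, C=2, G=3, T=4, N=0) of read 1 and of
// revcomp(read 2). For overlap length L the suffix a[n1-L .. n1-1] is
// compared with the prefix b[0 .. L-1]; N (code 0) always counts as a
// mismatch. Returns counts for L = min_overlap .. min(n1, n2), in that
// order; a zero-length vector when min(n1, n2) < min_overlap.
// [[Rcpp::export]]
IntegerVector overlap_mismatch_counts(IntegerVector a, IntegerVector b,
                                      int min_overlap) {
  const int n1 = a.size(), n2 = b.size();
  const int lmax = n1 < n2 ? n1 : n2;
  if (lmax < min_overlap) return IntegerVector(0);
  IntegerVector out(lmax - min_overlap + 1);
  for (int L = min_overlap; L <= lmax; ++L) {
    const int off = n1 - L;
    int mm = 0;
    for (int j = 0; j < L; ++j) {
      const int x = a[off + j], y = b[j];
      if (x == 0 || y == 0 || x != y) ++mm;
    }
    out[L - min_overlap] = mm;
  }
  return out;
}
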