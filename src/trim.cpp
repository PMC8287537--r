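#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Semi-global (suffix-overlap) adapter scan, substitutions only.
// For each sequence, returns the 0-based start of the leftmost occurrence of
// the adapter -- a full internal occurrence, or an adapter prefix as the read
// suffix -- whose overlap is >= min_overlap and whose mismatch count is
// <= floor(max_error_rate * overlap). -1 when no acceptable occurrence.
// [[Rcpp::export(name = ".adapter_match_start")]]
IntegerVector adapter_match_start(CharacterVector seqs, std::string adapter,
                                  double max_error_rate, int min_overlap) {
  const int n = seqs.size();
  const int alen = (int) adapter.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    if (seqs[r] == NA_STRING) { out[r] = -1; continue; }
    const char *s = CHAR(STRING_ELT(seqs, r));
    const int len = (int) LENGTH(STRING_ELT(seqs, r));
    int hit = -1;
    for (int p = 0; p + min_overlap <= len; ++p) {
      const int ov = std::min(len - p, alen);
      if (ov < min_overlap) break;
      // small epsilon so e.g. 0.1 * 10 floors to 1, not 0
      const int max_err = (int) (max_error_rate * ov + 1e-9);
      int err = 0;
      bool ok = true;
      for (int i = 0; i < ov; ++i) {
        if (s[p + i] != adapter[i] && ++err > max_err) { ok = false; break; }
      }
      if (ok) { hit = p; break; }
    }
    out[r] = hit;
  }
  return out;
}

// 3'-end quality trimming by the running-sum rule: scanning from the 3' end,
// accumulate (threshold - phred); the kept length is the position that
// maximises the accumulated deficit (equivalently minimises the running
// quality sum). threshold 0 is the identity.
// [[Rcpp::export(name = ".quality_keep_length")]]
IntegerVector quality_keep_length(CharacterVector quals, int threshold,
                                  int offset = 33) {
  const int n = quals.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    if (quals[r] == NA_STRING) { out[r] = 0; continue; }
    const char *q = CHAR(STRING_ELT(quals, r));
    const int len = (int) LENGTH(STRING_ELT(quals, r));
    long s = 0, best = 0;
    int stop = len;
    for (int i = len - 1; i >= 0; --i) {
      s += threshold - ((int) q[i] - offset);
      if (s < 0) break;
      if (s > best) { best = s; stop = i; }
    }
    out[r] = stop;
  }
  return out;
}
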