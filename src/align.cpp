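#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Smith-Waterman local alignment with linear (per-base) gap penalty and
// full traceback. Bases are encoded A=0, C=1, G=2, T=3, N=4; any pair
// involving N scores as a mismatch.
//
// Tie-breaking is deterministic: diagonal (match/mismatch) is preferred
// over a query gap, which is preferred over a text gap; among equal-score
// cells the first one in row-major order (smallest query end, then
// smallest text end) is chosen, which yields the earliest-starting path.
//
// Path alphabet: M match, X mismatch, I query base unaligned (insertion
// relative to the text), D text base skipped (deletion in the query).
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector t,
                  int match, int mismatch, int gap) {
  const int n = q.size(), m = t.size();
  const int w = m + 1;
  std::vector<int> H((size_t)(n + 1) * w, 0);
  std::vector<unsigned char> TB((size_t)(n + 1) * w, 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int qi = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int tj = t[j - 1];
      const int s = (qi == 4 || tj == 4 || qi != tj) ? mismatch : match;
      int v = H[(size_t)(i - 1) * w + (j - 1)] + s;  // diagonal
      unsigned char tb = 1;
      const int u = H[(size_t)(i - 1) * w + j] + gap;  // consume query base
      if (u > v) { v = u; tb = 2; }
      const int l = H[(size_t)i * w + (j - 1)] + gap;  // consume text base
      if (l > v) { v = l; tb = 3; }
      if (v <= 0) { v = 0; tb = 0; }
      H[(size_t)i * w + j] = v;
      TB[(size_t)i * w + j] = tb;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  std::string path;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    const unsigned char tb = TB[(size_t)i * w + j];
    if (tb == 0) break;
    if (tb == 1) {
      const bool is_match = (q[i - 1] == t[j - 1] && q[i - 1] != 4);
      path.push_back(is_match ? 'M' : 'X');
      --i; --j;
    } else if (tb == 2) {
      path.push_back('I');
      --i;
    } else {
      path.push_back('D');
      --j;
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(
    _["score"] = best,
    _["q_start"] = i,    // 0-based inclusive start in query
    _["q_end"] = bi,     // 0-based exclusive end
    _["t_start"] = j,
    _["t_end"] = bj,
    _["path"] = path);
}
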