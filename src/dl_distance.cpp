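#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Damerau-Levenshtein distance, optimal-string-alignment variant:
// unit-cost insertions, deletions, substitutions and adjacent
// transpositions; a transposed pair is not edited again.
static int dl_pair(const std::string& a, const std::string& b) {
  const int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev2(m + 1), prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int best = std::min(std::min(prev[j] + 1, cur[j - 1] + 1),
                          prev[j - 1] + cost);
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        best = std::min(best, prev2[j - 2] + 1);
      cur[j] = best;
    }
    std::swap(prev2, prev);
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
IntegerVector dl_distance_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  if (a.size() != n && a.size() != 1)
    stop("length mismatch: arguments must be equal length or length 1");
  if (b.size() != n && b.size() != 1)
    stop("length mismatch: arguments must be equal length or length 1");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    String sa = a[a.size() == 1 ? 0 : i];
    String sb = b[b.size() == 1 ? 0 : i];
    if (sa == NA_STRING || sb == NA_STRING) {
      out[i] = NA_INTEGER;
    } else {
      out[i] = dl_pair(std::string(sa.get_cstring()),
                       std::string(sb.get_cstring()));
    }
  }
  return out;
}
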