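#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Longest common subsequence over integer code-point vectors.
// Two-row DP: O(n*m) time, O(m) memory; length only.
// [[Rcpp::export]]
int lcs_length_int(IntegerVector a, IntegerVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      cur[j] = (ai == b[j - 1]) ? prev[j - 1] + 1
                                : std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Full-matrix DP with backtrack: returns 1-based indices of the reference
// (a) characters that participate in one maximal common subsequence.
// Memory guard is enforced on the R side (banded fallback for long units).
// [[Rcpp::export]]
IntegerVector lcs_match_ref_int(IntegerVector a, IntegerVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return IntegerVector(0);
  std::vector<int> d((size_t)(n + 1) * (m + 1), 0);
  const size_t W = m + 1;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j)
      d[i * W + j] = (a[i - 1] == b[j - 1])
        ? d[(i - 1) * W + (j - 1)] + 1
        : std::max(d[(i - 1) * W + j], d[i * W + (j - 1)]);
  std::vector<int> keep;
  int i = n, j = m;
  while (i > 0 && j > 0) {
    if (a[i - 1] == b[j - 1]) { keep.push_back(i); --i; --j; }
    else if (d[(i - 1) * W + j] >= d[i * W + (j - 1)]) --i;
    else --j;
  }
  std::reverse(keep.begin(), keep.end());
  return wrap(keep);
}

// Banded LCS length approximation for very long strings: only cells with
// |i - j| <= band are evaluated (lower bound on the true LCS length).
// [[Rcpp::export]]
int lcs_length_banded_int(IntegerVector a, IntegerVector b, int band) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    const int lo = std::max(1, i - band), hi = std::min(m, i + band);
    cur[lo - 1] = (lo > 1) ? prev[lo - 1] : 0;
    for (int j = lo; j <= hi; ++j) {
      cur[j] = (ai == b[j - 1]) ? prev[j - 1] + 1
                                : std::max(prev[j], cur[j - 1]);
    }
    for (int j = hi + 1; j <= m; ++j) cur[j] = cur[hi];
    std::swap(prev, cur);
  }
  return prev[m];
}
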