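#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Global Needleman-Wunsch alignment: match +1, mismatch -1, gap -2, with
// terminal gaps penalised like any other gap. Identity = matched columns /
// counted columns, where any column containing 'N' is excluded from both
// numerator and denominator: the single-N spacer used when joining read
// pairs must not penalise otherwise identical sequences.
//
// Terminal gaps are deliberately NOT free: with free end gaps and
// end-gap columns excluded from the identity denominator, a short perfect
// dovetail overlap between two unrelated sequences would score identity
// 1.0 and collapse distinct clusters. The pipeline's joined reads share a
// fixed length, so penalised end gaps cost nothing on real comparisons.

// [[Rcpp::export(name = ".nw_identity_cpp")]]
double nw_identity_cpp(std::string a, std::string b) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) return 0.0;

  const int MATCH = 1, MISMATCH = -1, GAP = -2;
  std::vector<int> H((size_t)(m + 1) * (n + 1), 0);
  // traceback: 1 = diag, 2 = up (gap in b), 3 = left (gap in a)
  std::vector<unsigned char> T((size_t)(m + 1) * (n + 1), 0);
  auto idx = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

  for (int i = 1; i <= m; ++i) { H[idx(i, 0)] = GAP * i; T[idx(i, 0)] = 2; }
  for (int j = 1; j <= n; ++j) { H[idx(0, j)] = GAP * j; T[idx(0, j)] = 3; }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int s = (a[i - 1] == b[j - 1]) ? MATCH : MISMATCH;
      int diag = H[idx(i - 1, j - 1)] + s;
      int up = H[idx(i - 1, j)] + GAP;
      int left = H[idx(i, j - 1)] + GAP;
      int best = diag; unsigned char ptr = 1;
      if (up > best) { best = up; ptr = 2; }
      if (left > best) { best = left; ptr = 3; }
      H[idx(i, j)] = best;
      T[idx(i, j)] = ptr;
    }
  }

  long matches = 0, cols = 0;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    unsigned char ptr = T[idx(i, j)];
    if (ptr == 1) {
      char ca = a[i - 1], cb = b[j - 1];
      if (ca != 'N' && cb != 'N') {
        ++cols;
        if (ca == cb) ++matches;
      }
      --i; --j;
    } else if (ptr == 2) {
      if (a[i - 1] != 'N') ++cols;  // gap column: counted, never a match
      --i;
    } else {
      if (b[j - 1] != 'N') ++cols;
      --j;
    }
  }

  if (cols == 0) return 0.0;
  return (double)matches / (double)cols;
}

// [[Rcpp::export(name = ".nw_identity_many_cpp")]]
NumericVector nw_identity_many_cpp(std::string query, CharacterVector targets) {
  const int k = targets.size();
  NumericVector out(k);
  for (int t = 0; t < k; ++t)
    out[t] = nw_identity_cpp(query, std::string(targets[t]));
  return out;
}
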