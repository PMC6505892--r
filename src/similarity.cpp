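#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment score with linear gap cost.
static int swScore(const std::string& a, const std::string& b,
                   int match, int mismatch, int gap) {
  const int m = b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0;
  for (size_t i = 1; i <= a.size(); ++i) {
    cur[0] = 0;
    const char ca = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      int v = prev[j - 1] + (ca == b[j - 1] ? match : mismatch);
      if (prev[j] + gap > v) v = prev[j] + gap;
      if (cur[j - 1] + gap > v) v = cur[j - 1] + gap;
      if (v < 0) v = 0;
      cur[j] = v;
      if (v > best) best = v;
    }
    std::swap(prev, cur);
  }
  return best;
}

// [[Rcpp::export(name = ".meanPairwiseLocalScores")]]
NumericVector meanPairwiseLocalScores(CharacterVector seqs,
                                      int match = 1, int mismatch = -1,
                                      int gap = -2) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  NumericVector tot(n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const int sc = swScore(s[i], s[j], match, mismatch, gap);
      tot[i] += sc;
      tot[j] += sc;
    }
    Rcpp::checkUserInterrupt();
  }
  if (n > 1)
    for (int i = 0; i < n; ++i) tot[i] /= (n - 1);
  return tot;
}
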