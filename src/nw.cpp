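#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global alignment score, linear gap penalty, two-row DP.
static double nw_pair(const std::string& a, const std::string& b,
                      double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j * gap;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      double diag = prev[j - 1] + (ai == b[j - 1] ? match : mismatch);
      double up = prev[j] + gap;
      double left = cur[j - 1] + gap;
      double best = diag > up ? diag : up;
      cur[j] = best > left ? best : left;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
double nw_score_cpp(std::string a, std::string b, double match,
                    double mismatch, double gap) {
  return nw_pair(a, b, match, mismatch, gap);
}

// All unordered pairs including self-alignments; symmetric result.
// [[Rcpp::export]]
NumericMatrix nw_score_matrix_cpp(CharacterVector seqs, double match,
                                  double mismatch, double gap) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double v = nw_pair(s[i], s[j], match, mismatch, gap);
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}
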