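#include <Rcpp.h>
using namespace Rcpp;

// Length of the longest common subsequence of two strings.
// Classic two-row dynamic programme, O(nm) time, O(m) memory.
// [[Rcpp::export]]
int cpp_lcs_length(const std::string& a, const std::string& b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (a[i - 1] == b[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Mean pairwise match-only global-alignment identity (percent) over all
// unordered pairs of sequences. Identity of a pair = matches / alignment
// columns where the alignment maximises matches with zero mismatch/gap
// penalty and pairs residues only when they match, i.e.
// 100 * L / (na + nb - L) with L the LCS length.
// [[Rcpp::export]]
double cpp_mean_pairwise_lcs_identity(const CharacterVector& seqs) {
  const int n = seqs.size();
  if (n < 2) return NA_REAL;
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  double tot = 0.0; int k = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double L = cpp_lcs_length(s[i], s[j]);
      double cols = (double)s[i].size() + (double)s[j].size() - L;
      tot += (cols > 0) ? 100.0 * L / cols : 100.0;
      ++k;
    }
  }
  return tot / k;
}

// Smith-Waterman local alignment with linear gap penalty and full
// traceback. Scores: match +1, mismatch `mismatch`, gap `gap`
// (both negative). Returns the single best-scoring local alignment.
// [[Rcpp::export]]
List cpp_sw_align(const std::string& q, const std::string& s,
                  double match = 1.0, double mismatch = -2.0,
                  double gap = -3.0) {
  const int n = q.size(), m = s.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0);
  // H: (n+1) x (m+1) score matrix, tb: traceback 0=stop,1=diag,2=up(gap in s),3=left(gap in q)
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<unsigned char> tb((n + 1) * (m + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int idx = i * (m + 1) + j;
      double diag = H[(i - 1) * (m + 1) + (j - 1)] +
        ((q[i - 1] == s[j - 1]) ? match : mismatch);
      double up = H[(i - 1) * (m + 1) + j] + gap;
      double left = H[i * (m + 1) + (j - 1)] + gap;
      double v = diag; unsigned char t = 1;
      if (up > v) { v = up; t = 2; }
      if (left > v) { v = left; t = 3; }
      if (v <= 0) { v = 0.0; t = 0; }
      H[idx] = v; tb[idx] = t;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0.0);
  int i = bi, j = bj, matches = 0, mm = 0, gaps = 0, cols = 0;
  while (i > 0 && j > 0) {
    unsigned char t = tb[i * (m + 1) + j];
    if (t == 0) break;
    ++cols;
    if (t == 1) {
      if (q[i - 1] == s[j - 1]) ++matches; else ++mm;
      --i; --j;
    } else if (t == 2) { ++gaps; --i; }
    else { ++gaps; --j; }
  }
  return List::create(
    _["score"] = best,
    _["q_start"] = i + 1, _["q_end"] = bi,
    _["s_start"] = j + 1, _["s_end"] = bj,
    _["matches"] = matches, _["mismatches"] = mm,
    _["gaps"] = gaps, _["columns"] = cols);
}
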