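#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Longest matching block between a[alo, ahi) and b[blo, bhi).
// Among blocks of maximal length the first found wins (scan order:
// ascending end position in a, then in b), a fixed documented tie rule.
static void longest_match(const std::string& a, int alo, int ahi,
                          const std::string& b, int blo, int bhi,
                          int& bi, int& bj, int& bk) {
  bi = alo; bj = blo; bk = 0;
  const int nb = bhi - blo;
  if (nb <= 0 || ahi - alo <= 0) return;
  std::vector<int> j2len(nb, 0);   // match length ending at (i-1, j)
  std::vector<int> newj2len(nb, 0);
  for (int i = alo; i < ahi; ++i) {
    std::fill(newj2len.begin(), newj2len.end(), 0);
    for (int j = blo; j < bhi; ++j) {
      if (a[i] == b[j]) {
        const int prev = (j > blo) ? j2len[j - blo - 1] : 0;
        const int len = prev + 1;
        newj2len[j - blo] = len;
        if (len > bk) { bk = len; bi = i - len + 1; bj = j - len + 1; }
      }
    }
    j2len.swap(newj2len);
  }
}

// Total characters in recursively found longest matching blocks
// (Ratcliff-Obershelp M).
static int matching_chars(const std::string& a, int alo, int ahi,
                          const std::string& b, int blo, int bhi) {
  int bi, bj, bk;
  longest_match(a, alo, ahi, b, blo, bhi, bi, bj, bk);
  if (bk == 0) return 0;
  return bk + matching_chars(a, alo, bi, b, blo, bj)
            + matching_chars(a, bi + bk, ahi, b, bj + bk, bhi);
}

// Ratcliff-Obershelp similarity ratio 2M / (|a| + |b|).
// [[Rcpp::export]]
double rcpp_similarity(std::string a, std::string b) {
  if (a.size() + b.size() == 0) return 1.0;
  const int m = matching_chars(a, 0, (int)a.size(), b, 0, (int)b.size());
  return 2.0 * m / (double)(a.size() + b.size());
}

// One query against many candidates.
// [[Rcpp::export]]
NumericVector rcpp_similarity_many(std::string query, CharacterVector candidates) {
  const int n = candidates.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = rcpp_similarity(query, as<std::string>(candidates[i]));
  return out;
}
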