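#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Watson-Crick + GU wobble over the DNA alphabet (T plays U's role).
static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// Base-pair maximisation with a hairpin-loop minimum (j - i > min_loop),
// nested structures only. Traceback is deterministic: pairing (i, j) is
// preferred over bifurcation on ties, and the smallest split point wins.
// [[Rcpp::export]]
IntegerMatrix nussinov_pairs(std::string seq, int min_loop) {
  int n = seq.size();
  if (n < 1) return IntegerMatrix(0, 2);
  std::vector<std::vector<int>> M(n + 2, std::vector<int>(n + 2, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 1; i + span <= n; ++i) {
      int j = i + span;
      int best = 0;
      if (can_pair(seq[i - 1], seq[j - 1]))
        best = 1 + M[i + 1][j - 1];
      for (int k = i; k < j; ++k) {
        int v = M[i][k] + M[k + 1][j];
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }
  std::vector<std::pair<int, int>> pairs;
  std::vector<std::pair<int, int>> todo;
  todo.push_back(std::make_pair(1, n));
  while (!todo.empty()) {
    int i = todo.back().first, j = todo.back().second;
    todo.pop_back();
    if (i >= j || M[i][j] == 0) continue;
    if (j - i > min_loop && can_pair(seq[i - 1], seq[j - 1]) &&
        M[i][j] == 1 + M[i + 1][j - 1]) {
      pairs.push_back(std::make_pair(i, j));
      todo.push_back(std::make_pair(i + 1, j - 1));
      continue;
    }
    for (int k = i; k < j; ++k) {
      if (M[i][k] + M[k + 1][j] == M[i][j]) {
        todo.push_back(std::make_pair(i, k));
        todo.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }
  IntegerMatrix out(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    out(r, 0) = pairs[r].first;
    out(r, 1) = pairs[r].second;
  }
  return out;
}
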