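#include <Rcpp.h>
#include <array>
using namespace Rcpp;

// Maximum-score pseudoknot-free folding (Nussinov-style DP with a
// stacking bonus). pair_score: 4x4 matrix indexed by A,C,G,U codes;
// a zero entry means the two bases cannot pair. A pair (i,j) requires
// j - i > min_loop. Tie-breaking in the traceback prefers pairing the
// leftmost available base, with the smallest partner.
//
// S(i,j): best score on [i,j]. P(i,j): best score on [i,j] given i-j
// paired. P(i,j) = score(i,j) + max(S(i+1,j-1), P(i+1,j-1) + stack).
// S(i,j) = max(S(i+1,j), max_k { P(i,k) + S(k+1,j) }).

// [[Rcpp::export]]
List nussinov_cpp(IntegerVector seq, int min_loop, NumericMatrix pair_score,
                  double stack_bonus) {
  int n = seq.size();
  NumericMatrix S(n, n), P(n, n);
  std::fill(P.begin(), P.end(), -1.0);

  for (int len = min_loop + 1; len < n; len++) {
    for (int i = 0; i + len < n; i++) {
      int j = i + len;
      double pr = pair_score(seq[i], seq[j]);
      if (pr > 0.0) {
        double inner = (j - i >= 2) ? S(i + 1, j - 1) : 0.0;
        double st = -1.0;
        if (j - 1 - (i + 1) > min_loop && P(i + 1, j - 1) >= 0.0)
          st = P(i + 1, j - 1) + stack_bonus;
        P(i, j) = pr + ((st > inner) ? st : inner);
      }
      double best = S(i + 1, j);  // i unpaired
      for (int k = i + min_loop + 1; k <= j; k++) {
        if (P(i, k) >= 0.0) {
          double c = P(i, k) + ((k < j) ? S(k + 1, j) : 0.0);
          if (c > best) best = c;
        }
      }
      S(i, j) = best;
    }
  }

  // traceback
  std::vector<int> pi, pj;
  std::vector<std::array<int, 3>> stack;  // (i, j, in_P)
  stack.push_back({0, n - 1, 0});
  const double eps = 1e-9;
  while (!stack.empty()) {
    auto fr = stack.back();
    stack.pop_back();
    int i = fr[0], j = fr[1];
    if (i >= j || j - i <= min_loop) continue;
    if (fr[2] == 1) {
      // (i, j) paired; decide inner expansion
      pi.push_back(i + 1);
      pj.push_back(j + 1);
      double pr = pair_score(seq[i], seq[j]);
      double rem = P(i, j) - pr;
      bool stackable = (j - 1 - (i + 1) > min_loop && P(i + 1, j - 1) >= 0.0);
      if (stackable && std::abs(P(i + 1, j - 1) + stack_bonus - rem) < eps)
        stack.push_back({i + 1, j - 1, 1});
      else if (j - i >= 2)
        stack.push_back({i + 1, j - 1, 0});
      continue;
    }
    // S frame: prefer pairing i, smallest partner k first
    bool done = false;
    for (int k = i + min_loop + 1; k <= j && !done; k++) {
      if (P(i, k) < 0.0) continue;
      double c = P(i, k) + ((k < j) ? S(k + 1, j) : 0.0);
      if (std::abs(c - S(i, j)) < eps) {
        stack.push_back({i, k, 1});
        if (k < j) stack.push_back({k + 1, j, 0});
        done = true;
      }
    }
    if (!done) stack.push_back({i + 1, j, 0});
  }

  IntegerMatrix pairs(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); k++) {
    pairs(k, 0) = pi[k];
    pairs(k, 1) = pj[k];
  }
  return List::create(_["score"] = (n > 1) ? S(0, n - 1) : 0.0,
                      _["pairs"] = pairs);
}
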