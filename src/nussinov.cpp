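#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// pair weight: G-C, A-U, G-U; 0 = cannot pair
static inline int pair_weight(char a, char b, int wGC, int wAU, int wGU) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return wGC;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return wAU;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return wGU;
  return 0;
}

// Weighted Nussinov maximum-pairing DP with deterministic traceback.
// Recurrence on [i,j]:
//   N(i,j) = max( pair(i,j): N(i+1,j-1) + w(i,j)   [if j-i > min_loop]
//               , N(i+1,j)                         [i unpaired]
//               , N(i,j-1)                         [j unpaired]
//               , max_k N(i,k) + N(k+1,j) )        [bifurcation]
// Ties resolved in that order; bifurcation prefers the largest split k.
// [[Rcpp::export]]
List nussinov_fold(std::string seq, int min_loop = 3,
                   int wGC = 3, int wAU = 2, int wGU = 1) {
  int n = seq.size();
  for (int i = 0; i < n; ++i) {
    char c = seq[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'U')
      stop("fold: sequence contains non-ACGU characters");
  }
  if (n == 0) {
    return List::create(_["structure"] = "", _["score"] = 0,
                        _["pairs"] = IntegerMatrix(0, 2));
  }
  std::vector<std::vector<int> > N(n, std::vector<int>(n, 0));
  for (int span = 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = N[i + 1][j];
      if (N[i][j - 1] > best) best = N[i][j - 1];
      if (j - i > min_loop) {
        int w = pair_weight(seq[i], seq[j], wGC, wAU, wGU);
        if (w > 0) {
          int v = (i + 1 <= j - 1 ? N[i + 1][j - 1] : 0) + w;
          if (v > best) best = v;
        }
      }
      for (int k = i; k < j; ++k) {
        int v = N[i][k] + N[k + 1][j];
        if (v > best) best = v;
      }
      N[i][j] = best;
    }
  }
  // iterative traceback
  std::string db(n, '.');
  std::vector<std::pair<int,int> > stackv, pairs;
  stackv.push_back(std::make_pair(0, n - 1));
  while (!stackv.empty()) {
    int i = stackv.back().first, j = stackv.back().second;
    stackv.pop_back();
    if (i >= j) continue;
    int target = N[i][j];
    if (target == 0) continue;
    if (j - i > min_loop) {
      int w = pair_weight(seq[i], seq[j], wGC, wAU, wGU);
      if (w > 0 && (i + 1 <= j - 1 ? N[i + 1][j - 1] : 0) + w == target) {
        db[i] = '('; db[j] = ')';
        pairs.push_back(std::make_pair(i + 1, j + 1));
        stackv.push_back(std::make_pair(i + 1, j - 1));
        continue;
      }
    }
    if (N[i + 1][j] == target) {
      stackv.push_back(std::make_pair(i + 1, j));
      continue;
    }
    if (N[i][j - 1] == target) {
      stackv.push_back(std::make_pair(i, j - 1));
      continue;
    }
    bool done = false;
    for (int k = j - 1; k > i && !done; --k) {
      if (N[i][k] + N[k + 1][j] == target) {
        stackv.push_back(std::make_pair(i, k));
        stackv.push_back(std::make_pair(k + 1, j));
        done = true;
      }
    }
    if (!done) stop("fold: traceback failed (internal error)");
  }
  IntegerMatrix pm(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    pm(r, 0) = pairs[r].first;
    pm(r, 1) = pairs[r].second;
  }
  return List::create(_["structure"] = db, _["score"] = N[0][n - 1],
                      _["pairs"] = pm);
}
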