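#include <Rcpp.h>
#include <string>
#include <vector>

// Maximum base-pairing secondary structure (Nussinov recursion) over
// Watson-Crick + G:U pairs with a minimum hairpin loop of `min_loop`
// unpaired bases. Traceback is deterministic: within an interval the 5'-most
// base either stays unpaired or is paired with the leftmost partner that
// still achieves the optimal pair count (pairing preferred on ties).

static inline bool can_pair(char a, char b, bool allow_gu) {
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return true;
  if ((a == 'C' && b == 'G') || (a == 'G' && b == 'C')) return true;
  if (allow_gu && ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')))
    return true;
  return false;
}

// [[Rcpp::export(name = ".nussinov_fold")]]
Rcpp::List nussinov_fold(std::string seq, int min_loop = 3,
                         bool allow_gu = true) {
  const int n = (int)seq.size();
  for (int i = 0; i < n; ++i) {
    if (seq[i] == 'T') seq[i] = 'U';
    char c = seq[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'U')
      Rcpp::stop("non-ACGU symbol at position %d", i + 1);
  }
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k], allow_gu)) continue;
        int inner = (k - i - 1 > min_loop) ? M[i + 1][k - 1] : 0;
        int outer = (k < j) ? M[k + 1][j] : 0;
        int v = 1 + inner + outer;
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }

  std::string db(n, '.');
  // Iterative traceback over interval stack.
  std::vector<std::pair<int, int> > stack;
  if (n > 0) stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < min_loop + 1) continue;
    int target = M[i][j];
    if (target == 0) continue;
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!can_pair(seq[i], seq[k], allow_gu)) continue;
      int inner = (k - i - 1 > min_loop) ? M[i + 1][k - 1] : 0;
      int outer = (k < j) ? M[k + 1][j] : 0;
      if (1 + inner + outer == target) {
        db[i] = '(';
        db[k] = ')';
        if (k - i - 1 > min_loop) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k < j) stack.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }

  int pc = 0;
  for (int i = 0; i < n; ++i) if (db[i] == '(') ++pc;
  return Rcpp::List::create(Rcpp::Named("dotbracket") = db,
                            Rcpp::Named("pair_count") = pc);
}
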