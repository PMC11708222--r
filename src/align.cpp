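#include <Rcpp.h>
using namespace Rcpp;

// Needleman-Wunsch global alignment over IUPAC bit-set encoded sequences.
// A column scores `match` when the two base sets intersect, `mismatch`
// otherwise; gaps are linear.  Traceback ties prefer diagonal, then up
// (gap in b), then left (gap in a), making the alignment deterministic.
// [[Rcpp::export(name = ".nw_align_bits")]]
List nw_align_bits(IntegerVector a, IntegerVector b,
                   int match, int mismatch, int gap) {
  const int n = a.size(), m = b.size();
  std::vector<int> score((n + 1) * (m + 1));
  std::vector<unsigned char> tb((n + 1) * (m + 1));  // 0 diag, 1 up, 2 left
  const int W = m + 1;
  for (int i = 1; i <= n; ++i) { score[i * W] = i * gap; tb[i * W] = 1; }
  for (int j = 1; j <= m; ++j) { score[j] = j * gap; tb[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int sub = (a[i - 1] & b[j - 1]) ? match : mismatch;
      int d = score[(i - 1) * W + (j - 1)] + sub;
      int u = score[(i - 1) * W + j] + gap;
      int l = score[i * W + (j - 1)] + gap;
      int best = d; unsigned char t = 0;
      if (u > best) { best = u; t = 1; }
      if (l > best) { best = l; t = 2; }
      score[i * W + j] = best;
      tb[i * W + j] = t;
    }
  }
  // traceback: collect column operations in reverse
  std::vector<unsigned char> ops;
  ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char t = tb[i * W + j];
    ops.push_back(t);
    if (t == 0) { --i; --j; }
    else if (t == 1) { --i; }
    else { --j; }
  }
  std::reverse(ops.begin(), ops.end());
  const int L = ops.size();
  IntegerVector ai(L), bi(L);  // 1-based index into a/b, 0 for gap
  i = 0; j = 0;
  for (int k = 0; k < L; ++k) {
    if (ops[k] == 0) { ai[k] = ++i; bi[k] = ++j; }
    else if (ops[k] == 1) { ai[k] = ++i; bi[k] = 0; }
    else { ai[k] = 0; bi[k] = ++j; }
  }
  return List::create(_["score"] = score[n * W + m], _["ai"] = ai, _["bi"] = bi);
}
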