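#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// Local alignment with affine gaps (Gotoh recurrences).  A gap of length L
// costs gap_open + L * gap_extend (both negative).  'N' scores as a mismatch
// against every base, including another 'N'.  Traceback is deterministic:
// the best cell is the maximum-score cell with the smallest (i, j) in
// row-major order, and at each step the operation priority is
// diagonal > up (gap in subject) > left (gap in query), with gap-open
// preferred over gap-extend inside a gap state.
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string q, std::string s,
              int match, int mismatch, int gap_open, int gap_extend) {
  const int n = q.size(), m = s.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const int NEG = INT_MIN / 4;
  const int go = gap_open + gap_extend; // cost of the first gap column

  std::vector<int> H((n + 1) * (m + 1), 0);
  std::vector<int> E((n + 1) * (m + 1), NEG); // gap in query (left moves)
  std::vector<int> F((n + 1) * (m + 1), NEG); // gap in subject (up moves)
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const char a = q[i - 1], b = s[j - 1];
      const int sub = (a == b && a != 'N' && a != 'n') ? match : mismatch;
      const int e = std::max(H[idx(i, j - 1)] + go, E[idx(i, j - 1)] + gap_extend);
      const int f = std::max(H[idx(i - 1, j)] + go, F[idx(i - 1, j)] + gap_extend);
      int h = H[idx(i - 1, j - 1)] + sub;
      if (f > h) h = f;
      if (e > h) h = e;
      if (h < 0) h = 0;
      E[idx(i, j)] = e;
      F[idx(i, j)] = f;
      H[idx(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  std::string qa, sa;
  int i = bi, j = bj, state = 0; // 0 = H, 1 = F (up), 2 = E (left)
  int matches = 0;
  while (i > 0 && j > 0) {
    if (state == 0) {
      const int h = H[idx(i, j)];
      if (h == 0) break;
      const char a = q[i - 1], b = s[j - 1];
      const int sub = (a == b && a != 'N' && a != 'n') ? match : mismatch;
      if (h == H[idx(i - 1, j - 1)] + sub) {
        qa.push_back(a); sa.push_back(b);
        if (sub == match && a == b && a != 'N' && a != 'n') ++matches;
        --i; --j;
      } else if (h == F[idx(i, j)]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // gap in subject: consume query base
      const int f = F[idx(i, j)];
      qa.push_back(q[i - 1]); sa.push_back('-');
      if (f == H[idx(i - 1, j)] + go) state = 0; else state = 1;
      --i;
    } else { // gap in query: consume subject base
      const int e = E[idx(i, j)];
      qa.push_back('-'); sa.push_back(s[j - 1]);
      if (e == H[idx(i, j - 1)] + go) state = 0; else state = 2;
      --j;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  const int len = qa.size();

  return List::create(
    _["score"] = best,
    _["aln_length"] = len,
    _["identity"] = len > 0 ? (double)matches / len : 0.0,
    _["query_start"] = i + 1, _["query_end"] = bi,
    _["subject_start"] = j + 1, _["subject_end"] = bj,
    _["query_aln"] = qa, _["subject_aln"] = sa
  );
}
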