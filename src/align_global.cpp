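#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global pairwise alignment with affine gap penalties (three-state DP).
// A gap of length k costs gap_open + k * gap_extend. Traceback ties are
// broken deterministically: match/mismatch > gap-in-seq2 (deletion from
// seq1's point of view) > gap-in-seq1 (insertion).

static const double NEG_INF = -1e18;

// [[Rcpp::export(name = ".align_global_cpp")]]
List align_global_cpp(std::string s1, std::string s2,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  int n = s1.size(), m = s2.size();
  // state 0 = M (diagonal), 1 = X (gap in s2, consumes s1), 2 = Y (gap in s1)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i)
    X[at(i, 0)] = gap_open + gap_extend * i;
  for (int j = 1; j <= m; ++j)
    Y[at(0, j)] = gap_open + gap_extend * j;

  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      if (i > 0 && j > 0) {
        double s = (s1[i - 1] == s2[j - 1]) ? match : mismatch;
        double best = M[at(i - 1, j - 1)];
        if (X[at(i - 1, j - 1)] > best) best = X[at(i - 1, j - 1)];
        if (Y[at(i - 1, j - 1)] > best) best = Y[at(i - 1, j - 1)];
        if (best > NEG_INF / 2) M[at(i, j)] = best + s;
      }
      if (i > 0) {
        double open_from = std::max(M[at(i - 1, j)], Y[at(i - 1, j)]);
        double o = (open_from > NEG_INF / 2) ?
          open_from + gap_open + gap_extend : NEG_INF;
        double e = (X[at(i - 1, j)] > NEG_INF / 2) ?
          X[at(i - 1, j)] + gap_extend : NEG_INF;
        double v = std::max(o, e);
        if (v > X[at(i, j)]) X[at(i, j)] = v;
      }
      if (j > 0) {
        double open_from = std::max(M[at(i, j - 1)], X[at(i, j - 1)]);
        double o = (open_from > NEG_INF / 2) ?
          open_from + gap_open + gap_extend : NEG_INF;
        double e = (Y[at(i, j - 1)] > NEG_INF / 2) ?
          Y[at(i, j - 1)] + gap_extend : NEG_INF;
        double v = std::max(o, e);
        if (v > Y[at(i, j)]) Y[at(i, j)] = v;
      }
    }
  }

  // terminal state: prefer M > X > Y on ties
  int state = 0;
  double score = M[at(n, m)];
  if (X[at(n, m)] > score) { score = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > score) { score = Y[at(n, m)]; state = 2; }

  std::string a1, a2, ops;
  int i = n, j = m;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      double s = (s1[i - 1] == s2[j - 1]) ? match : mismatch;
      a1 += s1[i - 1];
      a2 += s2[j - 1];
      ops += (s1[i - 1] == s2[j - 1]) ? 'M' : 'S';
      double prev = M[at(i, j)] - s;
      --i; --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M[at(i, j)] - prev) < eps) state = 0;
      else if (std::abs(X[at(i, j)] - prev) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      a1 += s1[i - 1];
      a2 += '-';
      ops += 'D';
      double cur = X[at(i, j)];
      --i;
      // stayed in X (extension) or opened from M/Y?
      if (std::abs(X[at(i, j)] + gap_extend - cur) < eps) state = 1;
      else if (std::abs(M[at(i, j)] + gap_open + gap_extend - cur) < eps)
        state = 0;
      else state = 2;
    } else {
      a1 += '-';
      a2 += s2[j - 1];
      ops += 'I';
      double cur = Y[at(i, j)];
      --j;
      if (std::abs(Y[at(i, j)] + gap_extend - cur) < eps) state = 2;
      else if (std::abs(M[at(i, j)] + gap_open + gap_extend - cur) < eps)
        state = 0;
      else state = 1;
    }
  }
  std::reverse(a1.begin(), a1.end());
  std::reverse(a2.begin(), a2.end());
  std::reverse(ops.begin(), ops.end());
  return List::create(_["seq1"] = a1, _["seq2"] = a2,
                      _["ops"] = ops, _["score"] = score);
}
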