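#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Gotoh alignment with affine gap penalties and free (zero-cost) end gaps.
// States: M = residues paired, X = gap in b (consumes a), Y = gap in a
// (consumes b).  The traceback walks predecessors whose stored value
// reproduces the current cell's value, preferring M over X over Y on ties
// (the "highroad" path), so repeated runs return identical alignments and
// the emitted path always scores exactly the DP optimum.

static const double NEG = -1e18;
static const double EPS = 1e-9;

static inline bool is_transition(char p, char q) {
  return (p == 'A' && q == 'G') || (p == 'G' && q == 'A') ||
         (p == 'C' && q == 'T') || (p == 'T' && q == 'C');
}

// [[Rcpp::export(name = ".gotoh_free_end_gaps")]]
List gotoh_free_end_gaps(std::string a, std::string b,
                         double match, double mismatch, double transition,
                         double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i * W] = 0.0;      // free leading gap in b
  for (int j = 1; j <= m; ++j) Y[j] = 0.0;          // free leading gap in a
  const double go = gap_open, ge = gap_extend;

  auto sub = [&](int i, int j) {
    const char ai = a[i - 1], bj = b[j - 1];
    if (ai == bj && ai != 'N') return match;
    if (is_transition(ai, bj)) return transition;
    return mismatch;
  };

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int d = (i - 1) * W + (j - 1), up = (i - 1) * W + j,
                lf = i * W + (j - 1), cur = i * W + j;
      double best = std::max(M[d], std::max(X[d], Y[d]));
      if (best > NEG / 2) M[cur] = best + sub(i, j);
      double xo = (M[up] > NEG / 2) ? M[up] + go + ge : NEG;
      double xe = (X[up] > NEG / 2) ? X[up] + ge : NEG;
      double xs = (Y[up] > NEG / 2) ? Y[up] + go + ge : NEG;
      X[cur] = std::max(xo, std::max(xe, xs));
      double yo = (M[lf] > NEG / 2) ? M[lf] + go + ge : NEG;
      double ye = (Y[lf] > NEG / 2) ? Y[lf] + ge : NEG;
      double ys = (X[lf] > NEG / 2) ? X[lf] + go + ge : NEG;
      Y[cur] = std::max(yo, std::max(ye, ys));
    }
  }

  // terminal: free trailing gaps -> best over last row and last column,
  // preferring the corner, then the last row right-to-left, then the last
  // column bottom-up (first strict maximum wins; ties keep the earlier).
  auto cellbest = [&](int i, int j, int &st) {
    const int c = i * W + j;
    double best = M[c]; st = 0;
    if (X[c] > best) { best = X[c]; st = 1; }
    if (Y[c] > best) { best = Y[c]; st = 2; }
    return best;
  };
  int bi = n, bj = m, bst;
  double bscore = cellbest(n, m, bst);
  for (int j = m - 1; j >= 0; --j) {
    int st; double v = cellbest(n, j, st);
    if (v > bscore + EPS) { bscore = v; bi = n; bj = j; bst = st; }
  }
  for (int i = n - 1; i >= 0; --i) {
    int st; double v = cellbest(i, m, st);
    if (v > bscore + EPS) { bscore = v; bi = i; bj = m; bst = st; }
  }

  std::string ra, rb;
  for (int i = n; i > bi; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  for (int j = m; j > bj; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }

  auto near = [&](double u, double v) { return std::abs(u - v) <= EPS; };
  int i = bi, j = bj, st = bst;
  while (i > 0 || j > 0) {
    if (st == 0) {                       // M: consumed a[i-1], b[j-1]
      if (i == 0 || j == 0) stop("traceback left the matrix in state M");
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      const int d = (i - 1) * W + (j - 1);
      const double need = M[i * W + j] - sub(i, j);
      --i; --j;
      if (near(M[d], need)) st = 0;
      else if (near(X[d], need)) st = 1;
      else if (near(Y[d], need)) st = 2;
      else stop("inconsistent traceback in state M");
      if (i == 0 && j == 0) break;
    } else if (st == 1) {                // X: gap in b, consumed a[i-1]
      ra.push_back(a[i - 1]); rb.push_back('-');
      const int up = (i - 1) * W + j;
      const double v = X[i * W + j];
      --i;
      if (j == 0) { st = 1; }            // free leading gap column
      else if (near(M[up] + go + ge, v)) st = 0;
      else if (near(X[up] + ge, v)) st = 1;
      else if (near(Y[up] + go + ge, v)) st = 2;
      else stop("inconsistent traceback in state X");
      if (i == 0 && j == 0) break;
    } else {                             // Y: gap in a, consumed b[j-1]
      ra.push_back('-'); rb.push_back(b[j - 1]);
      const int lf = i * W + (j - 1);
      const double v = Y[i * W + j];
      --j;
      if (i == 0) { st = 2; }            // free leading gap column
      else if (near(M[lf] + go + ge, v)) st = 0;
      else if (near(Y[lf] + ge, v)) st = 2;
      else if (near(X[lf] + go + ge, v)) st = 1;
      else stop("inconsistent traceback in state Y");
      if (i == 0 && j == 0) break;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = bscore);
}
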