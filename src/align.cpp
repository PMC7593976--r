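// Affine-gap pairwise protein alignment kernels.
//
// Conventions (fixed so alignments are byte-reproducible):
//  - a gap of length L costs gap_open + L * gap_extend
//  - traceback tie-break: diagonal (match/mismatch) > up (gap in b) > left
//    (gap in a); in gap states, closing the gap is preferred over extending
//  - sequences are passed as 0-based integer index vectors into the
//    substitution matrix; encoding/validation happens in R
//
// Returned patterns use 'A' for a residue of sequence a, 'B' for a residue of
// sequence b and '-' for gaps; R substitutes the actual letters.

#include <Rcpp.h>
#include <vector>
#include <limits>
#include <string>
#include <algorithm>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();
enum { ST_M = 0, ST_X = 1, ST_Y = 2 };  // X: gap in b (consumes a), Y: gap in a

// [[Rcpp::export(name = ".cpp_global_align")]]
List cpp_global_align(IntegerVector a, IntegerVector b, IntegerMatrix smat,
                      double gap_open, double gap_extend) {
  const int m = a.size(), n = b.size();
  const double oe = gap_open + gap_extend, e = gap_extend;

  std::vector<std::vector<double>> M(m + 1, std::vector<double>(n + 1, NEG_INF)),
      X(m + 1, std::vector<double>(n + 1, NEG_INF)),
      Y(m + 1, std::vector<double>(n + 1, NEG_INF));
  M[0][0] = 0.0;
  for (int i = 1; i <= m; ++i) X[i][0] = -(gap_open + i * e);
  for (int j = 1; j <= n; ++j) Y[0][j] = -(gap_open + j * e);

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double s = smat(a[i - 1], b[j - 1]);
      M[i][j] = s + std::max({M[i - 1][j - 1], X[i - 1][j - 1], Y[i - 1][j - 1]});
      X[i][j] = std::max(std::max(M[i - 1][j], Y[i - 1][j]) - oe, X[i - 1][j] - e);
      Y[i][j] = std::max(std::max(M[i][j - 1], X[i][j - 1]) - oe, Y[i][j - 1] - e);
    }
  }
  double best = std::max({M[m][n], X[m][n], Y[m][n]});

  std::string aa, bb;
  int i = m, j = n;
  int st = (best == M[m][n]) ? ST_M : (best == X[m][n] ? ST_X : ST_Y);
  while (i > 0 || j > 0) {
    if (st == ST_M) {
      double p = M[i][j] - smat(a[i - 1], b[j - 1]);
      aa.push_back('A'); bb.push_back('B'); --i; --j;
      if (i == 0 && j == 0) break;
      st = (p == M[i][j]) ? ST_M : (p == X[i][j] ? ST_X : ST_Y);
    } else if (st == ST_X) {
      double v = X[i][j];
      aa.push_back('A'); bb.push_back('-'); --i;
      if (v == M[i][j] - oe) st = ST_M;
      else if (v == X[i][j] - e) st = ST_X;
      else st = ST_Y;
      if (i == 0 && j == 0) break;
    } else {
      double v = Y[i][j];
      aa.push_back('-'); bb.push_back('B'); --j;
      if (v == M[i][j] - oe) st = ST_M;
      else if (v == X[i][j] - oe) st = ST_X;
      else st = ST_Y;
      if (i == 0 && j == 0) break;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(_["score"] = best, _["pat_a"] = aa, _["pat_b"] = bb,
                      _["a_start"] = 0, _["a_end"] = m,
                      _["b_start"] = 0, _["b_end"] = n);
}

// [[Rcpp::export(name = ".cpp_local_align")]]
List cpp_local_align(IntegerVector a, IntegerVector b, IntegerMatrix smat,
                     double gap_open, double gap_extend) {
  const int m = a.size(), n = b.size();
  const double oe = gap_open + gap_extend, e = gap_extend;
  std::vector<std::vector<double>> M(m + 1, std::vector<double>(n + 1, NEG_INF)),
      X(m + 1, std::vector<double>(n + 1, NEG_INF)),
      Y(m + 1, std::vector<double>(n + 1, NEG_INF));
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double s = smat(a[i - 1], b[j - 1]);
      double prev = std::max({0.0, M[i - 1][j - 1], X[i - 1][j - 1], Y[i - 1][j - 1]});
      M[i][j] = s + prev;
      X[i][j] = std::max(std::max(M[i - 1][j], Y[i - 1][j]) - oe, X[i - 1][j] - e);
      Y[i][j] = std::max(std::max(M[i][j - 1], X[i][j - 1]) - oe, Y[i][j - 1] - e);
      if (M[i][j] > best) { best = M[i][j]; bi = i; bj = j; }
    }
  }
  std::string aa, bb;
  int ai0 = 0, bj0 = 0, ai1 = 0, bj1 = 0;
  if (best > 0) {
    ai1 = bi; bj1 = bj;
    int i = bi, j = bj, st = ST_M;
    while (true) {
      if (st == ST_M) {
        double p = M[i][j] - smat(a[i - 1], b[j - 1]);
        aa.push_back('A'); bb.push_back('B'); --i; --j;
        if (i == 0 || j == 0) break;
        // prefer continuing (diagonal > up > left) over a fresh start
        if (p == M[i][j]) st = ST_M;
        else if (p == X[i][j]) st = ST_X;
        else if (p == Y[i][j]) st = ST_Y;
        else break;  // p == 0: local alignment starts here
      } else if (st == ST_X) {
        double v = X[i][j];
        aa.push_back('A'); bb.push_back('-'); --i;
        if (v == M[i][j] - oe) st = ST_M;
        else if (v == X[i][j] - e) st = ST_X;
        else st = ST_Y;
      } else {
        double v = Y[i][j];
        aa.push_back('-'); bb.push_back('B'); --j;
        if (v == M[i][j] - oe) st = ST_M;
        else if (v == X[i][j] - oe) st = ST_X;
        else st = ST_Y;
      }
    }
    ai0 = i; bj0 = j;
    std::reverse(aa.begin(), aa.end());
    std::reverse(bb.begin(), bb.end());
  }
  return List::create(_["score"] = best, _["pat_a"] = aa, _["pat_b"] = bb,
                      _["a_start"] = ai0, _["a_end"] = ai1,
                      _["b_start"] = bj0, _["b_end"] = bj1);
}

// score-only Smith-Waterman, Gotoh recurrences, O(n) memory.
// H merges the M/X/Y states (plus the fresh-start 0), which is equivalent to
// the three-state formulation above when X<->Y switches are allowed.
static double sw_score(const std::vector<int>& a, const std::vector<int>& b,
                       const double* smat, int nalpha, double oe, double e) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) return 0.0;
  const double VERY_NEG = -1e30;
  std::vector<double> H(n + 1, 0.0), F(n + 1, VERY_NEG);
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    const double* srow = smat + (size_t)a[i - 1] * nalpha;
    double hdiag = 0.0;        // H[i-1][j-1]
    double hleft = 0.0;        // H[i][j-1]
    double E = VERY_NEG;       // gap in a, current row
    for (int j = 1; j <= n; ++j) {
      E = std::max(E, hleft - oe + e) - e;
      double f = std::max(F[j], H[j] - oe + e) - e;
      F[j] = f;
      double h = hdiag + srow[b[j - 1]];
      if (E > h) h = E;
      if (f > h) h = f;
      if (h < 0.0) h = 0.0;
      hdiag = H[j];
      H[j] = h;
      hleft = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".cpp_sw_score_matrix")]]
NumericMatrix cpp_sw_score_matrix(List seqs_a, List seqs_b, IntegerMatrix smat,
                                  double gap_open, double gap_extend) {
  const double oe = gap_open + gap_extend, e = gap_extend;
  const int na = seqs_a.size(), nb = seqs_b.size();
  const int nalpha = smat.nrow();
  std::vector<double> sflat((size_t)nalpha * nalpha);
  for (int i = 0; i < nalpha; ++i)
    for (int j = 0; j < nalpha; ++j)
      sflat[(size_t)i * nalpha + j] = smat(i, j);
  std::vector<std::vector<int>> A(na), B(nb);
  for (int i = 0; i < na; ++i) A[i] = as<std::vector<int>>(seqs_a[i]);
  for (int j = 0; j < nb; ++j) B[j] = as<std::vector<int>>(seqs_b[j]);
  NumericMatrix out(na, nb);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j)
      out(i, j) = sw_score(A[i], B[j], sflat.data(), nalpha, oe, e);
  return out;
}
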