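// Glocal (global-in-model, local-in-sequence) Viterbi scoring for profile
// models.
//
// Model semantics (mirrored by the path-enumeration oracle in the tests):
//  - match states 1..L with log2-odds emissions (emission / background)
//  - insert states emit at background (log-odds 0)
//  - transition log2-probabilities in an (L+1) x 7 matrix, rows j = 0..L
//    (row 0 = begin), columns MM, MD, MI, IM, II, DM, DD; row j governs
//    M_j -> {M_{j+1}, D_{j+1}, I_j}, I_j -> {M_{j+1}, I_j}, D_j -> {M_{j+1},
//    D_{j+1}}; row L's M/I/D -> "M_{L+1}" transitions are the exits to END
//  - unannotated sequence flanks before BEGIN / after END are null-scored:
//    they cost nothing and contribute nothing
//  - the model builder sets MI at rows 0 and L (and II at row L) to zero
//    probability: there is no insert state before the first or after the
//    last match position, the free flanks play that role

#include <Rcpp.h>
#include <vector>
#include <limits>
#include <algorithm>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();
enum { MM = 0, MD = 1, MI = 2, IM = 3, II = 4, DM = 5, DD = 6 };

// score-only fast path: rolling rows over model positions, flat arrays
static double viterbi_score_only(const double* em, int L, int A,
                                 const double* tl, const std::vector<int>& x) {
  const int n = (int)x.size();
  const double NI = NEG_INF;
  std::vector<double> vm0(n + 1, NI), vm1(n + 1, NI),
      vd0(n + 1, NI), vd1(n + 1, NI), vi0(n + 1, NI), vi1(n + 1, NI);
  // row j = 1
  const double* em0 = em;  // emissions of match state 1 (row 0)
  for (int i = 1; i <= n; ++i) vm0[i] = em0[x[i - 1] * L] + tl[0];        // tl(0,MM)
  for (int i = 0; i <= n; ++i) vd0[i] = tl[(L + 1) * 1];                  // tl(0,MD)
  for (int i = 1; i <= n; ++i) {
    double a = vm0[i - 1] + tl[(L + 1) * 2 + 1];   // tl(1,MI)
    double b = vi0[i - 1] + tl[(L + 1) * 4 + 1];   // tl(1,II)
    vi0[i] = a > b ? a : b;
  }
  for (int j = 2; j <= L; ++j) {
    const double tMM = tl[j - 1], tMD = tl[(L + 1) + j - 1],
                 tIM = tl[(L + 1) * 3 + j - 1], tDM = tl[(L + 1) * 5 + j - 1],
                 tDD = tl[(L + 1) * 6 + j - 1];
    const double tMI = tl[(L + 1) * 2 + j], tII = tl[(L + 1) * 4 + j];
    const double* emj = em + (j - 1);
    vm1[0] = NI; vi1[0] = NI;
    {
      double a = vm0[0] + tMD, b = vd0[0] + tDD;
      vd1[0] = a > b ? a : b;
    }
    for (int i = 1; i <= n; ++i) {
      double best = vm0[i - 1] + tMM;
      double c = vi0[i - 1] + tIM; if (c > best) best = c;
      c = vd0[i - 1] + tDM; if (c > best) best = c;
      vm1[i] = best + emj[(size_t)x[i - 1] * L];
      double a = vm0[i] + tMD, b = vd0[i] + tDD;
      vd1[i] = a > b ? a : b;
      a = vm1[i - 1] + tMI; b = vi1[i - 1] + tII;
      vi1[i] = a > b ? a : b;
    }
    std::swap(vm0, vm1); std::swap(vd0, vd1); std::swap(vi0, vi1);
  }
  const double eM = tl[L], eI = tl[(L + 1) * 3 + L], eD = tl[(L + 1) * 5 + L];
  double best = NEG_INF;
  for (int i = 0; i <= n; ++i) {
    double v = vm0[i] + eM;
    if (v > best) best = v;
    v = vi0[i] + eI; if (v > best) best = v;
    v = vd0[i] + eD; if (v > best) best = v;
  }
  return best;
}

static double viterbi_core(const NumericMatrix& em, const NumericMatrix& tl,
                           const std::vector<int>& x,
                           std::vector<std::vector<int>>* tb_state = nullptr,
                           std::vector<int>* out_path = nullptr,
                           int* out_start = nullptr) {
  const int L = em.nrow();
  const int n = (int)x.size();
  // VM[j][i]: best path ending in M_j having consumed i residues (x_i emitted
  // by M_j); VI[j][i]: ending in I_j; VD[j][i]: ending in D_j
  std::vector<std::vector<double>> VM(L + 1, std::vector<double>(n + 1, NEG_INF)),
      VI(L + 1, std::vector<double>(n + 1, NEG_INF)),
      VD(L + 1, std::vector<double>(n + 1, NEG_INF));
  // trace: 0 from M, 1 from I, 2 from D, 3 from begin
  std::vector<std::vector<int>> TM, TI, TD;
  const bool trace = tb_state != nullptr;
  if (trace) {
    TM.assign(L + 1, std::vector<int>(n + 1, -1));
    TI.assign(L + 1, std::vector<int>(n + 1, -1));
    TD.assign(L + 1, std::vector<int>(n + 1, -1));
  }
  // entry: begin after any free flank of i residues
  for (int i = 1; i <= n; ++i) {
    VM[1][i] = em(0, x[i - 1]) + tl(0, MM);
    if (trace) TM[1][i] = 3;
  }
  for (int i = 0; i <= n; ++i) {
    VD[1][i] = tl(0, MD);
    if (trace) TD[1][i] = 3;
  }
  for (int j = 1; j <= L; ++j) {
    for (int i = 0; i <= n; ++i) {
      if (j >= 2 && i >= 1) {
        double vm = VM[j - 1][i - 1] + tl(j - 1, MM);
        double vi = VI[j - 1][i - 1] + tl(j - 1, IM);
        double vd = VD[j - 1][i - 1] + tl(j - 1, DM);
        double b = std::max({vm, vi, vd});
        if (b > NEG_INF) {
          VM[j][i] = b + em(j - 1, x[i - 1]);
          if (trace) TM[j][i] = (b == vm) ? 0 : (b == vi ? 1 : 2);
        }
      }
      if (j >= 2) {
        double vm = VM[j - 1][i] + tl(j - 1, MD);
        double vd = VD[j - 1][i] + tl(j - 1, DD);
        double b = std::max(vm, vd);
        if (b > VD[j][i]) {
          VD[j][i] = b;
          if (trace) TD[j][i] = (b == vm) ? 0 : 2;
        }
      }
      if (i >= 1) {
        double vm = VM[j][i - 1] + tl(j, MI);
        double vi = VI[j][i - 1] + tl(j, II);
        double b = std::max(vm, vi);
        VI[j][i] = b;  // insert emissions are null-scored
        if (trace) TI[j][i] = (b == vm) ? 0 : 1;
      }
    }
  }
  double best = NEG_INF;
  int bi = -1, bs = -1;
  for (int i = 0; i <= n; ++i) {
    double vm = VM[L][i] + tl(L, MM);
    double vi = VI[L][i] + tl(L, IM);
    double vd = VD[L][i] + tl(L, DM);
    if (vm > best) { best = vm; bi = i; bs = 0; }
    if (vi > best) { best = vi; bi = i; bs = 1; }
    if (vd > best) { best = vd; bi = i; bs = 2; }
  }
  if (trace && out_path != nullptr && best > NEG_INF) {
    // out_path: per match position 1..L, emitted residue index or -1 (delete)
    out_path->assign(L, -1);
    int j = L, i = bi, st = bs;
    while (j >= 1) {
      int prev;
      if (st == 0) {
        (*out_path)[j - 1] = x[i - 1];
        prev = TM[j][i];
        --i; --j;
      } else if (st == 1) {
        prev = TI[j][i];
        --i;  // stay at j
        st = prev == 0 ? 0 : 1;
        continue;
      } else {
        (*out_path)[j - 1] = -1;
        prev = TD[j][i];
        --j;
      }
      if (prev == 3) break;
      st = prev;
    }
    if (out_start != nullptr) *out_start = i;
  }
  return best;
}

// [[Rcpp::export(name = ".cpp_viterbi_bits")]]
NumericVector cpp_viterbi_bits(NumericMatrix em, NumericMatrix tl, List seqs) {
  const int N = seqs.size();
  NumericVector out(N);
  const double* emp = em.begin();
  const double* tlp = tl.begin();
  const int L = em.nrow(), A = em.ncol();
  for (int k = 0; k < N; ++k) {
    std::vector<int> x = as<std::vector<int>>(seqs[k]);
    out[k] = viterbi_score_only(emp, L, A, tlp, x);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_viterbi_path")]]
List cpp_viterbi_path(NumericMatrix em, NumericMatrix tl, IntegerVector seq) {
  std::vector<int> x = as<std::vector<int>>(seq);
  std::vector<std::vector<int>> tb;
  std::vector<int> path;
  int start = 0;
  double bits = viterbi_core(em, tl, x, &tb, &path, &start);
  return List::create(_["bits"] = bits,
                      _["match_residues"] = IntegerVector(path.begin(), path.end()));
}
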