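#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// Glocal (global-in-model, free query flanks) profile-HMM dynamic programming.
//
// Model nodes are 0..L where node 0 is the non-emitting begin state (treated
// as M0) and node L is the last match state.  Transition vectors are indexed
// by source node (length L+1), all values log2 probabilities, -Inf for
// structurally impossible moves:
//   mm[k] : M_k -> M_{k+1}   (k == L: M_L -> End)
//   mi[k] : M_k -> I_k
//   md[k] : M_k -> D_{k+1}   (md[L] = -Inf)
//   im[k] : I_k -> M_{k+1}   (k == L: I_L -> End)
//   ii[k] : I_k -> I_k
//   dm[k] : D_k -> M_{k+1}   (k == L: D_L -> End; dm[0] unused)
//   dd[k] : D_k -> D_{k+1}   (dd[L] = -Inf; dd[0] unused)
// em is the L x N matrix of match-emission log2 odds for the query; insert
// states and the free N/C flanks emit at background odds (0 bits).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  // log2(2^a + 2^b)
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double hi = a > b ? a : b, lo = a > b ? b : a;
  return hi + std::log1p(std::exp2(lo - hi)) / M_LN2;
}

// [[Rcpp::export]]
List viterbi_glocal_cpp(NumericMatrix em,
                        NumericVector mm, NumericVector mi, NumericVector md,
                        NumericVector im, NumericVector ii, NumericVector dm,
                        NumericVector dd) {
  const int L = em.nrow(), N = em.ncol();
  const int W = N + 1;
  std::vector<double> VM((L + 1) * W, NEG_INF), VI((L + 1) * W, NEG_INF),
      VD((L + 1) * W, NEG_INF);
  // traceback: predecessor state of each cell (0 = M, 1 = D, 2 = I)
  std::vector<signed char> PM((L + 1) * W, -1), PI((L + 1) * W, -1),
      PD((L + 1) * W, -1);
#define AT(k, i) ((k) * W + (i))

  // begin state reachable after any free N-flank
  for (int i = 0; i <= N; ++i) VM[AT(0, i)] = 0.0;
  for (int i = 1; i <= N; ++i) {
    double fm = VM[AT(0, i - 1)] + mi[0];
    double fi = VI[AT(0, i - 1)] + ii[0];
    if (fm >= fi) { VI[AT(0, i)] = fm; PI[AT(0, i)] = 0; }
    else          { VI[AT(0, i)] = fi; PI[AT(0, i)] = 2; }
  }
  for (int k = 1; k <= L; ++k) {
    for (int i = 0; i <= N; ++i) {
      // delete: from M_{k-1} or D_{k-1} at same i
      double cm = VM[AT(k - 1, i)] + md[k - 1];
      double cd = (k >= 2) ? VD[AT(k - 1, i)] + dd[k - 1] : NEG_INF;
      if (cm >= cd) { VD[AT(k, i)] = cm; PD[AT(k, i)] = 0; }
      else          { VD[AT(k, i)] = cd; PD[AT(k, i)] = 1; }
      if (i >= 1) {
        // match: tie preference M > D > I
        double bm = VM[AT(k - 1, i - 1)] + mm[k - 1];
        double bd = VD[AT(k - 1, i - 1)] + dm[k - 1];
        double bi = VI[AT(k - 1, i - 1)] + im[k - 1];
        double best = bm; signed char who = 0;
        if (bd > best) { best = bd; who = 1; }
        if (bi > best) { best = bi; who = 2; }
        VM[AT(k, i)] = best + em(k - 1, i - 1);
        PM[AT(k, i)] = who;
        // insert after node k
        double sm = VM[AT(k, i - 1)] + mi[k];
        double si = VI[AT(k, i - 1)] + ii[k];
        if (sm >= si) { VI[AT(k, i)] = sm; PI[AT(k, i)] = 0; }
        else          { VI[AT(k, i)] = si; PI[AT(k, i)] = 2; }
      }
    }
  }
  // end: free C-flank, preference M > D > I then smallest i
  double best = NEG_INF; int bi_ = -1; signed char bs = -1;
  for (int i = 0; i <= N; ++i) {
    double cands[3] = { VM[AT(L, i)] + mm[L], VD[AT(L, i)] + dm[L],
                        VI[AT(L, i)] + im[L] };
    for (int s = 0; s < 3; ++s)
      if (cands[s] > best) { best = cands[s]; bi_ = i; bs = (signed char)s; }
  }
  IntegerVector assignments(L, NA_INTEGER);
  std::vector<int> ins_node, ins_pos;
  int n_flank = 0;
  if (best > NEG_INF) {
    int k = L, i = bi_; signed char s = bs;  // 0=M,1=D,2=I
    while (!(s == 0 && k == 0)) {
      signed char prev;
      if (s == 0) {
        assignments[k - 1] = i;
        prev = PM[AT(k, i)]; --k; --i;
      } else if (s == 1) {
        prev = PD[AT(k, i)]; --k;
      } else {
        ins_node.push_back(k); ins_pos.push_back(i);
        prev = PI[AT(k, i)]; --i;
      }
      s = prev;
    }
    n_flank = i;
  }
  return List::create(_["score_bits"] = best,
                      _["assignments"] = assignments,
                      _["ins_node"] = wrap(ins_node),
                      _["ins_pos"] = wrap(ins_pos),
                      _["n_flank"] = n_flank,
                      _["c_flank"] = N - bi_);
#undef AT
}

// [[Rcpp::export]]
double forward_glocal_cpp(NumericMatrix em,
                          NumericVector mm, NumericVector mi, NumericVector md,
                          NumericVector im, NumericVector ii, NumericVector dm,
                          NumericVector dd) {
  const int L = em.nrow(), N = em.ncol();
  const int W = N + 1;
  std::vector<double> FM((L + 1) * W, NEG_INF), FI((L + 1) * W, NEG_INF),
      FD((L + 1) * W, NEG_INF);
#define AT(k, i) ((k) * W + (i))
  for (int i = 0; i <= N; ++i) FM[AT(0, i)] = 0.0;
  for (int i = 1; i <= N; ++i)
    FI[AT(0, i)] = lse2(FM[AT(0, i - 1)] + mi[0], FI[AT(0, i - 1)] + ii[0]);
  for (int k = 1; k <= L; ++k) {
    for (int i = 0; i <= N; ++i) {
      double d = FM[AT(k - 1, i)] + md[k - 1];
      if (k >= 2) d = lse2(d, FD[AT(k - 1, i)] + dd[k - 1]);
      FD[AT(k, i)] = d;
      if (i >= 1) {
        double m = lse2(lse2(FM[AT(k - 1, i - 1)] + mm[k - 1],
                             FD[AT(k - 1, i - 1)] + dm[k - 1]),
                        FI[AT(k - 1, i - 1)] + im[k - 1]);
        FM[AT(k, i)] = m + em(k - 1, i - 1);
        FI[AT(k, i)] = lse2(FM[AT(k, i - 1)] + mi[k],
                            FI[AT(k, i - 1)] + ii[k]);
      }
    }
  }
  double tot = NEG_INF;
  for (int i = 0; i <= N; ++i) {
    tot = lse2(tot, FM[AT(L, i)] + mm[L]);
    tot = lse2(tot, FD[AT(L, i)] + dm[L]);
    tot = lse2(tot, FI[AT(L, i)] + im[L]);
  }
  return tot;
#undef AT
}
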