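#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Profile-HMM scoring in log2-odds ("bits") against the background model.
//
// Architecture: match states M1..MK, insert states I0..IK, delete states
// D1..DK, with Begin acting as M0 and End as M(K+1). Allowed transitions:
// M->M, M->I, M->D, I->M, I->I, D->M, D->D (no I<->D), all passed as log2
// probabilities. Emission matrices are log2-odds vs the background; a
// residue coded 20 ('X') emits with log-odds 0 from every state.
//
// tm: (K+1) x 3 rows k = 0..K, from M_k to [M_{k+1}|End, I_k, D_{k+1}]
// ti: (K+1) x 2 rows k = 0..K, from I_k to [M_{k+1}|End, I_k]
// td: (K+1) x 2 rows k = 1..K, from D_k to [M_{k+1}|End, D_{k+1}] (row 0 unused)
// Impossible transitions (e.g. M_K -> D) must be -Inf in the input.

static const double LOG_NEG_INF = -1e30;

static inline double log2sum(double x, double y) {
  if (x <= LOG_NEG_INF / 2) return y;
  if (y <= LOG_NEG_INF / 2) return x;
  double mx = x > y ? x : y;
  return mx + std::log2(std::exp2(x - mx) + std::exp2(y - mx));
}

static double score_one(const IntegerVector& seq, const NumericMatrix& me,
                        const NumericMatrix& ie, const NumericMatrix& tm,
                        const NumericMatrix& ti, const NumericMatrix& td,
                        bool forward) {
  const int K = me.nrow();
  const int L = seq.size();
  // vm[k][i]: path ends in M_k having emitted first i residues (M_k emits residue i)
  // k runs 0..K with k = 0 the virtual Begin.
  std::vector<std::vector<double>> vm(K + 1, std::vector<double>(L + 1, LOG_NEG_INF)),
      vi(K + 1, std::vector<double>(L + 1, LOG_NEG_INF)),
      vd(K + 1, std::vector<double>(L + 1, LOG_NEG_INF));
  vm[0][0] = 0.0;

  for (int k = 0; k <= K; ++k) {
    for (int i = 0; i <= L; ++i) {
      if (k > 0 && i > 0) {
        int x = seq[i - 1];
        double e = (x >= 20) ? 0.0 : me(k - 1, x);
        double a = vm[k - 1][i - 1] + tm(k - 1, 0);
        double b = vi[k - 1][i - 1] + ti(k - 1, 0);
        double c = (k >= 2) ? vd[k - 1][i - 1] + td(k - 1, 0) : LOG_NEG_INF;
        double v = forward ? log2sum(log2sum(a, b), c)
                           : std::max(a, std::max(b, c));
        vm[k][i] = e + v;
      }
      if (i > 0) {
        int x = seq[i - 1];
        double e = (x >= 20) ? 0.0 : ie(k, x);
        double a = vm[k][i - 1] + tm(k, 1);
        double b = vi[k][i - 1] + ti(k, 1);
        double v = forward ? log2sum(a, b) : std::max(a, b);
        vi[k][i] = e + v;
      }
      if (k > 0) {
        double a = vm[k - 1][i] + tm(k - 1, 2);
        double b = (k >= 2) ? vd[k - 1][i] + td(k - 1, 1) : LOG_NEG_INF;
        vd[k][i] = forward ? log2sum(a, b) : std::max(a, b);
      }
    }
  }
  double a = vm[K][L] + tm(K, 0);
  double b = vi[K][L] + ti(K, 0);
  double c = (K >= 1) ? vd[K][L] + td(K, 0) : LOG_NEG_INF;
  double s = forward ? log2sum(log2sum(a, b), c) : std::max(a, std::max(b, c));
  return s <= LOG_NEG_INF / 2 ? R_NegInf : s;
}

// [[Rcpp::export(name = ".hmm_score_cpp")]]
double hmm_score_cpp(IntegerVector seq, NumericMatrix me, NumericMatrix ie,
                     NumericMatrix tm, NumericMatrix ti, NumericMatrix td,
                     bool forward) {
  return score_one(seq, me, ie, tm, ti, td, forward);
}

// [[Rcpp::export(name = ".hmm_score_many_cpp")]]
NumericVector hmm_score_many_cpp(List seqs, NumericMatrix me, NumericMatrix ie,
                                 NumericMatrix tm, NumericMatrix ti,
                                 NumericMatrix td, bool forward) {
  const int n = seqs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = score_one(as<IntegerVector>(seqs[i]), me, ie, tm, ti, td, forward);
  return out;
}
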