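#include <Rcpp.h>
using namespace Rcpp;

// Gotoh affine-gap dynamic programming on integer-encoded sequences.
// A gap of length k costs gap_open + k * gap_ext (BLAST convention, so the
// first gapped position pays open + ext). Traceback ties are broken
// diagonal > up > left so results are deterministic.
//
// op codes in the returned path: 0 = diagonal (consume a and b),
// 1 = up (consume a, gap in b), 2 = left (consume b, gap in a).

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".pairwise_align_cpp")]]
List pairwise_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                        double gap_open, double gap_ext, bool local) {
  const int n = a.size(), m = b.size();
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  // ptrH: 0 diag, 1 up(F), 2 left(E), 3 stop (local start)
  IntegerMatrix ptrH(n + 1, m + 1), ptrE(n + 1, m + 1), ptrF(n + 1, m + 1);
  const double go = gap_open + gap_ext;

  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      if (i == 0 && j == 0) { H(0, 0) = 0; E(0, 0) = F(0, 0) = NEG_INF; continue; }
      // E: gap in a (left move, consume b_j)
      if (j > 0) {
        double open_sc = H(i, j - 1) - go;
        double ext_sc  = E(i, j - 1) - gap_ext;
        if (open_sc >= ext_sc) { E(i, j) = open_sc; ptrE(i, j) = 0; }
        else                   { E(i, j) = ext_sc;  ptrE(i, j) = 1; }
      } else E(i, j) = NEG_INF;
      // F: gap in b (up move, consume a_i)
      if (i > 0) {
        double open_sc = H(i - 1, j) - go;
        double ext_sc  = F(i - 1, j) - gap_ext;
        if (open_sc >= ext_sc) { F(i, j) = open_sc; ptrF(i, j) = 0; }
        else                   { F(i, j) = ext_sc;  ptrF(i, j) = 1; }
      } else F(i, j) = NEG_INF;

      double best; int ptr;
      if (i > 0 && j > 0) {
        best = H(i - 1, j - 1) + sub(a[i - 1], b[j - 1]);
        ptr = 0;
      } else { best = NEG_INF; ptr = 0; }
      if (F(i, j) > best) { best = F(i, j); ptr = 1; }
      if (E(i, j) > best) { best = E(i, j); ptr = 2; }
      if (local && best < 0) { best = 0; ptr = 3; }
      H(i, j) = best; ptrH(i, j) = ptr;
    }
  }

  int ei = n, ej = m;
  double score;
  if (local) {
    score = 0; ei = 0; ej = 0;
    for (int i = 1; i <= n; ++i)
      for (int j = 1; j <= m; ++j)
        if (H(i, j) > score) { score = H(i, j); ei = i; ej = j; }
  } else {
    score = H(n, m);
  }

  // traceback (state machine over H/E/F)
  std::vector<int> ops;
  int i = ei, j = ej, state = 0; // 0 = H, 1 = F, 2 = E
  while (true) {
    if (state == 0) {
      if (i == 0 && j == 0) break;
      if (local && H(i, j) == 0 && ptrH(i, j) == 3) break;
      int p = ptrH(i, j);
      if (p == 0) { ops.push_back(0); --i; --j; }
      else if (p == 1) state = 1;
      else if (p == 2) state = 2;
      else break;
    } else if (state == 1) {
      int p = ptrF(i, j);
      ops.push_back(1); --i;
      if (p == 0) state = 0;
    } else {
      int p = ptrE(i, j);
      ops.push_back(2); --j;
      if (p == 0) state = 0;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = score,
                      _["ops"] = IntegerVector(ops.begin(), ops.end()),
                      _["a_start"] = i + 1, _["b_start"] = j + 1,
                      _["a_end"] = ei, _["b_end"] = ej);
}

// Global affine alignment of two frequency profiles (20 x L matrices of
// residue frequencies per column; gap mass simply missing). Column-column
// score is the expected substitution score f1' S f2.
// [[Rcpp::export(name = ".profile_align_cpp")]]
List profile_align_cpp(NumericMatrix p1, NumericMatrix p2, NumericMatrix sub,
                       double gap_open, double gap_ext) {
  const int n = p1.ncol(), m = p2.ncol();
  // T = sub %*% p2  (20 x m)
  NumericMatrix T(20, m);
  for (int j = 0; j < m; ++j)
    for (int a = 0; a < 20; ++a) {
      double s = 0;
      for (int b = 0; b < 20; ++b) s += sub(a, b) * p2(b, j);
      T(a, j) = s;
    }
  NumericMatrix S(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double s = 0;
      for (int a = 0; a < 20; ++a) s += p1(a, i) * T(a, j);
      S(i, j) = s;
    }

  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  IntegerMatrix ptrH(n + 1, m + 1), ptrE(n + 1, m + 1), ptrF(n + 1, m + 1);
  const double go = gap_open + gap_ext;
  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      if (i == 0 && j == 0) { H(0, 0) = 0; E(0, 0) = F(0, 0) = NEG_INF; continue; }
      if (j > 0) {
        double o = H(i, j - 1) - go, e = E(i, j - 1) - gap_ext;
        if (o >= e) { E(i, j) = o; ptrE(i, j) = 0; } else { E(i, j) = e; ptrE(i, j) = 1; }
      } else E(i, j) = NEG_INF;
      if (i > 0) {
        double o = H(i - 1, j) - go, e = F(i - 1, j) - gap_ext;
        if (o >= e) { F(i, j) = o; ptrF(i, j) = 0; } else { F(i, j) = e; ptrF(i, j) = 1; }
      } else F(i, j) = NEG_INF;
      double best; int ptr;
      if (i > 0 && j > 0) { best = H(i - 1, j - 1) + S(i - 1, j - 1); ptr = 0; }
      else { best = NEG_INF; ptr = 0; }
      if (F(i, j) > best) { best = F(i, j); ptr = 1; }
      if (E(i, j) > best) { best = E(i, j); ptr = 2; }
      H(i, j) = best; ptrH(i, j) = ptr;
    }
  }
  std::vector<int> ops;
  int i = n, j = m, state = 0;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int p = ptrH(i, j);
      if (p == 0) { ops.push_back(0); --i; --j; }
      else if (p == 1) state = 1;
      else state = 2;
    } else if (state == 1) {
      int p = ptrF(i, j); ops.push_back(1); --i; if (p == 0) state = 0;
    } else {
      int p = ptrE(i, j); ops.push_back(2); --j; if (p == 0) state = 0;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = H(n, m),
                      _["ops"] = IntegerVector(ops.begin(), ops.end()));
}
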