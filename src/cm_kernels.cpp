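// CYK kernels for covariance-model scoring.
//
// A model arrives flattened (see cm_flatten() on the R side): parallel
// vectors of state types, child ranges, and concatenated transition /
// emission score vectors with offset arrays. Scores are bits; -Inf is the
// impossibility sentinel. State type codes match STATE_CODE in R:
// S=0 D=1 IL=2 IR=3 ML=4 MR=5 MP=6 B=7 E=8.

#include <Rcpp.h>
#include <array>
#include <limits>
#include <vector>

using namespace Rcpp;

static const double NEG = -std::numeric_limits<double>::infinity();

enum { T_S = 0, T_D, T_IL, T_IR, T_ML, T_MR, T_MP, T_B, T_E };

struct FlatCM {
  int n;
  const int *type, *cfirst, *cnum, *toff, *eoff;
  const double *trans, *emis;

  FlatCM(const IntegerVector &type_, const IntegerVector &cfirst_,
         const IntegerVector &cnum_, const NumericVector &trans_,
         const IntegerVector &toff_, const NumericVector &emis_,
         const IntegerVector &eoff_)
      : n(type_.size()), type(type_.begin()), cfirst(cfirst_.begin()),
        cnum(cnum_.begin()), toff(toff_.begin()), eoff(eoff_.begin()),
        trans(trans_.begin()), emis(emis_.begin()) {}
};

// Full CYK over subsequences x states. M has dimension n*(L+1)*(L+1),
// cell (v,i,j) = best bits for state v deriving seq[i..j) (half-open).
// Optional choice arrays record the argmax child / bifurcation split with
// deterministic tie-breaks (first child in ascending order, leftmost
// split, strict improvement only).
static void cyk_fill(const FlatCM &cm, const int *seq, int L,
                     std::vector<double> &M, std::vector<int> *chArr,
                     std::vector<int> *spArr) {
  const int W = L + 1;
  const size_t cells = (size_t)cm.n * W * W;
  M.assign(cells, NEG);
  if (chArr) chArr->assign(cells, -1);
  if (spArr) spArr->assign(cells, -1);

  auto idx = [&](int v, int i, int j) -> size_t {
    return ((size_t)v * W + i) * W + j;
  };

  for (int d = 0; d <= L; ++d) {
    for (int i = 0; i + d <= L; ++i) {
      const int j = i + d;
      for (int v = cm.n - 1; v >= 0; --v) {
        const int ty = cm.type[v];
        double best = NEG;
        int bestCh = -1, bestSp = -1;
        switch (ty) {
        case T_E:
          if (d == 0) best = 0.0;
          break;
        case T_S:
        case T_D: {
          for (int c = 0; c < cm.cnum[v]; ++c) {
            const int y = cm.cfirst[v] + c;
            const double s = cm.trans[cm.toff[v] + c] + M[idx(y, i, j)];
            if (s > best) { best = s; bestCh = y; }
          }
          break;
        }
        case T_IL:
        case T_ML: {
          if (d >= 1) {
            const double e = cm.emis[cm.eoff[v] + seq[i]];
            for (int c = 0; c < cm.cnum[v]; ++c) {
              const int y = cm.cfirst[v] + c;
              const double s =
                  e + cm.trans[cm.toff[v] + c] + M[idx(y, i + 1, j)];
              if (s > best) { best = s; bestCh = y; }
            }
          }
          break;
        }
        case T_IR:
        case T_MR: {
          if (d >= 1) {
            const double e = cm.emis[cm.eoff[v] + seq[j - 1]];
            for (int c = 0; c < cm.cnum[v]; ++c) {
              const int y = cm.cfirst[v] + c;
              const double s =
                  e + cm.trans[cm.toff[v] + c] + M[idx(y, i, j - 1)];
              if (s > best) { best = s; bestCh = y; }
            }
          }
          break;
        }
        case T_MP: {
          if (d >= 2) {
            const double e = cm.emis[cm.eoff[v] + 4 * seq[i] + seq[j - 1]];
            for (int c = 0; c < cm.cnum[v]; ++c) {
              const int y = cm.cfirst[v] + c;
              const double s =
                  e + cm.trans[cm.toff[v] + c] + M[idx(y, i + 1, j - 1)];
              if (s > best) { best = s; bestCh = y; }
            }
          }
          break;
        }
        case T_B: {
          const int lft = cm.cfirst[v], rgt = cm.cnum[v];
          for (int k = i; k <= j; ++k) {
            const double s = M[idx(lft, i, k)] + M[idx(rgt, k, j)];
            if (s > best) { best = s; bestSp = k; }
          }
          break;
        }
        }
        M[idx(v, i, j)] = best;
        if (chArr) (*chArr)[idx(v, i, j)] = bestCh;
        if (spArr) (*spArr)[idx(v, i, j)] = bestSp;
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_cyk(IntegerVector type, IntegerVector cfirst, IntegerVector cnum,
             NumericVector trans, IntegerVector toff, NumericVector emis,
             IntegerVector eoff, IntegerVector seq, bool trace) {
  FlatCM cm(type, cfirst, cnum, trans, toff, emis, eoff);
  const int L = seq.size();
  std::vector<int> sq(seq.begin(), seq.end());
  std::vector<double> M;
  std::vector<int> ch, sp;
  cyk_fill(cm, sq.data(), L, M, trace ? &ch : nullptr, trace ? &sp : nullptr);
  const int W = L + 1;
  auto idx = [&](int v, int i, int j) -> size_t {
    return ((size_t)v * W + i) * W + j;
  };
  const double score = M[idx(0, 0, L)];

  if (!trace || !R_finite(score))
    return List::create(_["score"] = score,
                        _["trace"] = IntegerMatrix(0, 3));

  // pre-order walk collecting (state, i, j) rows
  std::vector<std::array<int, 3>> rows;
  std::vector<std::array<int, 3>> stack;
  stack.push_back({0, 0, L});
  while (!stack.empty()) {
    auto cur = stack.back();
    stack.pop_back();
    const int v = cur[0], i = cur[1], j = cur[2];
    rows.push_back(cur);
    const int ty = cm.type[v];
    if (ty == T_E) continue;
    if (ty == T_B) {
      const int k = sp[idx(v, i, j)];
      // right child pushed first so the left subtree is visited first
      stack.push_back({cm.cnum[v], k, j});
      stack.push_back({cm.cfirst[v], i, k});
      continue;
    }
    const int y = ch[idx(v, i, j)];
    int ni = i, nj = j;
    if (ty == T_IL || ty == T_ML) ni = i + 1;
    else if (ty == T_IR || ty == T_MR) nj = j - 1;
    else if (ty == T_MP) { ni = i + 1; nj = j - 1; }
    stack.push_back({y, ni, nj});
  }
  IntegerMatrix tr(rows.size(), 3);
  for (size_t r = 0; r < rows.size(); ++r) {
    tr(r, 0) = rows[r][0];
    tr(r, 1) = rows[r][1];
    tr(r, 2) = rows[r][2];
  }
  colnames(tr) = CharacterVector::create("state", "i", "j");
  return List::create(_["score"] = score, _["trace"] = tr);
}

// Enumerate all sequences of length 0..maxLen in canonical order (shorter
// first, then lexicographic with A<C<G<U) and return the first sequence
// attaining the maximum of `score(seq)` where score is either the single
// model's CYK score or the min over the two models. Strict improvement
// keeps the canonical-order tie-break.
static List enum_best(const FlatCM &a, const FlatCM *b, int maxLen) {
  if (maxLen > 8) stop("brute-force guard: maxLen must be <= 8");
  std::vector<double> Ma, Mb;
  double best = NEG;
  std::vector<int> bestSeq;

  std::vector<int> seq;
  for (int L = 0; L <= maxLen; ++L) {
    seq.assign(L, 0);
    while (true) {
      cyk_fill(a, seq.data(), L, Ma, nullptr, nullptr);
      const int W = L + 1;
      double s = Ma[(size_t)0 * W * W + 0 * W + L];
      if (b && s > NEG) {
        cyk_fill(*b, seq.data(), L, Mb, nullptr, nullptr);
        const double sb = Mb[(size_t)0 * W * W + 0 * W + L];
        s = std::min(s, sb);
      }
      if (s > best) { best = s; bestSeq = seq; }
      // odometer increment
      int p = L - 1;
      while (p >= 0 && seq[p] == 3) seq[p--] = 0;
      if (p < 0) break;
      ++seq[p];
    }
  }
  return List::create(_["score"] = best,
                      _["seq"] = IntegerVector(bestSeq.begin(),
                                               bestSeq.end()));
}

// [[Rcpp::export]]
List cpp_enum_best_single(IntegerVector type, IntegerVector cfirst,
                          IntegerVector cnum, NumericVector trans,
                          IntegerVector toff, NumericVector emis,
                          IntegerVector eoff, int maxLen) {
  FlatCM cm(type, cfirst, cnum, trans, toff, emis, eoff);
  return enum_best(cm, nullptr, maxLen);
}

// [[Rcpp::export]]
List cpp_enum_best_pair(IntegerVector typeA, IntegerVector cfirstA,
                        IntegerVector cnumA, NumericVector transA,
                        IntegerVector toffA, NumericVector emisA,
                        IntegerVector eoffA, IntegerVector typeB,
                        IntegerVector cfirstB, IntegerVector cnumB,
                        NumericVector transB, IntegerVector toffB,
                        NumericVector emisB, IntegerVector eoffB,
                        int maxLen) {
  FlatCM a(typeA, cfirstA, cnumA, transA, toffA, emisA, eoffA);
  FlatCM b(typeB, cfirstB, cnumB, transB, toffB, emisB, eoffB);
  return enum_best(a, &b, maxLen);
}
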