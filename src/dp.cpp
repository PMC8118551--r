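// Dynamic programming kernels for the 5-state pairwise-alignment CRF.
//
// The five collapsed states (M, Ix, Iy, Gh, Gt) are expanded to seven
// directional sub-states (M, Ix, Iy, Hx, Hy, Tx, Ty): a flank-gap step
// consumes exactly one residue of either protein, and within a flank all
// template-consuming steps precede query-consuming ones.  The grid cell
// (i, j) holds paths that have consumed the first i template and first j
// query residues.  A virtual start may enter {M, Hx, Hy}; a virtual end is
// reached from {M, Tx, Ty}; start/end transitions are unscored.
//
// Emission convention: a step in state s landing at cell (i, j) reads
// theta[max(i,1), max(j,1), u5(s)] (1-based), i.e. the unconsumed side of a
// gap step uses the last consumed index, clamped to the first position.
// This matches score_alignment() in R.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int DX[7] = {1, 1, 0, 1, 0, 1, 0};
static const int DY[7] = {1, 0, 1, 0, 1, 0, 1};
static const int U5[7] = {0, 1, 2, 3, 3, 4, 4};
static const int NS = 7;
static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline bool is_start(int s) { return s == 0 || s == 3 || s == 4; }
static inline bool is_end(int s) { return s == 0 || s == 5 || s == 6; }

struct Grid {
  int n1, n2;
  std::vector<double> v;
  Grid(int n1_, int n2_) : n1(n1_), n2(n2_),
    v((size_t)(n1_ + 1) * (n2_ + 1) * NS, NEG_INF) {}
  double& at(int i, int j, int s) {
    return v[((size_t)i * (n2 + 1) + j) * NS + s];
  }
};

static inline double emission(const NumericVector& theta, int n1, int n2,
                              int i, int j, int s) {
  int ii = i < 1 ? 0 : i - 1;
  int jj = j < 1 ? 0 : j - 1;
  return theta[(size_t)U5[s] * n1 * n2 + (size_t)jj * n1 + ii];
}

static inline double lse(const double* x, int n) {
  double m = NEG_INF;
  for (int k = 0; k < n; ++k) if (x[k] > m) m = x[k];
  if (m == NEG_INF) return NEG_INF;
  double s = 0.0;
  for (int k = 0; k < n; ++k) s += std::exp(x[k] - m);
  return m + std::log(s);
}

// [[Rcpp::export]]
List cpp_viterbi(NumericVector theta, IntegerVector dims,
                 LogicalMatrix f7, NumericMatrix s7) {
  const int n1 = dims[0], n2 = dims[1];
  Grid V(n1, n2);
  std::vector<signed char> bp((size_t)(n1 + 1) * (n2 + 1) * NS, -2);
  for (int i = 0; i <= n1; ++i) {
    for (int j = 0; j <= n2; ++j) {
      for (int s = 0; s < NS; ++s) {
        const int pi = i - DX[s], pj = j - DY[s];
        if (pi < 0 || pj < 0) continue;
        double best = NEG_INF;
        signed char arg = -2;
        if (pi == 0 && pj == 0 && is_start(s)) { best = 0.0; arg = -1; }
        for (int p = 0; p < NS; ++p) { // preference order M,Ix,Iy,Hx,Hy,Tx,Ty
          if (!f7(p, s)) continue;
          const double c = V.at(pi, pj, p) + s7(p, s);
          if (c > best) { best = c; arg = (signed char)p; }
        }
        if (arg == -2) continue;
        V.at(i, j, s) = best + emission(theta, n1, n2, i, j, s);
        bp[((size_t)i * (n2 + 1) + j) * NS + s] = arg;
      }
    }
  }
  double best = NEG_INF;
  int ends = -1;
  const int endorder[3] = {0, 5, 6};
  for (int k = 0; k < 3; ++k) {
    const int s = endorder[k];
    if (V.at(n1, n2, s) > best) { best = V.at(n1, n2, s); ends = s; }
  }
  if (ends < 0) stop("no valid alignment exists (empty state space)");
  std::vector<int> pi_, pj_, ps_;
  int ci = n1, cj = n2, cs = ends;
  while (cs != -1) {
    pi_.push_back(ci); pj_.push_back(cj); ps_.push_back(cs);
    const int prev = bp[((size_t)ci * (n2 + 1) + cj) * NS + cs];
    ci -= DX[cs]; cj -= DY[cs]; cs = prev;
  }
  const int L = (int)ps_.size();
  IntegerMatrix path(L, 3);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = pi_[L - 1 - k];
    path(k, 1) = pj_[L - 1 - k];
    path(k, 2) = ps_[L - 1 - k] + 1; // 1-based internal state for R
  }
  return List::create(_["path"] = path, _["score"] = best);
}

// [[Rcpp::export]]
List cpp_forward_backward(NumericVector theta, IntegerVector dims,
                          LogicalMatrix f7, NumericMatrix s7,
                          bool want_edges) {
  const int n1 = dims[0], n2 = dims[1];
  Grid F(n1, n2), B(n1, n2);
  double buf[NS + 1];
  // forward
  for (int i = 0; i <= n1; ++i) {
    for (int j = 0; j <= n2; ++j) {
      for (int s = 0; s < NS; ++s) {
        const int pi = i - DX[s], pj = j - DY[s];
        if (pi < 0 || pj < 0) continue;
        int nc = 0;
        if (pi == 0 && pj == 0 && is_start(s)) buf[nc++] = 0.0;
        for (int p = 0; p < NS; ++p)
          if (f7(p, s)) buf[nc++] = F.at(pi, pj, p) + s7(p, s);
        if (nc == 0) continue;
        const double v = lse(buf, nc);
        if (v == NEG_INF) continue;
        F.at(i, j, s) = v + emission(theta, n1, n2, i, j, s);
      }
    }
  }
  int nc = 0;
  for (int s = 0; s < NS; ++s)
    if (is_end(s)) buf[nc++] = F.at(n1, n2, s);
  const double logZ = lse(buf, nc);
  if (!std::isfinite(logZ)) stop("partition function underflow/overflow");
  // backward (B excludes the cell's own emission)
  for (int i = n1; i >= 0; --i) {
    for (int j = n2; j >= 0; --j) {
      for (int p = 0; p < NS; ++p) {
        int m = 0;
        if (i == n1 && j == n2 && is_end(p)) buf[m++] = 0.0;
        for (int s = 0; s < NS; ++s) {
          if (!f7(p, s)) continue;
          const int ni = i + DX[s], nj = j + DY[s];
          if (ni > n1 || nj > n2) continue;
          const double b = B.at(ni, nj, s);
          if (b == NEG_INF) continue;
          buf[m++] = s7(p, s) + emission(theta, n1, n2, ni, nj, s) + b;
        }
        if (m > 0) B.at(i, j, p) = lse(buf, m);
      }
    }
  }
  // expected indicator count per theta cell (i, j, u5)
  NumericVector post((size_t)n1 * n2 * 5, 0.0);
  post.attr("dim") = IntegerVector::create(n1, n2, 5);
  for (int i = 0; i <= n1; ++i) {
    for (int j = 0; j <= n2; ++j) {
      for (int s = 0; s < NS; ++s) {
        const double f = F.at(i, j, s);
        if (f == NEG_INF) continue;
        const double b = B.at(i, j, s);
        if (b == NEG_INF) continue;
        const int ii = i < 1 ? 0 : i - 1;
        const int jj = j < 1 ? 0 : j - 1;
        post[(size_t)U5[s] * n1 * n2 + (size_t)jj * n1 + ii] +=
          std::exp(f + b - logZ);
      }
    }
  }
  NumericMatrix edges(5, 5);
  if (want_edges) {
    for (int i = 0; i <= n1; ++i) {
      for (int j = 0; j <= n2; ++j) {
        for (int p = 0; p < NS; ++p) {
          const double f = F.at(i, j, p);
          if (f == NEG_INF) continue;
          for (int s = 0; s < NS; ++s) {
            if (!f7(p, s)) continue;
            const int ni = i + DX[s], nj = j + DY[s];
            if (ni > n1 || nj > n2) continue;
            const double b = B.at(ni, nj, s);
            if (b == NEG_INF) continue;
            edges(U5[p], U5[s]) += std::exp(
              f + s7(p, s) + emission(theta, n1, n2, ni, nj, s) + b - logZ);
          }
        }
      }
    }
  }
  return List::create(_["logZ"] = logZ, _["post"] = post,
                      _["edges"] = edges);
}
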