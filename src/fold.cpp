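// Single-sequence Nussinov-level folding engines.
//
// Nucleotides are encoded 0=A, 1=C, 2=G, 3=U.  `pairsc` is a 4x4 matrix of
// pair free energies (kcal/mol, negative = stabilizing) with NA for
// disallowed pairs.  `h` is the minimum number of unpaired nucleotides
// enclosed by a hairpin: a pair (i, j) (1-based) requires j - i > h.
// All partition-function arithmetic is in log space.

#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();
static const double POS_INF = std::numeric_limits<double>::infinity();

// log(exp(a) + exp(b)) without overflow
static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = (a > b) ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

struct PairTable {
  double sc[4][4];
  bool ok[4][4];
  explicit PairTable(const NumericMatrix& pairsc) {
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) {
        double v = pairsc(a, b);
        ok[a][b] = !NumericMatrix::is_na(v);
        sc[a][b] = ok[a][b] ? v : POS_INF;
      }
  }
};

// ---------------------------------------------------------------------------
// Minimum free energy (Viterbi) with (energy, #pairs) tie-break key and a
// deterministic traceback: unpaired extension is preferred, then the
// smallest pairing partner k.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List nussinov_mfe_cpp(IntegerVector seq, NumericMatrix pairsc, int h) {
  const int n = seq.size();
  PairTable pt(pairsc);
  // spans (i, j), 0-based inclusive; empty span value 0
  std::vector<double> E((size_t)n * n, 0.0);
  std::vector<int> NP((size_t)n * n, 0);
  std::vector<int> CH((size_t)n * n, -2); // -2 empty/base, -1 j unpaired, k>=0 pair (k, j)
  auto id = [n](int i, int j) { return (size_t)i * n + j; };
  auto val = [&](int i, int j) { return (j < i) ? 0.0 : E[id(i, j)]; };
  auto np = [&](int i, int j) { return (j < i) ? 0 : NP[id(i, j)]; };
  const double eps = 1e-9;

  for (int d = 1; d <= n; ++d) {
    for (int i = 0; i + d - 1 < n; ++i) {
      int j = i + d - 1;
      if (i == j) { E[id(i, j)] = 0.0; NP[id(i, j)] = 0; CH[id(i, j)] = -1; continue; }
      double best = val(i, j - 1);
      int bestnp = np(i, j - 1);
      int choice = -1;
      for (int k = i; k <= j - h - 1; ++k) {
        int a = seq[k], b = seq[j];
        if (!pt.ok[a][b]) continue;
        double cand = val(i, k - 1) + pt.sc[a][b] + val(k + 1, j - 1);
        int candnp = np(i, k - 1) + 1 + np(k + 1, j - 1);
        if (cand < best - eps ||
            (std::fabs(cand - best) <= eps && candnp < bestnp)) {
          best = cand; bestnp = candnp; choice = k;
        }
      }
      E[id(i, j)] = best; NP[id(i, j)] = bestnp; CH[id(i, j)] = choice;
    }
  }

  // traceback
  std::vector<std::pair<int, int> > pairs;
  std::vector<std::pair<int, int> > stack;
  if (n > 0) stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j <= i) continue;
    int c = CH[id(i, j)];
    if (c < 0) {
      stack.push_back(std::make_pair(i, j - 1));
    } else {
      pairs.push_back(std::make_pair(c + 1, j + 1)); // 1-based
      if (c - 1 >= i) stack.push_back(std::make_pair(i, c - 1));
      stack.push_back(std::make_pair(c + 1, j - 1));
    }
  }
  std::sort(pairs.begin(), pairs.end());
  IntegerMatrix pm(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    pm(r, 0) = pairs[r].first;
    pm(r, 1) = pairs[r].second;
  }
  double emin = (n > 0) ? E[id(0, n - 1)] : 0.0;
  return List::create(_["energy"] = emin, _["pairs"] = pm);
}

// ---------------------------------------------------------------------------
// Partition function + base-pairing probabilities (inside-outside).
// Q(i,j) = Q(i,j-1) + sum_k Q(i,k-1) * w(k,j) * Q(k+1,j-1),  w = exp(-dG/RT).
// p(k,j) * Q = sum_i O(i,j) * Q(i,k-1) * w(k,j) * Q(k+1,j-1).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List nussinov_pf_cpp(IntegerVector seq, NumericMatrix pairsc, int h, double RT) {
  const int n = seq.size();
  PairTable pt(pairsc);
  auto id = [n](int i, int j) { return (size_t)i * n + j; };
  std::vector<double> Z((size_t)n * n, 0.0); // log inside; empty span -> 0
  auto zval = [&](int i, int j) { return (j < i) ? 0.0 : Z[id(i, j)]; };

  for (int d = 2; d <= n; ++d) {
    for (int i = 0; i + d - 1 < n; ++i) {
      int j = i + d - 1;
      double acc = zval(i, j - 1);
      for (int k = i; k <= j - h - 1; ++k) {
        int a = seq[k], b = seq[j];
        if (!pt.ok[a][b]) continue;
        double lw = -pt.sc[a][b] / RT;
        acc = lse2(acc, zval(i, k - 1) + lw + zval(k + 1, j - 1));
      }
      Z[id(i, j)] = acc;
    }
  }
  double logQ = (n > 0) ? zval(0, n - 1) : 0.0;

  // outside
  std::vector<double> O((size_t)n * n, NEG_INF);
  std::vector<double> LP((size_t)n * n, NEG_INF); // log pair marginal mass
  if (n > 0) O[id(0, n - 1)] = 0.0;
  for (int d = n; d >= 2; --d) {
    for (int i = 0; i + d - 1 < n; ++i) {
      int j = i + d - 1;
      double o = O[id(i, j)];
      if (o == NEG_INF) continue;
      // j unpaired
      if (j - 1 >= i) O[id(i, j - 1)] = lse2(O[id(i, j - 1)], o);
      for (int k = i; k <= j - h - 1; ++k) {
        int a = seq[k], b = seq[j];
        if (!pt.ok[a][b]) continue;
        double lw = -pt.sc[a][b] / RT;
        double zl = zval(i, k - 1), zi = zval(k + 1, j - 1);
        LP[id(k, j)] = lse2(LP[id(k, j)], o + lw + zl + zi);
        if (k - 1 >= i) O[id(i, k - 1)] = lse2(O[id(i, k - 1)], o + lw + zi);
        if (j - 1 >= k + 1) O[id(k + 1, j - 1)] = lse2(O[id(k + 1, j - 1)], o + lw + zl);
      }
    }
  }

  NumericMatrix bpp(n, n);
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      int a = (i < j) ? i : j, b = (i < j) ? j : i;
      double lp = LP[id(a, b)];
      double p = (lp == NEG_INF) ? 0.0 : std::exp(lp - logQ);
      bpp(i, j) = p;
      tot += p;
    }
    bpp(i, i) = 1.0 - tot;
  }
  return List::create(_["logQ"] = logQ, _["bpp"] = bpp);
}
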