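// Lattice-parsing engines over the codon DFA.
//
// The lattice is layered: offsets 0..L (L = 3 * n_codons), `nstates[o]`
// states at offset o, and edges (offset, from, nuc, to) each advancing one
// offset.  Items are spans (i, a, j, b): state a at offset i to state b at
// offset j, covering nucleotide positions i+1..j (1-based).  The
// Nussinov-style recursion conditions on the last position j: either
// unpaired, or paired with position s+1 (j - (s+1) > h).
//
// Viterbi (min energy over paths x structures) yields the joint MFE design;
// the inside sum with per-edge log-probabilities log_tau yields the log
// expected partition function log Qtilde; the outside pass gives
// d Qtilde / d tau_e per edge (log magnitudes; the derivative of a
// multilinear form with nonnegative coefficients, hence nonnegative).
//
// Beam pruning: once the spans ending at offset j are filled, the state
// pairs (a, b) competing for the same offset cell (i, j) are ranked and
// only the top `beam` survive; beam <= 0 means exact.  The ranking score
// is the inside value plus the forward path log-probability of reaching
// the start state (the lattice analogue of prefix-score ranking in
// left-to-right beam search); ties break by state ids.  A one-hot
// distribution therefore keeps exactly its on-path state pair per cell at
// any width -- zero-probability branches prune first -- and search error
// is paid only where the distribution is soft.  Empty spans are never
// pruned.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();
static const double POS_INF = std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = (a > b) ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

namespace {

struct Lattice {
  int L;
  std::vector<int> nstates;              // length L+1
  std::vector<std::vector<int> > out;    // edge ids by source offset
  std::vector<int> e_from, e_nuc, e_to, e_off;
  int maxs;

  Lattice(int L_, const IntegerVector& ns, const IntegerMatrix& edges)
      : L(L_), nstates(ns.begin(), ns.end()), out(L_) {
    int m = edges.nrow();
    e_from.resize(m); e_nuc.resize(m); e_to.resize(m); e_off.resize(m);
    for (int e = 0; e < m; ++e) {
      e_off[e] = edges(e, 0);
      e_from[e] = edges(e, 1);
      e_nuc[e] = edges(e, 2);
      e_to[e] = edges(e, 3);
      out[e_off[e]].push_back(e);
    }
    maxs = 1;
    for (int o = 0; o <= L; ++o) maxs = std::max(maxs, nstates[o]);
  }

  size_t idx(int i, int a, int j, int b) const {
    return (((size_t)i * maxs + a) * (L + 1) + j) * maxs + b;
  }
  size_t nitems() const { return (size_t)(L + 1) * maxs * (L + 1) * maxs; }
};

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

// rank the state-pair items of every cell (i, j) and discard all but the
// top `beam`; pruned items are flagged so later passes skip them entirely
template <typename Better>
void prune_offset(const Lattice& lat, std::vector<double>& V,
                  const std::vector<double>& fwd,
                  std::vector<unsigned char>& pruned, int j, int beam,
                  double dead, Better better) {
  if (beam <= 0) return;
  struct Item { double v; int a, b; };
  std::vector<Item> items;
  for (int i = 0; i < j; ++i) {
    items.clear();
    for (int a = 0; a < lat.nstates[i]; ++a)
      for (int b = 0; b < lat.nstates[j]; ++b) {
        double v = V[lat.idx(i, a, j, b)];
        if (v != dead) items.push_back(Item{v + fwd[i * lat.maxs + a], a, b});
      }
    if ((int)items.size() <= beam) continue;
    std::sort(items.begin(), items.end(), [&](const Item& x, const Item& y) {
      if (x.v != y.v) return better(x.v, y.v);
      if (x.a != y.a) return x.a < y.a;
      return x.b < y.b;
    });
    for (size_t r = beam; r < items.size(); ++r) {
      size_t p = lat.idx(i, items[r].a, j, items[r].b);
      V[p] = dead;
      pruned[p] = 1;
    }
  }
}

// inside pass; fills B (log values) and the pruned flags, returns log Qtilde
double inside_pass(const Lattice& lat, const PairTable& pt,
                   const std::vector<double>& lt, int h, double RT,
                   int beam, std::vector<double>& B,
                   std::vector<unsigned char>& pruned) {
  const int L = lat.L;
  B.assign(lat.nitems(), NEG_INF);
  pruned.assign(lat.nitems(), 0);
  for (int i = 0; i <= L; ++i)
    for (int a = 0; a < lat.nstates[i]; ++a) B[lat.idx(i, a, i, a)] = 0.0;

  // forward path log-probabilities, used only to rank items for pruning
  std::vector<double> fwd((size_t)(L + 1) * lat.maxs, NEG_INF);
  fwd[0] = 0.0;
  if (beam > 0)
    for (int o = 0; o < L; ++o)
      for (size_t t = 0; t < lat.out[o].size(); ++t) {
        int e = lat.out[o][t];
        size_t dst = (size_t)(o + 1) * lat.maxs + lat.e_to[e];
        fwd[dst] = lse2(fwd[dst], fwd[(size_t)o * lat.maxs + lat.e_from[e]] + lt[e]);
      }

  for (int j = 1; j <= L; ++j) {
    for (int i = j - 1; i >= 0; --i) {
      for (int a = 0; a < lat.nstates[i]; ++a) {
        for (int e2idx = 0; e2idx < (int)lat.out[j - 1].size(); ++e2idx) {
          int e2 = lat.out[j - 1][e2idx];
          int r = lat.e_from[e2], y = lat.e_nuc[e2], b = lat.e_to[e2];
          double lt2 = lt[e2];
          size_t tgt = lat.idx(i, a, j, b);
          // position j unpaired
          double base = B[lat.idx(i, a, j - 1, r)];
          if (base != NEG_INF) B[tgt] = lse2(B[tgt], base + lt2);
          // position j paired with position s+1
          for (int s = i; s <= j - 2 - h; ++s) {
            for (int u = 0; u < lat.nstates[s]; ++u) {
              double Bl = B[lat.idx(i, a, s, u)];
              if (Bl == NEG_INF) continue;
              for (size_t t = 0; t < lat.out[s].size(); ++t) {
                int e1 = lat.out[s][t];
                if (lat.e_from[e1] != u) continue;
                int z = lat.e_nuc[e1], u2 = lat.e_to[e1];
                if (!pt.ok[z][y]) continue;
                double Bi = B[lat.idx(s + 1, u2, j - 1, r)];
                if (Bi == NEG_INF) continue;
                B[tgt] = lse2(B[tgt],
                              Bl + lt[e1] - pt.sc[z][y] / RT + Bi + lt2);
              }
            }
          }
        }
      }
    }
    prune_offset(lat, B, fwd, pruned, j, beam, NEG_INF,
                 [](double x, double y) { return x > y; });
  }
  return B[lat.idx(0, 0, L, 0)];
}

} // namespace

// [[Rcpp::export]]
double lattice_inside_cpp(int L, IntegerVector nstates, IntegerMatrix edges,
                          NumericVector log_tau, NumericMatrix pairsc,
                          int h, double RT, int beam) {
  Lattice lat(L, nstates, edges);
  PairTable pt(pairsc);
  std::vector<double> ltv(log_tau.begin(), log_tau.end());
  std::vector<double> B;
  std::vector<unsigned char> pruned;
  return inside_pass(lat, pt, ltv, h, RT, beam, B, pruned);
}

// [[Rcpp::export]]
List lattice_grad_cpp(int L, IntegerVector nstates, IntegerMatrix edges,
                      NumericVector log_tau, NumericMatrix pairsc,
                      int h, double RT, int beam) {
  Lattice lat(L, nstates, edges);
  PairTable pt(pairsc);
  std::vector<double> ltv(log_tau.begin(), log_tau.end());
  std::vector<double> B;
  std::vector<unsigned char> pruned;
  double logQ = inside_pass(lat, pt, ltv, h, RT, beam, B, pruned);

  // Outside pass.  Note: items with zero inside mass still carry outside
  // mass, and must distribute it -- a parameter with tau = 0 has a nonzero
  // derivative (differentiation removes that tau factor), so gradient
  // routes may pass through zero-probability subderivations.  Only items
  // removed by beam pruning are skipped.
  const int m = edges.nrow();
  std::vector<double> O(lat.nitems(), NEG_INF);
  std::vector<double> G((size_t)m, NEG_INF);
  O[lat.idx(0, 0, L, 0)] = 0.0;

  for (int j = L; j >= 1; --j) {
    for (int i = 0; i < j; ++i) {
      for (int a = 0; a < lat.nstates[i]; ++a) {
        for (int b = 0; b < lat.nstates[j]; ++b) {
          size_t p = lat.idx(i, a, j, b);
          double o = O[p];
          if (o == NEG_INF || pruned[p]) continue;
          for (size_t t2 = 0; t2 < lat.out[j - 1].size(); ++t2) {
            int e2 = lat.out[j - 1][t2];
            if (lat.e_to[e2] != b) continue;
            int r = lat.e_from[e2], y = lat.e_nuc[e2];
            double lt2 = ltv[e2];
            // unpaired extension: the child's context carries no B factor
            size_t c = lat.idx(i, a, j - 1, r);
            if (!pruned[c]) {
              O[c] = lse2(O[c], o + lt2);
              if (B[c] != NEG_INF) G[e2] = lse2(G[e2], o + B[c]);
            }
            // pair (s+1, j)
            for (int s = i; s <= j - 2 - h; ++s) {
              for (int u = 0; u < lat.nstates[s]; ++u) {
                size_t cl = lat.idx(i, a, s, u);
                if (pruned[cl]) continue;
                double Bl = B[cl];
                for (size_t t1 = 0; t1 < lat.out[s].size(); ++t1) {
                  int e1 = lat.out[s][t1];
                  if (lat.e_from[e1] != u) continue;
                  int z = lat.e_nuc[e1], u2 = lat.e_to[e1];
                  if (!pt.ok[z][y]) continue;
                  double lw = -pt.sc[z][y] / RT;
                  size_t ci = lat.idx(s + 1, u2, j - 1, r);
                  if (pruned[ci]) continue;
                  double Bi = B[ci];
                  if (Bi != NEG_INF)
                    O[cl] = lse2(O[cl], o + ltv[e1] + lt2 + lw + Bi);
                  if (Bl != NEG_INF)
                    O[ci] = lse2(O[ci], o + ltv[e1] + lt2 + lw + Bl);
                  if (Bl != NEG_INF && Bi != NEG_INF) {
                    G[e1] = lse2(G[e1], o + lt2 + lw + Bl + Bi);
                    G[e2] = lse2(G[e2], o + ltv[e1] + lw + Bl + Bi);
                  }
                }
              }
            }
          }
        }
      }
    }
  }

  NumericVector logg(m);
  for (int e = 0; e < m; ++e) logg[e] = G[e];
  return List::create(_["logQ"] = logQ, _["log_grad"] = logg);
}

// [[Rcpp::export]]
List lattice_viterbi_cpp(int L, IntegerVector nstates, IntegerMatrix edges,
                         NumericMatrix pairsc, int h, int beam) {
  Lattice lat(L, nstates, edges);
  PairTable pt(pairsc);
  std::vector<double> V(lat.nitems(), POS_INF);
  std::vector<double> vfwd((size_t)(L + 1) * lat.maxs, 0.0); // paths carry no energy
  std::vector<unsigned char> vpruned(lat.nitems(), 0);
  std::vector<int> bpE1(lat.nitems(), -9), bpE2(lat.nitems(), -9);
  for (int i = 0; i <= L; ++i)
    for (int a = 0; a < lat.nstates[i]; ++a) V[lat.idx(i, a, i, a)] = 0.0;

  for (int j = 1; j <= L; ++j) {
    for (int i = j - 1; i >= 0; --i) {
      for (int a = 0; a < lat.nstates[i]; ++a) {
        // unpaired candidates first (preferred on ties), then pairs
        for (size_t t2 = 0; t2 < lat.out[j - 1].size(); ++t2) {
          int e2 = lat.out[j - 1][t2];
          int r = lat.e_from[e2], b = lat.e_to[e2];
          size_t tgt = lat.idx(i, a, j, b);
          double base = V[lat.idx(i, a, j - 1, r)];
          if (base < V[tgt]) { V[tgt] = base; bpE1[tgt] = -1; bpE2[tgt] = e2; }
        }
        for (size_t t2 = 0; t2 < lat.out[j - 1].size(); ++t2) {
          int e2 = lat.out[j - 1][t2];
          int r = lat.e_from[e2], y = lat.e_nuc[e2], b = lat.e_to[e2];
          size_t tgt = lat.idx(i, a, j, b);
          for (int s = i; s <= j - 2 - h; ++s) {
            for (int u = 0; u < lat.nstates[s]; ++u) {
              double Vl = V[lat.idx(i, a, s, u)];
              if (Vl == POS_INF) continue;
              for (size_t t1 = 0; t1 < lat.out[s].size(); ++t1) {
                int e1 = lat.out[s][t1];
                if (lat.e_from[e1] != u) continue;
                int z = lat.e_nuc[e1], u2 = lat.e_to[e1];
                if (!pt.ok[z][y]) continue;
                double Vi = V[lat.idx(s + 1, u2, j - 1, r)];
                if (Vi == POS_INF) continue;
                double cand = Vl + pt.sc[z][y] + Vi;
                if (cand < V[tgt]) { V[tgt] = cand; bpE1[tgt] = e1; bpE2[tgt] = e2; }
              }
            }
          }
        }
      }
    }
    prune_offset(lat, V, vfwd, vpruned, j, beam, POS_INF,
                 [](double x, double y) { return x < y; });
  }

  size_t goal = lat.idx(0, 0, L, 0);
  if (V[goal] == POS_INF)
    stop("lattice Viterbi search failed (goal item pruned or unreachable)");

  // traceback
  IntegerVector seq(L, -1);
  std::vector<std::pair<int, int> > pairs;
  struct Node { int i, a, j, b; };
  std::vector<Node> stack;
  stack.push_back(Node{0, 0, L, 0});
  while (!stack.empty()) {
    Node nd = stack.back();
    stack.pop_back();
    if (nd.j <= nd.i) continue;
    size_t p = lat.idx(nd.i, nd.a, nd.j, nd.b);
    int e1 = bpE1[p], e2 = bpE2[p];
    if (e2 < 0) stop("lattice Viterbi traceback hit an unset item");
    if (e1 == -1) {
      seq[nd.j - 1] = lat.e_nuc[e2];
      stack.push_back(Node{nd.i, nd.a, nd.j - 1, lat.e_from[e2]});
    } else {
      int s = lat.e_off[e1];
      seq[s] = lat.e_nuc[e1];
      seq[nd.j - 1] = lat.e_nuc[e2];
      pairs.push_back(std::make_pair(s + 1, nd.j));
      stack.push_back(Node{nd.i, nd.a, s, lat.e_from[e1]});
      stack.push_back(Node{s + 1, lat.e_to[e1], nd.j - 1, lat.e_from[e2]});
    }
  }
  std::sort(pairs.begin(), pairs.end());
  IntegerMatrix pm(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    pm(r, 0) = pairs[r].first;
    pm(r, 1) = pairs[r].second;
  }
  return List::create(_["energy"] = V[goal], _["seq"] = seq, _["pairs"] = pm);
}
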