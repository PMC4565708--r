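// Exact branch-and-bound search for all most-parsimonious unrooted binary
// trees under Fitch parsimony on a 0/1 character matrix.
//
// Taxa are added in input order (the R wrapper fixes sorted-label order, so
// the search is deterministic). Character state sets are kept as two bit
// words per node (state 0 present / state 1 present), 64 characters per
// word. The lower bound for a partial tree is its Fitch length plus one
// change for every (character, state) pair present among the taxa not yet
// added but absent from the taxa already placed.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <set>
using namespace Rcpp;

namespace {

struct Matrix01 {
  int n;        // taxa
  int m;        // characters
  int W;        // 64-bit words per state set
  // tip state sets: tip * W + w
  std::vector<uint64_t> s0, s1;
  uint64_t lastmask;
};

inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

class BabSearch {
public:
  Matrix01 mat;
  int n;
  // adjacency as edge list; node ids: tips 0..n-1, internals n..2n-3
  std::vector<std::pair<int,int>> edges;
  // prefix/suffix state presence per word
  std::vector<uint64_t> pre0, pre1, suf0, suf1;
  int best;
  long long count;
  int max_trees;
  bool overflow;
  std::vector<IntegerMatrix> stored;
  std::set<std::vector<uint64_t>> consensus; // running split intersection
  bool consensus_init;
  int tw; // words for taxon bitmasks

  // scratch for scoring
  std::vector<std::vector<int>> adj;
  std::vector<uint64_t> node0, node1;
  std::vector<int> order, parent;

  BabSearch(const IntegerMatrix& states, int max_trees_)
      : best(INT_MAX), count(0), max_trees(max_trees_), overflow(false),
        consensus_init(false) {
    n = states.nrow();
    mat.n = n;
    mat.m = states.ncol();
    mat.W = (mat.m + 63) / 64;
    mat.lastmask = (mat.m % 64) ? ((1ULL << (mat.m % 64)) - 1ULL)
                                : ~0ULL;
    mat.s0.assign((size_t)n * mat.W, 0);
    mat.s1.assign((size_t)n * mat.W, 0);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < mat.m; ++j) {
        int v = states(i, j);
        uint64_t bit = 1ULL << (j % 64);
        size_t idx = (size_t)i * mat.W + j / 64;
        if (v == NA_INTEGER) { mat.s0[idx] |= bit; mat.s1[idx] |= bit; }
        else if (v == 0) mat.s0[idx] |= bit;
        else mat.s1[idx] |= bit;
      }
    // prefix unions over taxa [0, k), suffix over [k, n)
    pre0.assign((size_t)(n + 1) * mat.W, 0);
    pre1.assign((size_t)(n + 1) * mat.W, 0);
    suf0.assign((size_t)(n + 1) * mat.W, 0);
    suf1.assign((size_t)(n + 1) * mat.W, 0);
    for (int k = 0; k < n; ++k)
      for (int w = 0; w < mat.W; ++w) {
        pre0[(size_t)(k + 1) * mat.W + w] =
          pre0[(size_t)k * mat.W + w] | mat.s0[(size_t)k * mat.W + w];
        pre1[(size_t)(k + 1) * mat.W + w] =
          pre1[(size_t)k * mat.W + w] | mat.s1[(size_t)k * mat.W + w];
      }
    for (int k = n - 1; k >= 0; --k)
      for (int w = 0; w < mat.W; ++w) {
        suf0[(size_t)k * mat.W + w] =
          suf0[(size_t)(k + 1) * mat.W + w] | mat.s0[(size_t)k * mat.W + w];
        suf1[(size_t)k * mat.W + w] =
          suf1[(size_t)(k + 1) * mat.W + w] | mat.s1[(size_t)k * mat.W + w];
      }
    int nn = 2 * n - 2;
    adj.assign(nn, {});
    node0.assign((size_t)nn * mat.W, 0);
    node1.assign((size_t)nn * mat.W, 0);
    order.reserve(nn);
    parent.assign(nn, -1);
    tw = (n + 63) / 64;
  }

  // Fitch length of the current partial tree (taxa 0..k-1 placed)
  int fitch_current() {
    int nn = 2 * n - 2;
    for (int v = 0; v < nn; ++v) adj[v].clear();
    for (auto& e : edges) { adj[e.first].push_back(e.second);
                            adj[e.second].push_back(e.first); }
    // iterative postorder from internal node n (always present, degree >= 3)
    order.clear();
    std::vector<int> stack{n};
    parent[n] = -1;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      order.push_back(v);
      for (int u : adj[v]) if (u != parent[v]) { parent[u] = v; stack.push_back(u); }
    }
    int score = 0;
    for (int i = (int)order.size() - 1; i >= 0; --i) {
      int v = order[i];
      if (v < n) {
        for (int w = 0; w < mat.W; ++w) {
          node0[(size_t)v * mat.W + w] = mat.s0[(size_t)v * mat.W + w];
          node1[(size_t)v * mat.W + w] = mat.s1[(size_t)v * mat.W + w];
        }
        continue;
      }
      bool first = true;
      for (int u : adj[v]) {
        if (u == parent[v]) continue;
        if (first) {
          for (int w = 0; w < mat.W; ++w) {
            node0[(size_t)v * mat.W + w] = node0[(size_t)u * mat.W + w];
            node1[(size_t)v * mat.W + w] = node1[(size_t)u * mat.W + w];
          }
          first = false;
        } else {
          for (int w = 0; w < mat.W; ++w) {
            uint64_t a0 = node0[(size_t)v * mat.W + w];
            uint64_t a1 = node1[(size_t)v * mat.W + w];
            uint64_t b0 = node0[(size_t)u * mat.W + w];
            uint64_t b1 = node1[(size_t)u * mat.W + w];
            uint64_t i0 = a0 & b0, i1 = a1 & b1;
            uint64_t nonempty = i0 | i1;
            uint64_t valid = (w == mat.W - 1) ? mat.lastmask : ~0ULL;
            uint64_t empty = ~nonempty & valid;
            score += popcount64(empty);
            node0[(size_t)v * mat.W + w] = i0 | (empty & (a0 | b0));
            node1[(size_t)v * mat.W + w] = i1 | (empty & (a1 | b1));
          }
        }
      }
    }
    return score;
  }

  // lower bound on extra changes from taxa not yet placed
  int remaining_bound(int k) {
    int b = 0;
    for (int w = 0; w < mat.W; ++w) {
      b += popcount64(suf0[(size_t)k * mat.W + w] &
                      ~pre0[(size_t)k * mat.W + w]);
      b += popcount64(suf1[(size_t)k * mat.W + w] &
                      ~pre1[(size_t)k * mat.W + w]);
    }
    return b;
  }

  // canonical nontrivial splits of the current (complete) tree, as taxon
  // bitmask vectors not containing taxon 0
  std::set<std::vector<uint64_t>> current_splits() {
    int nn = 2 * n - 2;
    std::vector<std::vector<int>> a(nn);
    for (auto& e : edges) { a[e.first].push_back(e.second);
                            a[e.second].push_back(e.first); }
    std::set<std::vector<uint64_t>> out;
    for (auto& e : edges) {
      if (e.first < n || e.second < n) continue; // trivial split
      // taxa on the e.first side, not crossing e.second
      std::vector<uint64_t> mask(tw, 0);
      int cnt = 0;
      std::vector<std::pair<int,int>> stack{{e.first, e.second}};
      while (!stack.empty()) {
        auto pr = stack.back(); stack.pop_back();
        int v = pr.first, from = pr.second;
        if (v < n) { mask[v / 64] |= (1ULL << (v % 64)); ++cnt; }
        for (int u : a[v]) if (u != from) stack.push_back({v >= n ? u : u, v});
      }
      if (cnt < 2 || cnt > n - 2) continue;
      if (mask[0] & 1ULL) {                 // canonicalize: drop taxon 0 side
        for (int w = 0; w < tw; ++w) mask[w] = ~mask[w];
        uint64_t last = (n % 64) ? ((1ULL << (n % 64)) - 1ULL) : ~0ULL;
        mask[tw - 1] &= last;
      }
      out.insert(mask);
    }
    return out;
  }

  void record() {
    ++count;
    std::set<std::vector<uint64_t>> sp = current_splits();
    if (!consensus_init) { consensus = sp; consensus_init = true; }
    else {
      std::set<std::vector<uint64_t>> inter;
      for (auto& s : consensus) if (sp.count(s)) inter.insert(s);
      consensus.swap(inter);
    }
    if ((long long)stored.size() < max_trees) {
      IntegerMatrix em(edges.size(), 2);
      for (size_t i = 0; i < edges.size(); ++i) {
        em(i, 0) = edges[i].first + 1;
        em(i, 1) = edges[i].second + 1;
      }
      stored.push_back(em);
    } else overflow = true;
  }

  void reset_best(int score) {
    best = score;
    count = 0;
    stored.clear();
    consensus_init = false;
    overflow = false;
  }

  void search(int k, bool greedy_only = false) {
    if (k == n) {
      int s = fitch_current();
      if (s < best) reset_best(s);
      if (s == best && !greedy_only) record();
      return;
    }
    int nb = remaining_bound(k + 1);  // bound for taxa after the one placed here
    size_t ne = edges.size();
    int best_edge = -1, best_partial = INT_MAX;
    std::vector<int> partials(ne);
    for (size_t i = 0; i < ne; ++i) {
      std::pair<int,int> old = edges[i];
      int w = n + k - 2;
      edges[i] = {old.first, w};
      edges.push_back({w, old.second});
      edges.push_back({k, w});
      int s = fitch_current();
      partials[i] = s;
      if (s < best_partial) { best_partial = s; best_edge = (int)i; }
      edges.pop_back();
      edges.pop_back();
      edges[i] = old;
    }
    if (greedy_only) {
      // descend only along the best edge to get an initial upper bound
      std::pair<int,int> old = edges[best_edge];
      int w = n + k - 2;
      edges[best_edge] = {old.first, w};
      edges.push_back({w, old.second});
      edges.push_back({k, w});
      search(k + 1, true);
      edges.pop_back();
      edges.pop_back();
      edges[best_edge] = old;
      return;
    }
    for (size_t i = 0; i < ne; ++i) {
      if (partials[i] + nb > best) continue;  // prune
      std::pair<int,int> old = edges[i];
      int w = n + k - 2;
      edges[i] = {old.first, w};
      edges.push_back({w, old.second});
      edges.push_back({k, w});
      search(k + 1, false);
      edges.pop_back();
      edges.pop_back();
      edges[i] = old;
    }
  }

  void run() {
    edges.clear();
    edges.push_back({0, n});
    edges.push_back({1, n});
    edges.push_back({2, n});
    if (n == 3) { int s = fitch_current(); reset_best(s); record(); return; }
    // greedy pass for an initial upper bound
    search(3, true);
    // full search (best now holds the greedy score)
    edges.clear();
    edges.push_back({0, n});
    edges.push_back({1, n});
    edges.push_back({2, n});
    search(3, false);
  }

  List splits_as_list() {
    List out(consensus.size());
    int i = 0;
    for (auto& s : consensus) {
      std::vector<int> taxa;
      for (int t = 0; t < n; ++t)
        if (s[t / 64] & (1ULL << (t % 64))) taxa.push_back(t + 1);
      out[i++] = wrap(taxa);
    }
    return out;
  }
};

} // namespace

// [[Rcpp::export(name = ".bab_cpp")]]
List bab_cpp(IntegerMatrix states, int max_trees = 100000) {
  int n = states.nrow();
  if (n < 3) stop("branch and bound requires at least 3 taxa");
  if (n > 64) stop("at most 64 taxa supported");
  BabSearch bs(states, max_trees);
  bs.run();
  List trees(bs.stored.size());
  for (size_t i = 0; i < bs.stored.size(); ++i) trees[i] = bs.stored[i];
  return List::create(
    _["score"] = bs.best,
    _["count"] = (double)bs.count,
    _["edges"] = trees,
    _["consensus_splits"] = bs.splits_as_list(),
    _["overflow"] = bs.overflow);
}
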