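#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Deterministic generator independent of R's RNG so that walk corpora and
// trained embeddings are byte-reproducible from the integer seed alone
// (splitmix64 stream).
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next_u64() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  // uniform double in [0, 1)
  double unif() { return (next_u64() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int unif_int(int n) {
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

// Vose alias table: O(n) build, O(1) draw.
struct AliasTable {
  std::vector<double> prob;
  std::vector<int> alias;

  void build(const std::vector<double>& w) {
    int n = static_cast<int>(w.size());
    prob.assign(n, 0.0);
    alias.assign(n, 0);
    double total = 0.0;
    for (double x : w) total += x;
    std::vector<double> scaled(n);
    std::vector<int> small, large;
    small.reserve(n);
    large.reserve(n);
    for (int i = 0; i < n; ++i) {
      scaled[i] = w[i] * n / total;
      if (scaled[i] < 1.0) small.push_back(i); else large.push_back(i);
    }
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = scaled[s];
      alias[s] = l;
      scaled[l] = scaled[l] + scaled[s] - 1.0;
      if (scaled[l] < 1.0) small.push_back(l); else large.push_back(l);
    }
    while (!large.empty()) { prob[large.back()] = 1.0; large.pop_back(); }
    while (!small.empty()) { prob[small.back()] = 1.0; small.pop_back(); }
  }

  int draw(SplitMix& rng) const {
    int i = rng.unif_int(static_cast<int>(prob.size()));
    return rng.unif() < prob[i] ? i : alias[i];
  }
};

static bool is_adjacent(const std::vector<std::vector<int> >& adj, int a, int b) {
  const std::vector<int>& nb = adj[a];
  return std::binary_search(nb.begin(), nb.end(), b);
}

// Second-order biased random walks (alias-sampled).
//
// adj:     per-node neighbor lists, 0-based, each sorted ascending
// wts:     parallel edge weights (ignored when weighted = false)
// p, q:    return and in-out parameters; step bias is 1/p toward the
//          previous node, 1 toward common neighbors of (prev, cur), 1/q
//          toward distance-2 nodes, multiplied by the edge weight when
//          weighted transitions are on
// r, l:    walks per node and walk length in nodes
//
// Each of the r epochs shuffles the start-node order (Fisher-Yates under
// the same stream) and starts one walk per node. Walks truncate at
// neighbourless nodes.
// [[Rcpp::export]]
List cpp_simulate_walks(List adj_r, List wts_r, double p, double q,
                        int r, int l, bool weighted, double seed) {
  int n = adj_r.size();
  std::vector<std::vector<int> > adj(n);
  std::vector<std::vector<double> > wts(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector a = adj_r[i];
    NumericVector w = wts_r[i];
    adj[i].assign(a.begin(), a.end());
    wts[i].assign(w.begin(), w.end());
  }

  SplitMix rng(static_cast<uint64_t>(seed) + 0x51ed270b4d2c3fULL);

  // First-order tables (first step of every walk).
  std::vector<AliasTable> first(n);
  for (int v = 0; v < n; ++v) {
    if (adj[v].empty()) continue;
    std::vector<double> w(adj[v].size(), 1.0);
    if (weighted) w = wts[v];
    first[v].build(w);
  }

  // Second-order tables, one per directed pair (prev -> cur), indexed by
  // prev's position in cur's neighbor list.
  std::vector<std::vector<AliasTable> > second(n);
  for (int cur = 0; cur < n; ++cur) {
    int deg = static_cast<int>(adj[cur].size());
    second[cur].resize(deg);
    for (int ti = 0; ti < deg; ++ti) {
      int prev = adj[cur][ti];
      std::vector<double> w(deg);
      for (int xi = 0; xi < deg; ++xi) {
        int x = adj[cur][xi];
        double bias;
        if (x == prev) bias = 1.0 / p;
        else if (is_adjacent(adj, prev, x)) bias = 1.0;
        else bias = 1.0 / q;
        w[xi] = bias * (weighted ? wts[cur][xi] : 1.0);
      }
      second[cur][ti].build(w);
    }
  }

  List out(static_cast<R_xlen_t>(n) * r);
  R_xlen_t wi = 0;
  std::vector<int> order(n);
  std::vector<int> walk;
  walk.reserve(l);
  for (int epoch = 0; epoch < r; ++epoch) {
    for (int i = 0; i < n; ++i) order[i] = i;
    for (int i = n - 1; i > 0; --i) std::swap(order[i], order[rng.unif_int(i + 1)]);
    for (int s = 0; s < n; ++s) {
      int start = order[s];
      walk.clear();
      walk.push_back(start);
      if (!adj[start].empty() && l >= 2) {
        int cur = adj[start][first[start].draw(rng)];
        walk.push_back(cur);
        while (static_cast<int>(walk.size()) < l) {
          if (adj[cur].empty()) break;
          int prev = walk[walk.size() - 2];
          int ti = static_cast<int>(std::lower_bound(adj[cur].begin(),
                                                     adj[cur].end(), prev) -
                                    adj[cur].begin());
          int nxt = adj[cur][second[cur][ti].draw(rng)];
          walk.push_back(nxt);
          cur = nxt;
        }
      }
      out[wi++] = IntegerVector(walk.begin(), walk.end());
    }
  }
  return out;
}

static inline double sigmoid_clipped(double x) {
  if (x > 6.0) return 1.0;
  if (x < -6.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over node walks, plain per-pair SGD with
// a linearly decaying learning rate (word2vec conventions: unigram^0.75
// negative distribution, uniform(-0.5, 0.5)/d input init, zero output init).
//
// walks: list of 0-based integer vectors over a vocabulary of n_nodes.
// Returns the input (center) vectors, n_nodes x d; rows for nodes that never
// occur in a walk are left at their random initialisation and flagged by a
// zero in the returned counts so the caller can drop them.
// [[Rcpp::export]]
List cpp_train_sgns(List walks_r, int n_nodes, int d, int window,
                    int negative, int epochs, double alpha0, double seed) {
  R_xlen_t n_walks = walks_r.size();
  std::vector<std::vector<int> > walks(n_walks);
  std::vector<double> counts(n_nodes, 0.0);
  long long total_tokens = 0;
  for (R_xlen_t i = 0; i < n_walks; ++i) {
    IntegerVector w = walks_r[i];
    walks[i].assign(w.begin(), w.end());
    for (int v : walks[i]) counts[v] += 1.0;
    total_tokens += walks[i].size();
  }

  SplitMix rng(static_cast<uint64_t>(seed) + 0x9e3779b9ULL);

  std::vector<double> noise(n_nodes);
  for (int v = 0; v < n_nodes; ++v) noise[v] = std::pow(counts[v], 0.75);
  AliasTable neg_table;
  neg_table.build(noise);

  std::vector<double> syn0(static_cast<size_t>(n_nodes) * d);
  std::vector<double> syn1(static_cast<size_t>(n_nodes) * d, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) syn0[i] = (rng.unif() - 0.5) / d;

  const double total_work = static_cast<double>(total_tokens) *
                            std::max(epochs, 1);
  const double min_alpha = alpha0 * 1e-4;
  double processed = 0.0;
  std::vector<double> grad_acc(d);

  for (int ep = 0; ep < epochs; ++ep) {
    for (R_xlen_t wi = 0; wi < n_walks; ++wi) {
      const std::vector<int>& walk = walks[wi];
      int len = static_cast<int>(walk.size());
      for (int i = 0; i < len; ++i) {
        double alpha = alpha0 * (1.0 - processed / total_work);
        if (alpha < min_alpha) alpha = min_alpha;
        processed += 1.0;
        int center = walk[i];
        double* v = &syn0[static_cast<size_t>(center) * d];
        int lo = i - window < 0 ? 0 : i - window;
        int hi = i + window >= len ? len - 1 : i + window;
        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          int context = walk[j];
          std::fill(grad_acc.begin(), grad_acc.end(), 0.0);
          for (int s = 0; s <= negative; ++s) {
            int target;
            double label;
            if (s == 0) { target = context; label = 1.0; }
            else {
              target = neg_table.draw(rng);
              if (target == context) continue;
              label = 0.0;
            }
            double* u = &syn1[static_cast<size_t>(target) * d];
            double dot = 0.0;
            for (int c = 0; c < d; ++c) dot += v[c] * u[c];
            double g = (label - sigmoid_clipped(dot)) * alpha;
            for (int c = 0; c < d; ++c) {
              grad_acc[c] += g * u[c];
              u[c] += g * v[c];
            }
          }
          for (int c = 0; c < d; ++c) v[c] += grad_acc[c];
        }
      }
    }
  }

  NumericMatrix emb(n_nodes, d);
  for (int vtx = 0; vtx < n_nodes; ++vtx)
    for (int c = 0; c < d; ++c)
      emb(vtx, c) = syn0[static_cast<size_t>(vtx) * d + c];
  return List::create(_["vectors"] = emb,
                      _["counts"] = NumericVector(counts.begin(), counts.end()));
}
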