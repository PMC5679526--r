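// Subgraph census machinery: exact ESU enumeration of connected induced
// k-subgraphs, leaf sampling on the ESU tree, and FANMOD-style canonical
// integer motif ids (minimum row-major adjacency integer over node
// permutations).

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

struct DiGraph {
  int n;
  std::vector<std::vector<int>> und;      // undirected neighbour lists
  std::unordered_set<long long> dir;      // directed edges a*n+b
  bool has(int a, int b) const {
    return dir.count((long long)a * n + b) > 0;
  }
};

static DiGraph build_graph(const IntegerVector& from, const IntegerVector& to,
                           int n) {
  DiGraph g;
  g.n = n;
  g.und.assign(n, {});
  std::vector<std::unordered_set<int>> uset(n);
  for (R_xlen_t i = 0; i < from.size(); ++i) {
    int a = from[i], b = to[i];
    if (a < 0 || b < 0 || a >= n || b >= n)
      stop("edge endpoint out of range");
    if (a == b) continue;
    g.dir.insert((long long)a * n + b);
    if (uset[a].insert(b).second) g.und[a].push_back(b);
    if (uset[b].insert(a).second) g.und[b].push_back(a);
  }
  return g;
}

static void all_perms(int k, std::vector<std::vector<int>>& out) {
  std::vector<int> p(k);
  for (int i = 0; i < k; ++i) p[i] = i;
  do { out.push_back(p); } while (std::next_permutation(p.begin(), p.end()));
}

// minimum row-major integer over all k! relabelings
static uint64_t canon_bits(uint64_t bits, int k,
                           const std::vector<std::vector<int>>& perms) {
  bool adj[8][8] = {{false}};
  for (int r = 0; r < k; ++r)
    for (int c = 0; c < k; ++c)
      adj[r][c] = (bits >> (uint64_t)(k * k - 1 - (k * r + c))) & 1ULL;
  uint64_t best = ~0ULL;
  for (const auto& p : perms) {
    uint64_t v = 0;
    for (int r = 0; r < k; ++r)
      for (int c = 0; c < k; ++c) {
        v <<= 1;
        if (adj[p[r]][p[c]]) v |= 1ULL;
      }
    if (v < best) best = v;
  }
  return best;
}

struct Census {
  const DiGraph& g;
  int k;
  std::vector<std::vector<int>> perms;
  std::unordered_map<uint64_t, uint64_t> canon_cache;
  std::unordered_map<uint64_t, double> tally;
  std::vector<int> sub;
  std::vector<char> visited;

  Census(const DiGraph& g_, int k_) : g(g_), k(k_) {
    all_perms(k, perms);
    visited.assign(g.n, 0);
  }

  uint64_t sub_bits() const {
    uint64_t bits = 0;
    for (int r = 0; r < k; ++r)
      for (int c = 0; c < k; ++c)
        if (r != c && g.has(sub[r], sub[c]))
          bits |= 1ULL << (uint64_t)(k * k - 1 - (k * r + c));
    return bits;
  }

  void record(double w) {
    uint64_t bits = sub_bits();
    auto it = canon_cache.find(bits);
    uint64_t id;
    if (it == canon_cache.end()) {
      id = canon_bits(bits, k, perms);
      canon_cache.emplace(bits, id);
    } else id = it->second;
    tally[id] += w;
  }

  // exact ESU extension
  void extend(std::vector<int>& ext, int root) {
    if ((int)sub.size() == (int)k) { record(1.0); return; }
    while (!ext.empty()) {
      int w = ext.back();
      ext.pop_back();
      std::vector<int> ext2 = ext;
      std::vector<int> newly;
      for (int u : g.und[w])
        if (u > root && !visited[u]) {
          visited[u] = 1;
          newly.push_back(u);
          ext2.push_back(u);
        }
      sub.push_back(w);
      extend(ext2, root);
      sub.pop_back();
      for (int u : newly) visited[u] = 0;
    }
  }

  void run_exact() {
    for (int v = 0; v < g.n; ++v) {
      std::fill(visited.begin(), visited.end(), 0);
      visited[v] = 1;
      std::vector<int> ext;
      for (int u : g.und[v])
        if (u > v) { visited[u] = 1; ext.push_back(u); }
      sub.assign(1, v);
      extend(ext, v);
    }
  }

  // one random root-to-leaf descent of the ESU tree; returns false on a
  // dead end.  weight accumulates the inverse path probability.
  bool descend(double& weight) {
    int v = (int)(unif_rand() * g.n);
    if (v >= g.n) v = g.n - 1;
    weight = (double)g.n;
    std::fill(visited.begin(), visited.end(), 0);
    visited[v] = 1;
    std::vector<int> ext;
    for (int u : g.und[v])
      if (u > v) { visited[u] = 1; ext.push_back(u); }
    sub.assign(1, v);
    while ((int)sub.size() < k) {
      if (ext.empty()) return false;
      int m = (int)ext.size();
      int idx = (int)(unif_rand() * m);
      if (idx >= m) idx = m - 1;
      weight *= (double)m;
      int w = ext[idx];
      // the chosen child keeps only the extension entries after idx,
      // mirroring the sibling order of the exact enumeration
      std::vector<int> ext2(ext.begin() + idx + 1, ext.end());
      for (int u : g.und[w])
        if (u > v && !visited[u]) { visited[u] = 1; ext2.push_back(u); }
      sub.push_back(w);
      ext.swap(ext2);
    }
    return true;
  }
};

static DataFrame tally_to_df(const std::unordered_map<uint64_t, double>& t) {
  std::vector<std::pair<uint64_t, double>> v(t.begin(), t.end());
  std::sort(v.begin(), v.end());
  NumericVector id(v.size()), count(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    id[i] = (double)v[i].first;
    count[i] = v[i].second;
  }
  return DataFrame::create(_["motif_id"] = id, _["count"] = count);
}

// [[Rcpp::export]]
DataFrame cpp_enumerate(IntegerVector from, IntegerVector to, int n, int k) {
  if (k < 2 || k > 7) stop("k must be in 2..7");
  DiGraph g = build_graph(from, to, n);
  Census c(g, k);
  c.run_exact();
  return tally_to_df(c.tally);
}

// [[Rcpp::export]]
DataFrame cpp_sample(IntegerVector from, IntegerVector to, int n, int k,
                     int n_samples) {
  if (k < 2 || k > 7) stop("k must be in 2..7");
  if (n_samples <= 0) stop("n_samples must be positive");
  DiGraph g = build_graph(from, to, n);
  Census c(g, k);
  for (int s = 0; s < n_samples; ++s) {
    double w = 0;
    if (c.descend(w)) c.record(w);
  }
  return tally_to_df(c.tally);
}

// [[Rcpp::export]]
double cpp_canonical_id(IntegerMatrix adj) {
  int k = adj.nrow();
  if (adj.ncol() != k) stop("adjacency matrix must be square");
  if (k < 1 || k > 7) stop("k must be in 1..7");
  uint64_t bits = 0;
  for (int r = 0; r < k; ++r) {
    if (adj(r, r) != 0) stop("nonzero diagonal: self-loops not allowed");
    for (int c = 0; c < k; ++c)
      if (r != c && adj(r, c) != 0)
        bits |= 1ULL << (uint64_t)(k * k - 1 - (k * r + c));
  }
  std::vector<std::vector<int>> perms;
  all_perms(k, perms);
  return (double)canon_bits(bits, k, perms);
}
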