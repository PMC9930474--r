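#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cstdint>
using namespace Rcpp;

// Minimal deterministic LCG so results do not depend on R's global RNG state.
// Constants from Park-Miller minimal standard.
namespace {
struct Lcg {
  uint64_t state;
  explicit Lcg(uint32_t seed) : state(seed == 0 ? 1u : seed) {}
  uint32_t next() {
    state = (state * 48271u) % 2147483647u;
    return static_cast<uint32_t>(state);
  }
  // integer in [0, n)
  int below(int n) { return static_cast<int>(next() % static_cast<uint32_t>(n)); }
};

void shuffle_order(std::vector<int>& ord, Lcg& rng) {
  for (int i = static_cast<int>(ord.size()) - 1; i > 0; --i) {
    int j = rng.below(i + 1);
    std::swap(ord[i], ord[j]);
  }
}
} // namespace

//' All-pairs shortest path lengths on a weighted graph.
//'
//' Edge lengths are 1/weight for positive weights; absent edges (weight <= 0)
//' are non-adjacent. Plain O(n^2) Dijkstra per source, adequate for the
//' few-hundred-node parcellations this package targets.
//'
//' @noRd
// [[Rcpp::export(name = ".dijkstra_all_cpp")]]
NumericMatrix dijkstra_all_cpp(const NumericMatrix& w) {
  const int n = w.nrow();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix d(n, n);

  // precompute adjacency as lengths
  std::vector<std::vector<std::pair<int, double> > > adj(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && w(i, j) > 0.0)
        adj[i].push_back(std::make_pair(j, 1.0 / w(i, j)));

  std::vector<double> dist(n);
  std::vector<char> done(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(done.begin(), done.end(), 0);
    dist[s] = 0.0;
    for (int iter = 0; iter < n; ++iter) {
      int u = -1;
      double best = INF;
      for (int v = 0; v < n; ++v)
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      if (u < 0) break;
      done[u] = 1;
      for (size_t k = 0; k < adj[u].size(); ++k) {
        int v = adj[u][k].first;
        double nd = dist[u] + adj[u][k].second;
        if (nd < dist[v]) dist[v] = nd;
      }
    }
    for (int v = 0; v < n; ++v) d(s, v) = dist[v];
  }
  return d;
}

namespace {
// One greedy node-move pass over an aggregated graph.
// a: dense symmetric weights (diagonal = self-loop weight, counted once in
// row sums and once in the total, i.e. Q = sum_ij (A_ij - g k_i k_j / W) d_ij / W
// over ordered pairs with W = sum_ij A_ij).
bool louvain_level(const std::vector<double>& a, int n, double gamma,
                   Lcg& rng, std::vector<int>& comm) {
  std::vector<double> k(n, 0.0);
  double wtot = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += a[i * n + j];
    k[i] = s;
    wtot += s;
  }
  if (wtot <= 0.0) return false;

  std::vector<double> ctot(n, 0.0); // total strength per community
  for (int i = 0; i < n; ++i) { comm[i] = i; ctot[i] = k[i]; }

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;

  std::vector<double> kin(n);
  bool any_move = false;
  bool improved = true;
  int guard = 0;
  while (improved && ++guard <= 1000) {
    improved = false;
    shuffle_order(ord, rng);
    for (int oi = 0; oi < n; ++oi) {
      int i = ord[oi];
      int ci = comm[i];
      // strength from i into each community (excluding the self-loop)
      std::fill(kin.begin(), kin.end(), 0.0);
      for (int j = 0; j < n; ++j)
        if (j != i && a[i * n + j] > 0.0) kin[comm[j]] += a[i * n + j];
      // remove i from its community
      ctot[ci] -= k[i];
      double base = kin[ci] - gamma * k[i] * ctot[ci] / wtot;
      int best_c = ci;
      double best_gain = 0.0;
      for (int c = 0; c < n; ++c) {
        if (c == ci || (kin[c] <= 0.0 && ctot[c] <= 0.0)) continue;
        if (kin[c] <= 0.0) continue;
        double gain = (kin[c] - gamma * k[i] * ctot[c] / wtot) - base;
        if (gain > best_gain + 1e-12 ||
            (gain > best_gain - 1e-12 && gain > 0 && c < best_c)) {
          best_gain = gain;
          best_c = c;
        }
      }
      comm[i] = best_c;
      ctot[best_c] += k[i];
      if (best_c != ci) { improved = true; any_move = true; }
    }
  }
  return any_move;
}
} // namespace

//' Louvain community detection on a dense nonnegative symmetric matrix.
//'
//' Greedy node moves followed by community aggregation, repeated until no
//' move improves modularity. Deterministic for a given seed: node visiting
//' order is shuffled with an internal LCG, ties broken towards the lowest
//' community index.
//'
//' @noRd
// [[Rcpp::export(name = ".louvain_cpp")]]
IntegerVector louvain_cpp(const NumericMatrix& w, double gamma, int seed) {
  const int n0 = w.nrow();
  Lcg rng(static_cast<uint32_t>(seed));

  std::vector<double> a(w.begin(), w.end()); // column-major == row-major (symmetric)
  int n = n0;
  std::vector<int> node2final(n0);
  for (int i = 0; i < n0; ++i) node2final[i] = i;

  for (int level = 0; level < 64; ++level) {
    std::vector<int> comm(n);
    bool moved = louvain_level(a, n, gamma, rng, comm);
    // compact community labels
    std::vector<int> remap(n, -1);
    int nc = 0;
    for (int i = 0; i < n; ++i)
      if (remap[comm[i]] < 0) remap[comm[i]] = nc++;
    for (int i = 0; i < n; ++i) comm[i] = remap[comm[i]];
    // push mapping down to original nodes
    for (int i = 0; i < n0; ++i) node2final[i] = comm[node2final[i]];
    if (!moved || nc == n) break;
    // aggregate
    std::vector<double> b(static_cast<size_t>(nc) * nc, 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        b[comm[i] * nc + comm[j]] += a[i * n + j];
    a.swap(b);
    n = nc;
  }

  IntegerVector out(n0);
  for (int i = 0; i < n0; ++i) out[i] = node2final[i] + 1;
  return out;
}
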