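#include <Rcpp.h>
#include <queue>
#include <stack>
#include <vector>
using namespace Rcpp;

// Adjacency list from a 0/1 adjacency matrix (symmetric, zero diagonal).
static std::vector<std::vector<int> > adj_list(const IntegerMatrix &A) {
  int n = A.nrow();
  std::vector<std::vector<int> > adj(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (A(i, j) != 0 && i != j) adj[i].push_back(j);
  return adj;
}

// All-pairs shortest path lengths by BFS from every source.
// Unreachable pairs are coded -1.
// [[Rcpp::export]]
IntegerMatrix bfs_distances_cpp(IntegerMatrix A) {
  int n = A.nrow();
  std::vector<std::vector<int> > adj = adj_list(A);
  IntegerMatrix D(n, n);
  std::fill(D.begin(), D.end(), -1);
  std::vector<int> dist(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (size_t k = 0; k < adj[v].size(); ++k) {
        int w = adj[v][k];
        if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
      }
    }
    for (int j = 0; j < n; ++j) D(s, j) = dist[j];
  }
  return D;
}

// Brandes betweenness centrality for an unweighted undirected graph,
// pair-count convention: each unordered pair {s,t} contributes
// sigma_st(v)/sigma_st to every interior vertex v of its shortest paths.
// [[Rcpp::export]]
NumericVector betweenness_cpp(IntegerMatrix A) {
  int n = A.nrow();
  std::vector<std::vector<int> > adj = adj_list(A);
  NumericVector bc(n, 0.0);
  std::vector<double> sigma(n), delta(n);
  std::vector<int> dist(n);
  std::vector<std::vector<int> > pred(n);
  for (int s = 0; s < n; ++s) {
    std::stack<int> order;
    for (int i = 0; i < n; ++i) { pred[i].clear(); sigma[i] = 0.0; dist[i] = -1; }
    sigma[s] = 1.0; dist[s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      order.push(v);
      for (size_t k = 0; k < adj[v].size(); ++k) {
        int w = adj[v][k];
        if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
        if (dist[w] == dist[v] + 1) { sigma[w] += sigma[v]; pred[w].push_back(v); }
      }
    }
    std::fill(delta.begin(), delta.end(), 0.0);
    while (!order.empty()) {
      int w = order.top(); order.pop();
      for (size_t k = 0; k < pred[w].size(); ++k) {
        int v = pred[w][k];
        delta[v] += (sigma[v] / sigma[w]) * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  // each unordered pair counted from both endpoints
  for (int i = 0; i < n; ++i) bc[i] /= 2.0;
  return bc;
}

// Maslov-Sneppen degree-preserving rewiring. Attempts double-edge swaps
// (a-b, c-d) -> (a-d, c-b) until `target_swaps` succeed or the attempt
// budget (20x target) is exhausted. Self-loops and multi-edges are never
// created; connectivity is not enforced. Uses R's RNG (seed with set.seed).
// Returns the rewired adjacency; attribute "swaps" holds the success count.
// [[Rcpp::export]]
IntegerMatrix rewire_ms_cpp(IntegerMatrix A, int target_swaps) {
  int n = A.nrow();
  IntegerMatrix B(clone(A));
  std::vector<std::pair<int, int> > edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (B(i, j) != 0) edges.push_back(std::make_pair(i, j));
  int m = (int)edges.size();
  int done = 0;
  if (m >= 2 && target_swaps > 0) {
    long long budget = 20LL * target_swaps;
    RNGScope scope;
    for (long long att = 0; att < budget && done < target_swaps; ++att) {
      int e1 = (int)(unif_rand() * m);
      int e2 = (int)(unif_rand() * m);
      if (e1 >= m) e1 = m - 1;
      if (e2 >= m) e2 = m - 1;
      if (e1 == e2) continue;
      int a = edges[e1].first, b = edges[e1].second;
      int c = edges[e2].first, d = edges[e2].second;
      if (unif_rand() < 0.5) std::swap(c, d);
      if (a == c || a == d || b == c || b == d) continue;
      if (B(a, d) != 0 || B(c, b) != 0) continue;
      B(a, b) = B(b, a) = 0;
      B(c, d) = B(d, c) = 0;
      B(a, d) = B(d, a) = 1;
      B(c, b) = B(b, c) = 1;
      edges[e1] = std::make_pair(std::min(a, d), std::max(a, d));
      edges[e2] = std::make_pair(std::min(c, b), std::max(c, b));
      ++done;
    }
  }
  B.attr("swaps") = done;
  return B;
}
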