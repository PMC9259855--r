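#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Unweighted BFS from source s over an adjacency-list graph; dist[] gets -1
// for unreachable vertices.
static void bfs(const std::vector< std::vector<int> > &adj, int s,
                std::vector<int> &dist) {
  std::fill(dist.begin(), dist.end(), -1);
  std::vector<int> queue;
  queue.reserve(adj.size());
  dist[s] = 0;
  queue.push_back(s);
  for (size_t head = 0; head < queue.size(); ++head) {
    int u = queue[head];
    for (size_t t = 0; t < adj[u].size(); ++t) {
      int v = adj[u][t];
      if (dist[v] < 0) {
        dist[v] = dist[u] + 1;
        queue.push_back(v);
      }
    }
  }
}

static std::vector< std::vector<int> > to_adj(const NumericMatrix &A) {
  int n = A.nrow();
  std::vector< std::vector<int> > adj(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && A(i, j) != 0) adj[i].push_back(j);
  return adj;
}

// Mean over ordered pairs of 1/d_ij with 1/Inf := 0 (empty/singleton -> 0).
static double eglob_adj(const std::vector< std::vector<int> > &adj) {
  int n = (int) adj.size();
  if (n < 2) return 0.0;
  std::vector<int> dist(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    bfs(adj, i, dist);
    for (int j = 0; j < n; ++j)
      if (j != i && dist[j] > 0) acc += 1.0 / dist[j];
  }
  return acc / ((double) n * (n - 1));
}

// [[Rcpp::export]]
NumericMatrix cpp_bfs_distances(NumericMatrix A) {
  int n = A.nrow();
  std::vector< std::vector<int> > adj = to_adj(A);
  NumericMatrix D(n, n);
  std::vector<int> dist(n);
  for (int s = 0; s < n; ++s) {
    bfs(adj, s, dist);
    for (int j = 0; j < n; ++j)
      D(s, j) = dist[j] < 0 ? R_PosInf : (double) dist[j];
  }
  return D;
}

// [[Rcpp::export]]
double cpp_global_efficiency(NumericMatrix A) {
  return eglob_adj(to_adj(A));
}

// Per-node global efficiency of the subgraph induced on each node's
// neighbours; 0 where degree < 2.
// [[Rcpp::export]]
NumericVector cpp_local_efficiency(NumericMatrix A) {
  int n = A.nrow();
  std::vector< std::vector<int> > adj = to_adj(A);
  NumericVector out(n);
  std::vector<int> idx(n, -1);
  for (int i = 0; i < n; ++i) {
    const std::vector<int> &nb = adj[i];
    int k = (int) nb.size();
    if (k < 2) { out[i] = 0.0; continue; }
    for (int t = 0; t < k; ++t) idx[nb[t]] = t;
    std::vector< std::vector<int> > sub(k);
    for (int t = 0; t < k; ++t) {
      int u = nb[t];
      for (size_t s = 0; s < adj[u].size(); ++s) {
        int v = adj[u][s];
        if (idx[v] >= 0) sub[t].push_back(idx[v]);
      }
    }
    out[i] = eglob_adj(sub);
    for (int t = 0; t < k; ++t) idx[nb[t]] = -1;
  }
  return out;
}
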