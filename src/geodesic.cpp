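#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>

using namespace Rcpp;

// All-pairs shortest paths by Floyd–Warshall on a dense weight matrix.
// Non-edges are R_PosInf; the diagonal is 0. This is the reference solver.
// [[Rcpp::export]]
NumericMatrix floyd_warshall_cpp(NumericMatrix W) {
  int n = W.nrow();
  if (W.ncol() != n) stop("weight matrix must be square");
  NumericMatrix D(clone(W));
  for (int k = 0; k < n; ++k) {
    for (int i = 0; i < n; ++i) {
      double dik = D(i, k);
      if (!R_FINITE(dik)) continue;
      for (int j = 0; j < n; ++j) {
        double cand = dik + D(k, j);
        if (cand < D(i, j)) D(i, j) = cand;
      }
    }
  }
  return D;
}

// All-pairs shortest paths by binary-heap Dijkstra from every source.
// Equivalent to Floyd–Warshall (all weights are non-negative distances) but
// much faster on sparse nu-nearest-neighbour graphs.
// [[Rcpp::export]]
NumericMatrix dijkstra_all_cpp(NumericMatrix W) {
  int n = W.nrow();
  if (W.ncol() != n) stop("weight matrix must be square");
  const double inf = std::numeric_limits<double>::infinity();

  // adjacency lists from the finite off-diagonal entries
  std::vector< std::vector< std::pair<int, double> > > adj(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i != j && R_FINITE(W(i, j))) {
        adj[i].push_back(std::make_pair(j, W(i, j)));
      }
    }
  }

  NumericMatrix D(n, n);
  typedef std::pair<double, int> Item;  // (distance, vertex)
  for (int s = 0; s < n; ++s) {
    std::vector<double> dist(n, inf);
    dist[s] = 0.0;
    std::priority_queue<Item, std::vector<Item>, std::greater<Item> > pq;
    pq.push(std::make_pair(0.0, s));
    while (!pq.empty()) {
      Item top = pq.top(); pq.pop();
      double d = top.first;
      int v = top.second;
      if (d > dist[v]) continue;  // stale entry
      for (size_t e = 0; e < adj[v].size(); ++e) {
        int u = adj[v][e].first;
        double nd = d + adj[v][e].second;
        if (nd < dist[u]) {
          dist[u] = nd;
          pq.push(std::make_pair(nd, u));
        }
      }
    }
    for (int j = 0; j < n; ++j) D(s, j) = dist[j];
  }
  return D;
}
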