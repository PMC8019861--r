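#include <Rcpp.h>
#include <deque>
#include <vector>
using namespace Rcpp;

// adj: list of 0-based integer neighbor vectors, one per node.

static std::vector<std::vector<int>> adj_from_list(const List& adj) {
  int n = adj.size();
  std::vector<std::vector<int>> A(n);
  for (int i = 0; i < n; ++i) A[i] = as<std::vector<int>>(adj[i]);
  return A;
}

// All-pairs unweighted shortest-path distances by BFS from every source.
// Unreachable pairs get NA_INTEGER.
// [[Rcpp::export]]
IntegerMatrix bfs_distance_matrix(List adj) {
  std::vector<std::vector<int>> A = adj_from_list(adj);
  int n = A.size();
  IntegerMatrix D(n, n);
  std::fill(D.begin(), D.end(), NA_INTEGER);
  std::deque<int> Q;
  for (int s = 0; s < n; ++s) {
    D(s, s) = 0;
    Q.clear();
    Q.push_back(s);
    while (!Q.empty()) {
      int v = Q.front();
      Q.pop_front();
      int dv = D(v, s);
      for (int w : A[v]) {
        if (D(w, s) == NA_INTEGER) {
          D(w, s) = dv + 1;
          Q.push_back(w);
        }
      }
    }
  }
  return D;
}

// Brandes' accumulation algorithm for unweighted betweenness.
// Returns the directed-pair sum; halve for unordered pairs on an
// undirected graph.
// [[Rcpp::export]]
NumericVector brandes_betweenness(List adj) {
  std::vector<std::vector<int>> A = adj_from_list(adj);
  int n = A.size();
  NumericVector bc(n);
  std::vector<int> dist(n);
  std::vector<double> sigma(n), delta(n);
  std::vector<std::vector<int>> pred(n);
  std::vector<int> order;
  order.reserve(n);
  std::deque<int> Q;
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (auto& p : pred) p.clear();
    order.clear();
    Q.clear();
    dist[s] = 0;
    sigma[s] = 1.0;
    Q.push_back(s);
    while (!Q.empty()) {
      int v = Q.front();
      Q.pop_front();
      order.push_back(v);
      for (int w : A[v]) {
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          Q.push_back(w);
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] += sigma[v];
          pred[w].push_back(v);
        }
      }
    }
    for (int i = (int)order.size() - 1; i >= 0; --i) {
      int w = order[i];
      for (int v : pred[w]) {
        delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  return bc;
}
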