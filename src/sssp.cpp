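#include <Rcpp.h>
#include <queue>
#include <vector>
#include <utility>

using namespace Rcpp;

// Single-source shortest paths with path multiplicities on an undirected
// positively weighted graph in CSR form.
//
// head: length n+1, 0-based offsets into nbr/wt; nbr: 0-based neighbour
// indices; wt: positive edge weights. Returns dist (Inf for unreachable) and
// sigma, the number of distinct minimum-weight paths from source (0 for
// unreachable, exact as long as counts stay below 2^53).
//
// Sigma is accumulated over the shortest-path DAG during the Dijkstra sweep:
// relaxations happen only out of settled nodes, so each predecessor
// contributes exactly once.
// [[Rcpp::export]]
List cpp_sssp(int n, IntegerVector head, IntegerVector nbr,
              NumericVector wt, int source) {
  std::vector<double> dist(n, R_PosInf);
  std::vector<double> sigma(n, 0.0);
  std::vector<bool> done(n, false);

  typedef std::pair<double, int> QE; // (dist, node), min-heap
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;

  dist[source] = 0.0;
  sigma[source] = 1.0;
  pq.push(std::make_pair(0.0, source));

  while (!pq.empty()) {
    QE top = pq.top();
    pq.pop();
    int u = top.second;
    if (done[u]) continue; // stale heap entry
    done[u] = true;
    double du = dist[u];
    for (int k = head[u]; k < head[u + 1]; ++k) {
      int v = nbr[k];
      if (done[v]) continue;
      double nd = du + wt[k];
      if (nd < dist[v]) {
        dist[v] = nd;
        sigma[v] = sigma[u];
        pq.push(std::make_pair(nd, v));
      } else if (nd == dist[v]) { // integer weights: exact comparison
        sigma[v] += sigma[u];
      }
    }
  }

  return List::create(_["dist"] = NumericVector(dist.begin(), dist.end()),
                      _["sigma"] = NumericVector(sigma.begin(), sigma.end()));
}
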