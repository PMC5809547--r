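// Weighted shortest paths and centrality. Edge lengths are 1/|w|; absent
// edges (w == 0) have no direct connection. Betweenness uses Brandes-style
// counting with fractional credit for tied shortest paths, endpoints
// excluded; ties are detected with a small relative tolerance.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double TIE_EPS = 1e-12;

struct SPTree {
  std::vector<double> dist;
  std::vector<double> sigma;               // shortest-path counts
  std::vector<std::vector<int> > pred;     // predecessor lists
  std::vector<int> order;                  // nodes in nondecreasing dist
};

static void dijkstra(const NumericMatrix &W, int s, SPTree &T) {
  int p = W.nrow();
  T.dist.assign(p, R_PosInf);
  T.sigma.assign(p, 0.0);
  T.pred.assign(p, std::vector<int>());
  T.order.clear();
  std::vector<bool> done(p, false);
  T.dist[s] = 0.0;
  T.sigma[s] = 1.0;
  for (int it = 0; it < p; it++) {
    int u = -1;
    double du = R_PosInf;
    for (int v = 0; v < p; v++)
      if (!done[v] && T.dist[v] < du) {
        du = T.dist[v];
        u = v;
      }
    if (u < 0) break;
    done[u] = true;
    T.order.push_back(u);
    for (int v = 0; v < p; v++) {
      double w = W(u, v);
      if (v == u || w == 0.0 || done[v]) continue;
      double nd = T.dist[u] + 1.0 / std::fabs(w);
      double tol = TIE_EPS * (1.0 + std::fabs(nd));
      if (nd < T.dist[v] - tol) {
        T.dist[v] = nd;
        T.sigma[v] = T.sigma[u];
        T.pred[v].assign(1, u);
      } else if (std::fabs(nd - T.dist[v]) <= tol) {
        T.sigma[v] += T.sigma[u];
        T.pred[v].push_back(u);
      }
    }
  }
}

// [[Rcpp::export(name = ".cppDistances")]]
NumericMatrix cpp_distances(NumericMatrix W) {
  int p = W.nrow();
  NumericMatrix D(p, p);
  SPTree T;
  for (int s = 0; s < p; s++) {
    dijkstra(W, s, T);
    for (int v = 0; v < p; v++) D(s, v) = T.dist[v];
  }
  return D;
}

// [[Rcpp::export(name = ".cppCentrality")]]
List cpp_centrality(NumericMatrix W) {
  int p = W.nrow();
  NumericVector strength(p), closeness(p), betweenness(p);
  for (int i = 0; i < p; i++) {
    double s = 0.0;
    for (int j = 0; j < p; j++)
      if (j != i) s += std::fabs(W(i, j));
    strength[i] = s;
  }
  SPTree T;
  std::vector<double> delta(p);
  for (int s = 0; s < p; s++) {
    dijkstra(W, s, T);
    double total = 0.0;
    bool reach_all = true;
    for (int v = 0; v < p; v++) {
      if (v == s) continue;
      if (!R_finite(T.dist[v])) reach_all = false;
      else total += T.dist[v];
    }
    closeness[s] = reach_all && total > 0.0 ? 1.0 / total : 0.0;
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int k = (int)T.order.size() - 1; k >= 0; k--) {
      int w = T.order[k];
      for (size_t q = 0; q < T.pred[w].size(); q++) {
        int v = T.pred[w][q];
        delta[v] += T.sigma[v] / T.sigma[w] * (1.0 + delta[w]);
      }
      if (w != s) betweenness[w] += delta[w];
    }
  }
  for (int i = 0; i < p; i++) betweenness[i] *= 0.5;  // undirected pairs
  return List::create(_["strength"] = strength, _["closeness"] = closeness,
                      _["betweenness"] = betweenness);
}
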