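#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Seed-pair shortest-path betweenness by BFS geodesic counting.
//
// For every node v the statistic is
//   B(v) = sum over unordered seed pairs (s, t), s != t, of sigma_st(v),
// where sigma_st(v) is the number of distinct geodesics (hop-count shortest
// paths) from s to t that pass through v as an interior node.  Using one BFS
// per seed we obtain d_s(.) and the geodesic counts sigma_s(.); then
//   sigma_st(v) = sigma_s(v) * sigma_t(v)   if d_s(v) + d_t(v) == d(s, t)
//               = 0                          otherwise,
// with endpoints excluded.  Counts are held in doubles (exact integers up to
// 2^53; geodesic counts on sparse graphs stay far below that).
//
// adj   : list of integer vectors, 1-based neighbour ids (simple undirected
//         graph, both directions present)
// seeds : 1-based node ids, distinct
// [[Rcpp::export]]
NumericVector seed_pair_betweenness_counts(List adj, IntegerVector seeds) {
  const int n = adj.size();
  const int ns = seeds.size();

  // CSR adjacency
  std::vector<int> deg(n), off(n + 1, 0);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj[i];
    deg[i] = nb.size();
    off[i + 1] = off[i] + deg[i];
  }
  std::vector<int> nbr(off[n]);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj[i];
    for (int j = 0; j < deg[i]; ++j) nbr[off[i] + j] = nb[j] - 1;
  }

  std::vector<std::vector<int> > dist(ns, std::vector<int>(n, -1));
  std::vector<std::vector<double> > sig(ns, std::vector<double>(n, 0.0));
  std::vector<int> queue_buf(n);

  for (int si = 0; si < ns; ++si) {
    int s = seeds[si] - 1;
    std::vector<int>& d = dist[si];
    std::vector<double>& sg = sig[si];
    d[s] = 0; sg[s] = 1.0;
    int head = 0, tail = 0;
    queue_buf[tail++] = s;
    while (head < tail) {
      int u = queue_buf[head++];
      int du = d[u];
      for (int j = off[u]; j < off[u + 1]; ++j) {
        int w = nbr[j];
        if (d[w] < 0) { d[w] = du + 1; queue_buf[tail++] = w; }
        if (d[w] == du + 1) sg[w] += sg[u];
      }
    }
  }

  NumericVector out(n);
  for (int si = 0; si < ns; ++si) {
    int s = seeds[si] - 1;
    for (int ti = si + 1; ti < ns; ++ti) {
      int t = seeds[ti] - 1;
      int dst = dist[si][t];
      if (dst < 0 || dst < 2) continue;  // disconnected or adjacent: no interior
      const std::vector<int>& ds = dist[si];
      const std::vector<int>& dt = dist[ti];
      const std::vector<double>& ss = sig[si];
      const std::vector<double>& st = sig[ti];
      for (int v = 0; v < n; ++v) {
        if (v == s || v == t) continue;
        if (ds[v] > 0 && dt[v] > 0 && ds[v] + dt[v] == dst)
          out[v] += ss[v] * st[v];
      }
    }
  }
  return out;
}
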