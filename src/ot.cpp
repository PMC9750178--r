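// Exact optimal transport between two discrete mass distributions by
// successive shortest augmenting paths with node potentials (min-cost flow
// on the complete bipartite graph).  Each augmentation exhausts a remaining
// supply or demand, or zeroes a rerouted backward arc, so termination is
// finite but can exceed m + n augmentations on degenerate grid costs (hence
// the generous stall guard).  Dijkstra runs on the dense graph in
// O((m+n)^2) per augmentation.  Potentials keep all
// reduced costs nonnegative, with complementary slackness tying carried
// flow to tight arcs, so the final plan is optimal (up to floating-point
// tolerance on the reduced costs).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// [[Rcpp::export]]
List ot_exact(NumericVector a, NumericVector b, NumericMatrix C) {
  const int m = a.size(), n = b.size(), N = m + n;
  if (C.nrow() != m || C.ncol() != n) stop("cost matrix dimensions mismatch");
  double suma = 0, sumb = 0;
  for (int i = 0; i < m; i++) suma += a[i];
  for (int j = 0; j < n; j++) sumb += b[j];
  if (std::fabs(suma - sumb) > 1e-9 * std::max(suma, sumb))
    stop("supplies and demands must have equal total mass");
  const double eps = 1e-14 * suma;

  std::vector<double> rema(a.begin(), a.end()), remb(b.begin(), b.end());
  std::vector<double> flow((size_t)m * n, 0.0);
  std::vector<double> pot(N, 0.0);          // node potentials
  std::vector<double> dist(N);
  std::vector<int> parent(N);
  std::vector<char> done(N);
  const double INF = std::numeric_limits<double>::infinity();

  double remaining = suma;
  int guard = 0;
  while (remaining > eps) {
    if (++guard > 400 * N + 16) stop("optimal transport solver stalled");
    // multi-source Dijkstra over reduced costs
    for (int v = 0; v < N; v++) {
      dist[v] = (v < m && rema[v] > eps) ? 0.0 : INF;
      parent[v] = -1;
      done[v] = 0;
    }
    int target = -1;
    while (true) {
      int u = -1; double du = INF;
      for (int v = 0; v < N; v++)
        if (!done[v] && dist[v] < du) { du = dist[v]; u = v; }
      if (u < 0) break;
      done[u] = 1;
      if (u >= m && remb[u - m] > eps) { target = u; break; }
      if (u < m) {                         // left -> right forward arcs
        for (int j = 0; j < n; j++) {
          double rc = C(u, j) + pot[u] - pot[m + j];
          if (rc < 0) rc = 0;
          if (du + rc < dist[m + j]) {
            dist[m + j] = du + rc;
            parent[m + j] = u;
          }
        }
      } else {                             // right -> left backward arcs
        int j = u - m;
        for (int i = 0; i < m; i++) {
          if (flow[(size_t)i * n + j] <= eps) continue;
          double rc = -C(i, j) + pot[u] - pot[i];
          if (rc < 0) rc = 0;
          if (du + rc < dist[i]) {
            dist[i] = du + rc;
            parent[i] = u;
          }
        }
      }
    }
    if (target < 0) stop("optimal transport solver: no augmenting path");
    const double dt = dist[target];
    for (int v = 0; v < N; v++)
      pot[v] += std::min(dist[v], dt);
    // bottleneck along the path
    double amt = remb[target - m];
    for (int v = target; parent[v] >= 0; v = parent[v]) {
      int u = parent[v];
      if (v < m)                            // backward arc u(right)->v(left)
        amt = std::min(amt, flow[(size_t)v * n + (u - m)]);
    }
    {
      int v = target;
      while (parent[v] >= 0) v = parent[v];
      amt = std::min(amt, rema[v]);
    }
    if (amt <= 0) stop("optimal transport solver: zero augmentation");
    // apply
    int v = target;
    while (parent[v] >= 0) {
      int u = parent[v];
      if (v >= m) flow[(size_t)u * n + (v - m)] += amt;   // forward
      else flow[(size_t)v * n + (u - m)] -= amt;          // backward
      v = u;
    }
    rema[v] -= amt;
    remb[target - m] -= amt;
    remaining -= amt;
  }

  // collect plan triplets and total cost
  std::vector<int> fi, fj; std::vector<double> fm;
  double total = 0;
  for (int i = 0; i < m; i++)
    for (int j = 0; j < n; j++) {
      double f = flow[(size_t)i * n + j];
      if (f > eps) {
        fi.push_back(i + 1); fj.push_back(j + 1); fm.push_back(f);
        total += f * C(i, j);
      }
    }
  return List::create(_["from"] = wrap(fi), _["to"] = wrap(fj),
                      _["mass"] = wrap(fm), _["cost"] = total);
}
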