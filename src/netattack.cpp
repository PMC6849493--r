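#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Per-step state metrics along a node-removal trajectory.
//
// adj: symmetric weighted adjacency (zero diagonal). order: 0-based node
// indices removed one at a time (length N-1 for a full attack). weighted:
// connectivity as sum of |w| instead of edge count. inverse_weight:
// shortest paths use 1/|w| edge lengths instead of hops.
//
// Returns connectivity, n_components and average path length for the
// initial network (step 0) and after each removal; average path length is
// NA when the surviving graph has no edges.
//
// The surviving subgraph is kept in a CSR structure compacted after every
// removal, so each per-source BFS touches only surviving edges.
// [[Rcpp::export]]
List attack_trajectory_cpp(NumericMatrix adj, IntegerVector order,
                           bool weighted, bool inverse_weight) {
  const int n = adj.nrow();
  const int steps = order.size() + 1;

  // CSR of the full graph
  std::vector<int> xadj(n + 1, 0), adjncy;
  std::vector<double> ew;
  double conn = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double w = adj(i, j);
      if (i != j && w != 0.0) {
        adjncy.push_back(j);
        ew.push_back(std::fabs(w));
        if (j > i) conn += weighted ? std::fabs(w) : 1.0;
      }
    }
    xadj[i + 1] = (int)adjncy.size();
  }

  NumericVector connectivity(steps);
  IntegerVector ncomp(steps);
  NumericVector apl(steps);

  std::vector<char> active(n, 1);
  std::vector<int> qbuf(n), idist(n), vis(n, -1), comp(n, 0);
  std::vector<double> ddist(n);
  std::vector<int> done(n, -1);
  int ver = 0;       // BFS stamp
  int compver = 0;   // per-step component stamp (negative range)

  for (int s = 0; s < steps; ++s) {
    if (s > 0) {
      int v = order[s - 1];
      if (v < 0 || v >= n || !active[v]) stop("invalid removal order");
      for (int k = xadj[v]; k < xadj[v + 1]; ++k)
        conn -= weighted ? ew[k] : 1.0;
      active[v] = 0;
      // compact: drop row v and references to v
      std::vector<int> nx(n + 1, 0), na;
      std::vector<double> nw;
      na.reserve(adjncy.size());
      nw.reserve(ew.size());
      for (int i = 0; i < n; ++i) {
        if (active[i]) {
          for (int k = xadj[i]; k < xadj[i + 1]; ++k) {
            if (adjncy[k] != v) {
              na.push_back(adjncy[k]);
              nw.push_back(ew[k]);
            }
          }
        }
        nx[i + 1] = (int)na.size();
      }
      xadj.swap(nx);
      adjncy.swap(na);
      ew.swap(nw);
    }
    connectivity[s] = conn;

    int nactive = 0;
    for (int i = 0; i < n; ++i) if (active[i]) ++nactive;

    if (conn <= 0.0) {
      ncomp[s] = nactive;
      apl[s] = NA_REAL;
      continue;
    }

    int ncp = 0;
    double total = 0.0;
    long long pairs = 0;
    --compver;  // fresh stamp for this step (negative, never collides with ver)

    for (int src = 0; src < n; ++src) {
      if (!active[src]) continue;
      bool newcomp = (comp[src] != compver);
      if (newcomp) ++ncp;
      ++ver;
      if (!inverse_weight) {
        int head = 0, tail = 0;
        qbuf[tail++] = src;
        vis[src] = ver;
        idist[src] = 0;
        while (head < tail) {
          int x = qbuf[head++];
          if (newcomp) comp[x] = compver;
          for (int k = xadj[x]; k < xadj[x + 1]; ++k) {
            int u = adjncy[k];
            if (vis[u] != ver) {
              vis[u] = ver;
              idist[u] = idist[x] + 1;
              total += idist[u];
              ++pairs;
              qbuf[tail++] = u;
            }
          }
        }
      } else {
        typedef std::pair<double, int> Node;
        std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
        vis[src] = ver;
        ddist[src] = 0.0;
        pq.push(Node(0.0, src));
        while (!pq.empty()) {
          Node top = pq.top(); pq.pop();
          int x = top.second;
          if (done[x] == ver) continue;
          done[x] = ver;
          if (newcomp) comp[x] = compver;
          if (x != src) { total += top.first; ++pairs; }
          for (int k = xadj[x]; k < xadj[x + 1]; ++k) {
            int u = adjncy[k];
            if (done[u] == ver) continue;
            double nd = top.first + 1.0 / ew[k];
            if (vis[u] != ver || nd < ddist[u]) {
              vis[u] = ver;
              ddist[u] = nd;
              pq.push(Node(nd, u));
            }
          }
        }
      }
    }
    ncomp[s] = ncp;
    apl[s] = (pairs > 0) ? total / (double)pairs : NA_REAL;
  }

  return List::create(_["connectivity"] = connectivity,
                      _["n_components"] = ncomp,
                      _["avg_path_length"] = apl);
}

// Gibbs sampler for a 0/1 Ising model. u holds pre-drawn uniforms,
// (burnin + n * thin) * p of them, so the R side owns all randomness.
// [[Rcpp::export]]
IntegerMatrix sample_ising_cpp(NumericVector thresholds, NumericMatrix couplings,
                               NumericVector init, int n, int burnin, int thin,
                               NumericVector u) {
  const int p = thresholds.size();
  std::vector<double> x(p);
  for (int i = 0; i < p; ++i) x[i] = init[i];
  IntegerMatrix out(n, p);
  long long uk = 0;
  int recorded = 0;
  const int total_sweeps = burnin + n * thin;
  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int i = 0; i < p; ++i) {
      double field = thresholds[i];
      for (int j = 0; j < p; ++j)
        if (j != i && couplings(i, j) != 0.0) field += couplings(i, j) * x[j];
      double pr = 1.0 / (1.0 + std::exp(-field));
      x[i] = (u[uk++] < pr) ? 1.0 : 0.0;
    }
    if (sweep >= burnin && (sweep - burnin + 1) % thin == 0) {
      for (int i = 0; i < p; ++i) out(recorded, i) = (int)x[i];
      ++recorded;
      if (recorded == n) break;
    }
  }
  return out;
}
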