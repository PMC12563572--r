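#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Wiring rule codes (kept in sync with gnm_rules() on the R side):
//  1 spatial
//  2 neighbors  3 matching
//  4 clu_avg  5 clu_min  6 clu_max  7 clu_diff  8 clu_prod
//  9 deg_avg 10 deg_min 11 deg_max 12 deg_diff 13 deg_prod

struct GrowState {
  int n;
  std::vector<uint8_t> adj;           // n*n, row-major
  std::vector<std::vector<int> > nbr; // adjacency lists
  std::vector<int> deg;
  std::vector<double> tri;            // triangle counts
  std::vector<double> clu;            // local clustering (Watts-Strogatz)
  bool a(int i, int j) const { return adj[i * n + j] != 0; }
};

static int common_neighbors(const GrowState& st, int i, int j,
                            std::vector<int>* out = nullptr) {
  const std::vector<int>& ni = st.nbr[i].size() <= st.nbr[j].size()
                                   ? st.nbr[i] : st.nbr[j];
  int other = st.nbr[i].size() <= st.nbr[j].size() ? j : i;
  int c = 0;
  for (size_t k = 0; k < ni.size(); ++k)
    if (st.a(other, ni[k])) { ++c; if (out) out->push_back(ni[k]); }
  return c;
}

static double rule_value(const GrowState& st, int rule, int i, int j) {
  switch (rule) {
    case 1: return 1.0;
    case 2: return (double)common_neighbors(st, i, j);
    case 3: {  // matching index: neighborhoods excluding each other
      int c = common_neighbors(st, i, j);
      int uni = st.deg[i] + st.deg[j] - 2 * (st.a(i, j) ? 1 : 0) - c;
      return uni > 0 ? (double)c / (double)uni : 0.0;
    }
    case 4: return 0.5 * (st.clu[i] + st.clu[j]);
    case 5: return std::min(st.clu[i], st.clu[j]);
    case 6: return std::max(st.clu[i], st.clu[j]);
    case 7: return std::fabs(st.clu[i] - st.clu[j]);
    case 8: return st.clu[i] * st.clu[j];
    case 9: return 0.5 * (double)(st.deg[i] + st.deg[j]);
    case 10: return (double)std::min(st.deg[i], st.deg[j]);
    case 11: return (double)std::max(st.deg[i], st.deg[j]);
    case 12: return std::fabs((double)(st.deg[i] - st.deg[j]));
    case 13: return (double)st.deg[i] * (double)st.deg[j];
    default: stop("unknown wiring rule code %d", rule);
  }
  return 0.0;
}

// Iterative economic growth: start from the empty graph, add one undirected
// edge per step with probability proportional to D^eta * (K + eps)^gamma over
// currently unconnected pairs; K updates after every addition. Optionally
// records the probability-score vector over unconnected pairs at regular
// fractions of completion.
// [[Rcpp::export]]
List grow_network_cpp(NumericMatrix D, int rule, double eta, double gamma,
                      double eps, int m, double snapshot_interval,
                      bool record_snapshots) {
  int n = D.nrow();
  int npair = n * (n - 1) / 2;
  if (m > npair) stop("m exceeds the number of node pairs");

  std::vector<int> pi(npair), pj(npair);
  std::vector<double> deta(npair);
  {
    int p = 0;
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j, ++p) {
        pi[p] = i; pj[p] = j;
        double d = D(i, j);
        if (!(d > 0.0))
          stop("off-diagonal distances must be strictly positive");
        deta[p] = std::pow(d, eta);
        if (!std::isfinite(deta[p]))
          stop("non-finite value from D^eta at pair (%d,%d): D=%g eta=%g",
               i + 1, j + 1, d, eta);
      }
  }
  // pair index lookup for (i, j), i < j
  std::vector<int> pidx(n * n, -1);
  for (int p = 0; p < npair; ++p) {
    pidx[pi[p] * n + pj[p]] = p;
    pidx[pj[p] * n + pi[p]] = p;
  }

  GrowState st;
  st.n = n;
  st.adj.assign(n * n, 0);
  st.nbr.assign(n, std::vector<int>());
  st.deg.assign(n, 0);
  st.tri.assign(n, 0.0);
  st.clu.assign(n, 0.0);

  std::vector<uint8_t> connected(npair, 0);
  std::vector<double> w(npair);
  double k0 = rule == 1 ? 1.0 : 0.0;   // K on the empty graph
  double wk0 = std::pow(k0 + eps, gamma);
  if (!std::isfinite(wk0))
    stop("non-finite value from (K+eps)^gamma with K=%g eps=%g gamma=%g",
         k0, eps, gamma);
  for (int p = 0; p < npair; ++p) w[p] = deta[p] * wk0;

  IntegerMatrix edge_order(m, 2);
  std::vector<double> snap_frac;
  List snapshots;
  std::vector<int> snap_at;  // edge counts at which to record
  if (record_snapshots && m > 0) {
    int prev = 0;
    for (double f = snapshot_interval; f < 1.0 + 1e-9; f += snapshot_interval) {
      int e = (int)std::lround(std::min(f, 1.0) * m);
      if (e > prev && e <= m) { snap_at.push_back(e); snap_frac.push_back((double)e / m); prev = e; }
    }
    snapshots = List(snap_at.size());
  }
  size_t next_snap = 0;

  std::vector<int> touched;   // nodes whose K rows need refresh
  std::vector<int> common;

  for (int step = 0; step < m; ++step) {
    double total = 0.0;
    for (int p = 0; p < npair; ++p) total += w[p];
    if (!(total > 0.0) || !std::isfinite(total))
      stop("degenerate wiring probabilities at step %d: sum of D^eta*(K+eps)^gamma is %g",
           step + 1, total);
    double r = unif_rand() * total, acc = 0.0;
    int chosen = npair - 1;
    for (int p = 0; p < npair; ++p) {
      acc += w[p];
      if (r <= acc && w[p] > 0.0) { chosen = p; break; }
    }
    int u = pi[chosen], v = pj[chosen];
    connected[chosen] = 1;
    w[chosen] = 0.0;
    edge_order(step, 0) = u + 1;
    edge_order(step, 1) = v + 1;

    // update adjacency and incremental statistics
    common.clear();
    common_neighbors(st, u, v, &common);
    st.adj[u * n + v] = st.adj[v * n + u] = 1;
    st.nbr[u].push_back(v);
    st.nbr[v].push_back(u);
    st.deg[u]++; st.deg[v]++;
    st.tri[u] += common.size();
    st.tri[v] += common.size();
    for (size_t k = 0; k < common.size(); ++k) st.tri[common[k]] += 1.0;

    touched.clear();
    touched.push_back(u);
    touched.push_back(v);
    if (rule >= 4 && rule <= 8)  // clustering rules: common neighbours change too
      for (size_t k = 0; k < common.size(); ++k) touched.push_back(common[k]);
    for (size_t k = 0; k < touched.size(); ++k) {
      int a = touched[k];
      st.clu[a] = st.deg[a] < 2
        ? 0.0 : 2.0 * st.tri[a] / ((double)st.deg[a] * (st.deg[a] - 1));
    }

    if (rule != 1) {
      for (size_t k = 0; k < touched.size(); ++k) {
        int a = touched[k];
        for (int b = 0; b < n; ++b) {
          if (b == a) continue;
          int p = pidx[a * n + b];
          if (connected[p]) { w[p] = 0.0; continue; }
          double kv = rule_value(st, rule, pi[p], pj[p]);
          double wp = deta[p] * std::pow(kv + eps, gamma);
          if (!std::isfinite(wp))
            stop("non-finite value from (K+eps)^gamma: K=%g eps=%g gamma=%g",
                 kv, eps, gamma);
          w[p] = wp;
        }
      }
    }

    if (record_snapshots && next_snap < snap_at.size() &&
        step + 1 == snap_at[next_snap]) {
      NumericVector pv(npair - (step + 1));
      int q = 0;
      for (int p = 0; p < npair; ++p)
        if (!connected[p]) pv[q++] = w[p];
      snapshots[next_snap] = pv;
      ++next_snap;
    }
    if (step % 64 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix A(n, n);
  for (int p = 0; p < npair; ++p)
    if (connected[p]) { A(pi[p], pj[p]) = 1; A(pj[p], pi[p]) = 1; }

  return List::create(_["adjacency"] = A,
                      _["edge_order"] = edge_order,
                      _["snapshot_fractions"] = wrap(snap_frac),
                      _["p_snapshots"] = snapshots);
}
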