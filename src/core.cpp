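#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Orientation convention throughout: A(i, j) = 1  <=>  directed link j -> i.

// Tarjan strongly-connected components, iterative (graphs can be deep).
// A nontrivial SCC (size >= 2) contains at least one simple directed cycle;
// it contains exactly one iff its internal link count equals its size.
// [[Rcpp::export]]
List cpp_cycle_flags(const IntegerMatrix& A) {
  const int n = A.nrow();
  std::vector<std::vector<int>> succ(n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (A(i, j) != 0) succ[j].push_back(i);

  std::vector<int> index(n, -1), low(n, 0), comp(n, -1);
  std::vector<char> onstack(n, 0);
  std::vector<int> stk;
  int idx = 0, ncomp = 0;

  // explicit DFS stack: (node, position in its successor list)
  std::vector<std::pair<int, size_t>> dfs;
  for (int root = 0; root < n; ++root) {
    if (index[root] != -1) continue;
    dfs.clear();
    dfs.push_back({root, 0});
    index[root] = low[root] = idx++;
    stk.push_back(root);
    onstack[root] = 1;
    while (!dfs.empty()) {
      int v = dfs.back().first;
      size_t& pos = dfs.back().second;
      if (pos < succ[v].size()) {
        int w = succ[v][pos++];
        if (index[w] == -1) {
          index[w] = low[w] = idx++;
          stk.push_back(w);
          onstack[w] = 1;
          dfs.push_back({w, 0});
        } else if (onstack[w]) {
          low[v] = std::min(low[v], index[w]);
        }
      } else {
        if (low[v] == index[v]) {
          int w;
          do {
            w = stk.back();
            stk.pop_back();
            onstack[w] = 0;
            comp[w] = ncomp;
          } while (w != v);
          ++ncomp;
        }
        dfs.pop_back();
        if (!dfs.empty()) {
          int u = dfs.back().first;
          low[u] = std::min(low[u], low[v]);
        }
      }
    }
  }

  std::vector<int> comp_size(ncomp, 0);
  for (int v = 0; v < n; ++v) comp_size[comp[v]]++;

  int n_cyclic = 0, cyclic_comp = -1;
  for (int c = 0; c < ncomp; ++c)
    if (comp_size[c] >= 2) { ++n_cyclic; cyclic_comp = c; }

  bool has_cycle = n_cyclic > 0;
  bool single_cycle = false;
  IntegerVector cycle_nodes;
  if (n_cyclic == 1) {
    int sz = comp_size[cyclic_comp], edges = 0;
    for (int j = 0; j < n; ++j) {
      if (comp[j] != cyclic_comp) continue;
      for (int i : succ[j]) if (comp[i] == cyclic_comp) ++edges;
    }
    if (edges == sz) {
      single_cycle = true;
      std::vector<int> mem;
      for (int v = 0; v < n; ++v)
        if (comp[v] == cyclic_comp) mem.push_back(v + 1);
      cycle_nodes = wrap(mem);
    }
  }
  return List::create(_["has_cycle"] = has_cycle,
                      _["single_cycle"] = single_cycle,
                      _["n_cyclic_scc"] = n_cyclic,
                      _["cycle_nodes"] = cycle_nodes);
}

static void reinit_state(const std::vector<std::vector<int>>& succ,
                         std::vector<char>& inf, std::vector<int>& press,
                         int& ninf, double& S, std::vector<double>& t0,
                         double t, double reinit_prob, int reinit_mode) {
  const int n = (int)inf.size();
  do {
    std::fill(inf.begin(), inf.end(), 0);
    ninf = 0;
    if (reinit_mode == 1) {
      int k = (int)(R::unif_rand() * n);
      if (k == n) k = n - 1;
      inf[k] = 1;
      ninf = 1;
    } else {
      for (int i = 0; i < n; ++i)
        if (R::unif_rand() < reinit_prob) { inf[i] = 1; ++ninf; }
    }
  } while (ninf == 0);
  std::fill(press.begin(), press.end(), 0);
  for (int j = 0; j < n; ++j)
    if (inf[j]) for (int i : succ[j]) press[i]++;
  S = 0.0;
  for (int i = 0; i < n; ++i) {
    if (inf[i]) t0[i] = t;
    else S += press[i];
  }
}

// Exact event-driven (Gillespie) SIS on a directed network.  Each infected j
// transmits along every out-link j -> i to susceptible i at rate beta; each
// infected node recovers at rate r.  On extinction the state is re-drawn by
// the re-initialization policy and the clock keeps running.  Uses R's RNG.
// [[Rcpp::export]]
List cpp_sis_gillespie(const IntegerMatrix& A, double beta, double r,
                       double duration, double reinit_prob, int reinit_mode) {
  const int n = A.nrow();
  std::vector<std::vector<int>> succ(n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (A(i, j) != 0) succ[j].push_back(i);

  std::vector<char> inf(n, 0);
  std::vector<int> press(n, 0);          // infected in-neighbours, all nodes
  std::vector<double> t0(n, 0.0), tinf(n, 0.0);
  int ninf = 0, n_reinits = -1;          // first init is not a re-init
  double S = 0.0, t = 0.0;

  reinit_state(succ, inf, press, ninf, S, t0, t, reinit_prob, reinit_mode);
  ++n_reinits;

  while (t < duration) {
    if (ninf == 0) {
      reinit_state(succ, inf, press, ninf, S, t0, t, reinit_prob, reinit_mode);
      ++n_reinits;
      continue;
    }
    double rate = r * ninf + beta * S;
    if (rate <= 0.0) break;              // absorbing (e.g. r = 0, all infected)
    double dt = R::exp_rand() / rate;
    if (t + dt >= duration) { t = duration; break; }
    t += dt;
    double u = R::unif_rand() * rate;
    if (u < r * ninf) {                  // recovery
      int k = (int)(u / r);              // k-th infected node
      if (k >= ninf) k = ninf - 1;
      int j = -1, seen = 0;
      for (int v = 0; v < n; ++v)
        if (inf[v] && seen++ == k) { j = v; break; }
      inf[j] = 0;
      --ninf;
      tinf[j] += t - t0[j];
      S += press[j];
      for (int i : succ[j]) {
        press[i]--;
        if (!inf[i]) S -= 1.0;
      }
    } else {                             // transmission to susceptible i
      double target = (u - r * ninf) / beta, acc = 0.0;
      int i = -1;
      for (int v = 0; v < n; ++v) {
        if (inf[v] || press[v] == 0) continue;
        acc += press[v];
        if (acc > target) { i = v; break; }
      }
      if (i < 0) continue;               // numerical edge of the partition
      inf[i] = 1;
      ++ninf;
      t0[i] = t;
      S -= press[i];
      for (int k : succ[i]) {
        press[k]++;
        if (!inf[k]) S += 1.0;
      }
    }
  }
  for (int v = 0; v < n; ++v)
    if (inf[v]) tinf[v] += duration - t0[v];

  NumericVector p_hat(n);
  for (int v = 0; v < n; ++v) p_hat[v] = tinf[v] / duration;
  return List::create(_["p_hat"] = p_hat, _["n_reinits"] = n_reinits);
}

// ---- Jain-Krishna fast structural step -------------------------------------

struct JKStructure {
  bool has_cycle, single_cycle, converged;
  int S;
  std::vector<int> weak;     // 0-based candidate set for elimination
};

// Iterative Tarjan SCC; comp ids are assigned in reverse topological order
// of the condensation (an SCC's successors always get smaller ids).
static int tarjan_comps(const std::vector<std::vector<int>>& succ,
                        std::vector<int>& comp) {
  const int n = (int)succ.size();
  comp.assign(n, -1);
  std::vector<int> index(n, -1), low(n, 0), stk;
  std::vector<char> onstack(n, 0);
  int idx = 0, ncomp = 0;
  std::vector<std::pair<int, size_t>> dfs;
  for (int root = 0; root < n; ++root) {
    if (index[root] != -1) continue;
    dfs.clear();
    dfs.push_back({root, 0});
    index[root] = low[root] = idx++;
    stk.push_back(root);
    onstack[root] = 1;
    while (!dfs.empty()) {
      int v = dfs.back().first;
      size_t& pos = dfs.back().second;
      if (pos < succ[v].size()) {
        int w = succ[v][pos++];
        if (index[w] == -1) {
          index[w] = low[w] = idx++;
          stk.push_back(w);
          onstack[w] = 1;
          dfs.push_back({w, 0});
        } else if (onstack[w]) {
          low[v] = std::min(low[v], index[w]);
        }
      } else {
        if (low[v] == index[v]) {
          int w;
          do {
            w = stk.back();
            stk.pop_back();
            onstack[w] = 0;
            comp[w] = ncomp;
          } while (w != v);
          ++ncomp;
        }
        dfs.pop_back();
        if (!dfs.empty()) low[dfs.back().first] =
          std::min(low[dfs.back().first], low[v]);
      }
    }
  }
  return ncomp;
}

// spectral radius of the subgraph induced by `nodes` (power iteration on
// I + M restricted to the SCC; strictly dominant real eigenvalue there)
static double scc_spectral_radius(const std::vector<std::vector<int>>& succ,
                                  const std::vector<int>& comp,
                                  const std::vector<int>& nodes, int cid) {
  const int m = (int)nodes.size();
  std::vector<int> pos(succ.size(), -1);
  for (int k = 0; k < m; ++k) pos[nodes[k]] = k;
  std::vector<double> x(m, 1.0 / m), y(m);
  double lam = 1.0;
  for (int it = 0; it < 20000; ++it) {
    for (int k = 0; k < m; ++k) y[k] = x[k];
    for (int k = 0; k < m; ++k)
      for (int v : succ[nodes[k]])
        if (comp[v] == cid) y[pos[v]] += x[k];
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += y[k];
    double lam_new = s;                    // sum(x) == 1 before the sweep
    double d = 0.0;
    for (int k = 0; k < m; ++k) {
      y[k] /= s;
      d = std::max(d, std::fabs(y[k] - x[k]));
      x[k] = y[k];
    }
    if (d <= 1e-13 && std::fabs(lam_new - lam) <= 1e-13) { lam = lam_new; break; }
    lam = lam_new;
  }
  return lam - 1.0;                        // spectral radius of M itself
}

// Per-step structure of the linear attractor, resolved exactly from the
// topology: acyclic networks concentrate on ends of maximal chains
// (longest-path DP); single-cycle networks have x proportional to the
// integer cycle-to-node path multiplicity; multi-cycle networks are handled
// through the SCC condensation -- the asymptotic support is the set of nodes
// reachable from the dominant-eigenvalue SCCs of maximal driving depth
// (chains of equal-lambda SCCs feeding one another grow by an extra power
// of t, so only the terminal SCCs of the deepest chains keep relative
// mass).  Attractor values (via power iteration) are needed only when every
// node is populated, where the dominant eigenspace is non-defective.  The
// "weak" set is the attractor's minimum set: the unpopulated nodes if any,
// else the nodes at the minimal positive value.
static JKStructure jk_structure_core(const IntegerMatrix& A) {
  const int n = A.nrow();
  std::vector<std::vector<int>> succ(n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (A(i, j) != 0) succ[j].push_back(i);

  JKStructure st;
  st.converged = true;

  std::vector<int> comp;
  int ncomp = tarjan_comps(succ, comp);
  std::vector<int> comp_size(ncomp, 0), internal_edges(ncomp, 0);
  for (int v = 0; v < n; ++v) comp_size[comp[v]]++;
  for (int j = 0; j < n; ++j)
    for (int i : succ[j])
      if (comp[i] == comp[j]) internal_edges[comp[j]]++;

  std::vector<int> cyclic;
  for (int c = 0; c < ncomp; ++c) if (comp_size[c] >= 2) cyclic.push_back(c);
  st.has_cycle = !cyclic.empty();
  st.single_cycle = cyclic.size() == 1 &&
    internal_edges[cyclic[0]] == comp_size[cyclic[0]];

  if (!st.has_cycle) {
    // longest incoming path per node (graph is a DAG here)
    std::vector<int> lp(n, 0), deg(n, 0), topo;
    for (int j = 0; j < n; ++j) for (int i : succ[j]) deg[i]++;
    topo.reserve(n);
    for (int i = 0; i < n; ++i) if (deg[i] == 0) topo.push_back(i);
    for (size_t q = 0; q < topo.size(); ++q) {
      int u = topo[q];
      for (int v : succ[u]) {
        if (lp[u] + 1 > lp[v]) lp[v] = lp[u] + 1;
        if (--deg[v] == 0) topo.push_back(v);
      }
    }
    int kmax = 0;
    for (int i = 0; i < n; ++i) kmax = std::max(kmax, lp[i]);
    st.S = 0;
    for (int i = 0; i < n; ++i) if (lp[i] == kmax) st.S++;
    if (kmax == 0) {
      for (int i = 0; i < n; ++i) st.weak.push_back(i);
    } else {
      for (int i = 0; i < n; ++i) if (lp[i] < kmax) st.weak.push_back(i);
    }
    return st;
  }

  if (st.single_cycle) {
    std::vector<char> on_cycle(n, 0);
    for (int v = 0; v < n; ++v) if (comp[v] == cyclic[0]) on_cycle[v] = 1;
    // integer path-multiplicity DP in topological order of the off-cycle part
    std::vector<double> mult(n, 0.0);
    std::vector<int> deg(n, 0), topo;
    for (int i = 0; i < n; ++i) {
      if (on_cycle[i]) { mult[i] = 1.0; continue; }
      for (int j = 0; j < n; ++j)
        if (A(i, j) != 0 && !on_cycle[j]) deg[i]++;
    }
    for (int i = 0; i < n; ++i) if (!on_cycle[i] && deg[i] == 0) topo.push_back(i);
    for (size_t q = 0; q < topo.size(); ++q) {
      int u = topo[q];
      // multiplicity of u = sum over all in-neighbours (cycle nodes carry 1)
      double s = 0.0;
      for (int j = 0; j < n; ++j) if (A(u, j) != 0) s += mult[j];
      mult[u] = s;
      for (int v : succ[u])
        if (!on_cycle[v] && --deg[v] == 0) topo.push_back(v);
    }
    st.S = 0;
    bool any_zero = false;
    for (int i = 0; i < n; ++i) {
      if (mult[i] > 0) st.S++; else any_zero = true;
    }
    for (int i = 0; i < n; ++i) {
      if (any_zero) { if (mult[i] == 0) st.weak.push_back(i); }
      else if (mult[i] == 1.0) st.weak.push_back(i);
    }
    return st;
  }

  // multi-cycle: dominant SCCs and driving depth in the condensation
  std::vector<double> lam(ncomp, 0.0);
  double lam_max = 0.0;
  for (int c : cyclic) {
    if (internal_edges[c] == comp_size[c]) lam[c] = 1.0;  // simple cycle
    else {
      std::vector<int> nodes;
      for (int v = 0; v < n; ++v) if (comp[v] == c) nodes.push_back(v);
      lam[c] = scc_spectral_radius(succ, comp, nodes, c);
    }
    lam_max = std::max(lam_max, lam[c]);
  }
  std::vector<char> dominant(ncomp, 0);
  for (int c : cyclic)
    if (lam[c] >= lam_max * (1.0 - 1e-10)) dominant[c] = 1;

  // condensation in-edges; comp ids are reverse-topological, so scanning
  // comps downward processes predecessors before successors
  std::vector<std::vector<int>> comp_pred(ncomp), comp_succ(ncomp);
  for (int j = 0; j < n; ++j)
    for (int i : succ[j])
      if (comp[j] != comp[i]) {
        comp_pred[comp[i]].push_back(comp[j]);
        comp_succ[comp[j]].push_back(comp[i]);
      }
  std::vector<int> depth(ncomp, 0);
  int dmax = 0;
  for (int c = ncomp - 1; c >= 0; --c) {
    int d = 0;
    for (int p : comp_pred[c]) d = std::max(d, depth[p]);
    depth[c] = d + (dominant[c] ? 1 : 0);
    if (dominant[c]) dmax = std::max(dmax, depth[c]);
  }
  // support: everything reachable from the deepest dominant SCCs
  std::vector<char> reach(ncomp, 0);
  std::vector<int> bfs;
  for (int c = 0; c < ncomp; ++c)
    if (dominant[c] && depth[c] == dmax) { reach[c] = 1; bfs.push_back(c); }
  for (size_t q = 0; q < bfs.size(); ++q)
    for (int d : comp_succ[bfs[q]])
      if (!reach[d]) { reach[d] = 1; bfs.push_back(d); }

  st.S = 0;
  for (int v = 0; v < n; ++v) if (reach[comp[v]]) st.S++;
  if (st.S < n) {
    for (int v = 0; v < n; ++v) if (!reach[comp[v]]) st.weak.push_back(v);
    return st;
  }

  // fully populated: need the attractor values for the minimum set
  std::vector<double> x(n, 1.0 / n), y(n), xb(x);
  const int max_iter = 30000, block = 50;
  st.converged = false;
  for (int it = 1; it <= max_iter; ++it) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) y[i] = x[i];
    for (int j = 0; j < n; ++j) {
      double xj = x[j];
      if (xj == 0.0) continue;
      for (int i : succ[j]) y[i] += xj;
    }
    for (int i = 0; i < n; ++i) s += y[i];
    for (int i = 0; i < n; ++i) x[i] = y[i] / s;
    if (it % block == 0) {
      double d = 0.0;
      for (int i = 0; i < n; ++i) d = std::max(d, std::fabs(x[i] - xb[i]));
      if (d <= 1e-13) { st.converged = true; break; }
      xb = x;
    }
  }
  double xmin = x[0];
  for (int i = 1; i < n; ++i) xmin = std::min(xmin, x[i]);
  for (int i = 0; i < n; ++i)
    if (x[i] <= xmin * (1.0 + 1e-9)) st.weak.push_back(i);
  return st;
}

// [[Rcpp::export]]
List cpp_jk_structure(const IntegerMatrix& A) {
  JKStructure st = jk_structure_core(A);
  IntegerVector weak(st.weak.size());
  for (size_t k = 0; k < st.weak.size(); ++k) weak[k] = st.weak[k] + 1;
  return List::create(_["has_cycle"] = st.has_cycle,
                      _["single_cycle"] = st.single_cycle,
                      _["S"] = st.S, _["weak"] = weak,
                      _["converged"] = st.converged);
}

// Full slow-timescale loop: per step, record structure flags, then replace a
// uniformly chosen weakest node by a newcomer wired with probability
// m / (n - 1) per ordered pair.  RNG draws match the R-level jk_replace()
// exactly (one draw for the tie-break when the weak set has > 1 member, then
// n - 1 in-link draws and n - 1 out-link draws in ascending node order), so
// runs are reproducible and interchangeable with the R path under one seed.
// [[Rcpp::export]]
List cpp_jk_run(const IntegerMatrix& A0, double m, int n_steps,
                int stop_after_collapses) {
  IntegerMatrix A = clone(A0);
  const int n = A.nrow();
  const double p = m / (n - 1);
  IntegerVector S(n_steps);
  LogicalVector has_cycle(n_steps), single_cycle(n_steps);
  int n_collapses = 0, t_done = n_steps;
  bool prev_cycle = false;

  for (int t = 0; t < n_steps; ++t) {
    JKStructure st = jk_structure_core(A);
    S[t] = st.S;
    has_cycle[t] = st.has_cycle;
    single_cycle[t] = st.single_cycle;
    if (t > 0 && prev_cycle && !st.has_cycle) ++n_collapses;
    prev_cycle = st.has_cycle;
    if (stop_after_collapses > 0 && n_collapses >= stop_after_collapses) {
      t_done = t + 1;
      break;
    }
    int w;
    if (st.weak.size() == 1) w = st.weak[0];
    else {
      int k = (int)(R::unif_rand() * st.weak.size());
      if (k >= (int)st.weak.size()) k = (int)st.weak.size() - 1;
      w = st.weak[k];
    }
    for (int j = 0; j < n; ++j) { A(w, j) = 0; A(j, w) = 0; }
    for (int j = 0; j < n; ++j) {           // in-links j -> w
      if (j == w) continue;
      A(w, j) = (R::unif_rand() < p) ? 1 : 0;
    }
    for (int j = 0; j < n; ++j) {           // out-links w -> j
      if (j == w) continue;
      A(j, w) = (R::unif_rand() < p) ? 1 : 0;
    }
  }
  return List::create(
    _["S"] = S[Range(0, t_done - 1)],
    _["has_cycle"] = has_cycle[Range(0, t_done - 1)],
    _["single_cycle"] = single_cycle[Range(0, t_done - 1)],
    _["n_collapses"] = n_collapses, _["steps_run"] = t_done);
}
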