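#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Hazard lookup: gaps beyond the tabulated support force activation.
static inline double haz(const std::vector<double>& h, int gap) {
  return (gap <= (int)h.size()) ? h[gap - 1] : 1.0;
}

// Run the spanning-tree construction on a fixed forest for t_tol steps.
//
// order:     node ids (1-based), every parent before its children
// parent:    parent id per node, 0 for roots
// node_tab:  hazard-table index per node (1-based into `tables`)
// trunk_tab: hazard-table index of the trunk above each node, 0 for roots
// tables:    list of numeric hazard vectors (hazard[g], g = 1..support_max)
//
// Exactly one uniform deviate is consumed per node per step, in `order`,
// so runs are reproducible from R's seed and match the R reference engine.
// Returns per-node activation time lists (times 0..t_tol, 0 always active);
// trunk and branch activity is derived in R as the intersection of endpoint
// activations (link state = product of endpoint states).
// [[Rcpp::export]]
List cpp_construct_tree(IntegerVector order, IntegerVector parent,
                        IntegerVector node_tab, IntegerVector trunk_tab,
                        List tables, int t_tol, double tol = 1e-12) {
  const int n = parent.size();
  std::vector<std::vector<double>> H(tables.size());
  for (int k = 0; k < tables.size(); ++k) {
    NumericVector v = tables[k];
    H[k].assign(v.begin(), v.end());
  }
  std::vector<int> last_node(n, 0), last_trunk(n, 0);
  std::vector<std::vector<int>> acts(n);
  for (int i = 0; i < n; ++i) acts[i].push_back(0);
  std::vector<double> hcur(n, 0.0);
  std::vector<char> scur(n, 1);

  bool ok = true;
  int bad_t = 0, bad_child = 0;
  double bad_p = 0.0;
  std::string bad_name;

  for (int t = 1; t <= t_tol && ok; ++t) {
    for (int oi = 0; oi < n; ++oi) {
      const int v = order[oi] - 1;
      const double hv = haz(H[node_tab[v] - 1], t - last_node[v]);
      const double u = R::unif_rand();
      bool on;
      const int p = parent[v];
      if (p == 0) {
        on = (u < hv);
      } else {
        const int pi = p - 1;
        const double hp = hcur[pi];
        double hz = haz(H[trunk_tab[v] - 1], t - last_trunk[v]);
        const double p2 = hp - hz, p3 = hv - hz, p4 = 1.0 + hz - hp - hv;
        if (p2 < -tol || p3 < -tol || p4 < -tol) {
          ok = false; bad_t = t; bad_child = v + 1;
          if (p2 <= p3 && p2 <= p4) { bad_name = "p2"; bad_p = p2; }
          else if (p3 <= p4)        { bad_name = "p3"; bad_p = p3; }
          else                      { bad_name = "p4"; bad_p = p4; }
          break;
        }
        if (hz > hp) hz = hp;   // clip rounding noise
        if (hz > hv) hz = hv;
        double cond;
        if (scur[pi]) cond = (hp > 0.0) ? hz / hp : 1.0;
        else          cond = (hp < 1.0) ? (hv - hz) / (1.0 - hp) : 0.0;
        if (cond < 0.0) cond = 0.0;
        if (cond > 1.0) cond = 1.0;
        on = (u < cond);
        if (on && scur[pi]) last_trunk[v] = t;
      }
      hcur[v] = hv;
      scur[v] = on;
      if (on) { last_node[v] = t; acts[v].push_back(t); }
    }
  }

  List out(n);
  for (int i = 0; i < n; ++i)
    out[i] = IntegerVector(acts[i].begin(), acts[i].end());
  if (ok) return List::create(_["ok"] = true, _["node_activations"] = out);
  return List::create(_["ok"] = false, _["node_activations"] = out,
                      _["time"] = bad_t, _["child"] = bad_child,
                      _["p_name"] = bad_name, _["p_value"] = bad_p);
}
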