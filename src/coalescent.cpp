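// Structured Kingman coalescent with piecewise-constant deme sizes,
// divergence (lineage-transfer) events, and SNP-ascertainment mutation
// dropping.  Uses R's RNG so set.seed() governs reproducibility.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

// current size of deme d at backward time t, given per-deme step functions
// (start times sorted ascending; size applies from start_time onward)
double deme_size(const std::vector<std::vector<double> > &starts,
                 const std::vector<std::vector<double> > &sizes,
                 int d, double t) {
  const std::vector<double> &st = starts[d];
  // last epoch with start <= t
  int lo = 0, hi = (int)st.size() - 1, ans = 0;
  while (lo <= hi) {
    int mid = (lo + hi) / 2;
    if (st[mid] <= t) { ans = mid; lo = mid + 1; } else hi = mid - 1;
  }
  return sizes[d][ans];
}

struct Breakpoint {
  double time;
  int kind;   // 0 = size change (rate refresh only), 1 = merge event
  int from, to;
};

} // namespace

// [[Rcpp::export(name = ".sim_genealogy_cpp")]]
List sim_genealogy_cpp(IntegerVector n_lineages,     // haploid sample per deme
                       List epoch_starts,            // per deme: numeric starts
                       List epoch_sizes,             // per deme: diploid sizes
                       NumericVector ev_time,        // merge events, sorted
                       IntegerVector ev_from,        // 0-based deme indices
                       IntegerVector ev_to) {
  int D = n_lineages.size();
  int n = 0;
  for (int d = 0; d < D; ++d) n += n_lineages[d];
  if (n < 1) stop("no lineages sampled");

  std::vector<std::vector<double> > starts(D), sizes(D);
  for (int d = 0; d < D; ++d) {
    NumericVector s = epoch_starts[d], z = epoch_sizes[d];
    if (s.size() != z.size() || s.size() == 0)
      stop("malformed epoch table for deme %d", d + 1);
    for (int i = 0; i < s.size(); ++i) {
      if (z[i] <= 0) stop("non-positive deme size in epoch table");
      starts[d].push_back(s[i]);
      sizes[d].push_back(z[i]);
    }
  }

  // breakpoints: all epoch starts > 0 plus merge events, time-sorted;
  // merges after size changes at equal times
  std::vector<Breakpoint> bp;
  for (int d = 0; d < D; ++d)
    for (size_t i = 0; i < starts[d].size(); ++i)
      if (starts[d][i] > 0)
        bp.push_back(Breakpoint{starts[d][i], 0, -1, -1});
  for (int i = 0; i < ev_time.size(); ++i)
    bp.push_back(Breakpoint{ev_time[i], 1, ev_from[i], ev_to[i]});
  std::stable_sort(bp.begin(), bp.end(),
                   [](const Breakpoint &a, const Breakpoint &b) {
                     if (a.time != b.time) return a.time < b.time;
                     return a.kind < b.kind;
                   });

  int n_nodes = 2 * n - 1;
  NumericVector times(n_nodes, 0.0);
  IntegerVector parent(n_nodes, -1);
  IntegerVector leaf_deme(n);

  std::vector<std::vector<int> > act(D);  // active node ids per deme
  int id = 0;
  for (int d = 0; d < D; ++d)
    for (int i = 0; i < n_lineages[d]; ++i) {
      act[d].push_back(id);
      leaf_deme[id] = d;
      ++id;
    }

  RNGScope scope;
  double t = 0.0;
  int next_node = n, active_total = n;
  size_t bp_i = 0;
  std::vector<double> lam(D);

  while (active_total > 1) {
    double R = 0.0;
    for (int d = 0; d < D; ++d) {
      double k = (double)act[d].size();
      lam[d] = (k > 1) ? k * (k - 1.0) / (4.0 * deme_size(starts, sizes, d, t))
                       : 0.0;
      R += lam[d];
    }
    double tb = (bp_i < bp.size()) ? bp[bp_i].time : R_PosInf;
    double dt = (R > 0.0) ? exp_rand() / R : R_PosInf;
    if (t + dt < tb) {
      t += dt;
      // choose deme proportional to lam
      double u = unif_rand() * R, acc = 0.0;
      int d = D - 1;
      for (int j = 0; j < D; ++j) {
        acc += lam[j];
        if (u <= acc) { d = j; break; }
      }
      int k = (int)act[d].size();
      int i = (int)std::floor(unif_rand() * k); if (i >= k) i = k - 1;
      int j = (int)std::floor(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      int a = act[d][i], b = act[d][j];
      int p = next_node++;
      times[p] = t;
      parent[a] = p; parent[b] = p;
      // replace a by p, remove b (b still sits at index j)
      act[d][i] = p;
      act[d].erase(act[d].begin() + j);
      active_total -= 1;
    } else {
      if (!R_finite(tb))
        stop("coalescent stalled: lineages in disconnected demes with no remaining events");
      t = tb;
      if (bp[bp_i].kind == 1) {
        int f = bp[bp_i].from, g = bp[bp_i].to;
        for (size_t q = 0; q < act[f].size(); ++q) act[g].push_back(act[f][q]);
        act[f].clear();
      }
      ++bp_i;
    }
  }

  double tbl = 0.0;
  for (int v = 0; v < n_nodes - 1; ++v) tbl += times[parent[v]] - times[v];

  return List::create(_["n_leaves"] = n,
                      _["times"] = times,
                      _["parent"] = parent,
                      _["leaf_deme"] = leaf_deme + 1,
                      _["total_branch_length"] = tbl);
}

// [[Rcpp::export(name = ".drop_snps_cpp")]]
IntegerMatrix drop_snps_cpp(IntegerVector parent, NumericVector times,
                            int n_leaves, int n_snps, double maf_min,
                            int max_tries) {
  int n_nodes = parent.size();
  if (n_leaves == 1) stop("cannot place SNPs on a single-lineage genealogy");
  // descendant leaf lists per node
  std::vector<std::vector<int> > leaves(n_nodes);
  for (int v = 0; v < n_leaves; ++v) leaves[v].push_back(v);
  // nodes are created in time order, so ascending id = bottom-up
  for (int v = 0; v < n_nodes - 1; ++v) {
    int p = parent[v];
    for (size_t i = 0; i < leaves[v].size(); ++i)
      leaves[p].push_back(leaves[v][i]);
  }
  std::vector<double> cum(n_nodes - 1);
  double tot = 0.0;
  for (int v = 0; v < n_nodes - 1; ++v) {
    tot += times[parent[v]] - times[v];
    cum[v] = tot;
  }
  if (tot <= 0.0) stop("genealogy has zero total branch length");

  RNGScope scope;
  IntegerMatrix hap(n_snps, n_leaves);
  int filled = 0, tries = 0;
  while (filled < n_snps) {
    if (++tries > max_tries)
      stop("SNP ascertainment failed: could not reach MAF %.3f after %d tries",
           maf_min, max_tries);
    double u = unif_rand() * tot;
    int v = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (v >= n_nodes - 1) v = n_nodes - 2;
    int c = (int)leaves[v].size();
    double maf = std::min(c, n_leaves - c) / (double)n_leaves;
    if (maf < maf_min - 1e-12) continue;
    for (size_t i = 0; i < leaves[v].size(); ++i)
      hap(filled, leaves[v][i]) = 1;
    ++filled;
  }
  return hap;
}
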