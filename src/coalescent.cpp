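#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Ancestral recombination process over a row of L markers at fixed
// positions, with recombination permitted only between adjacent markers.
// Time is in coalescent units (pairwise coalescence rate 1, i.e. units of
// 2N generations for a diploid population of size N), so the per-interval
// recombination rate on a lineage equals the population rate 2Nr supplied
// as `rho`. Multiple recombination events per interval are allowed.
//
// One marginal tree is recorded per marker: node ids 0..(2*nh - 2), leaves
// 0..(nh - 1) at time 0, internal nodes numbered in coalescence order for
// that marker, root = 2*nh - 2 with parent -1.

namespace {

struct Lineage {
  std::vector<int> node;  // per-marker tree-node id; -1 = not ancestral
  int lo, hi;             // first/last ancestral marker index; -1 if none

  void refresh() {
    lo = -1; hi = -1;
    for (int m = 0; m < (int)node.size(); ++m) {
      if (node[m] >= 0) { if (lo < 0) lo = m; hi = m; }
    }
  }
  int span() const { return (lo < 0) ? 0 : hi - lo; }
  bool empty() const { return lo < 0; }
};

inline int rand_below(int k) {
  int i = (int)(unif_rand() * k);
  return (i >= k) ? k - 1 : i;
}

}  // namespace

// [[Rcpp::export(name = ".simulate_arg_cpp")]]
List simulate_arg_cpp(int n_haplotypes, int n_markers, double rho) {
  const int nh = n_haplotypes, L = n_markers;
  if (nh < 2) stop("need at least 2 haplotypes");
  if (L < 1) stop("need at least 1 marker");
  if (rho < 0) stop("rho must be non-negative");

  const int n_nodes = 2 * nh - 1;
  IntegerMatrix parent(n_nodes, L);
  NumericMatrix node_time(n_nodes, L);
  std::fill(parent.begin(), parent.end(), -1);

  std::vector<int> next_node(L, nh);   // next free internal node per marker
  std::vector<int> carriers(L, nh);    // lineages ancestral to each marker
  int n_done = 0;

  std::vector<Lineage> lin(nh);
  for (int i = 0; i < nh; ++i) {
    lin[i].node.assign(L, -1);
    for (int m = 0; m < L; ++m) lin[i].node[m] = i;
    lin[i].lo = 0; lin[i].hi = L - 1;
  }

  double t = 0.0;
  while (n_done < L) {
    const int k = (int)lin.size();
    double span_total = 0.0;
    for (int i = 0; i < k; ++i) span_total += lin[i].span();
    const double rate_coal = 0.5 * k * (k - 1);
    const double rate_rec = rho * span_total;
    const double rate = rate_coal + rate_rec;
    t += exp_rand() / rate;

    if (unif_rand() * rate < rate_coal) {
      // coalescence: merge two random lineages (into the lower slot so the
      // swap-removal of the higher slot cannot move the merged lineage)
      int i = rand_below(k);
      int j = rand_below(k - 1);
      if (j >= i) ++j;
      if (i > j) std::swap(i, j);
      Lineage &a = lin[i];
      Lineage &b = lin[j];
      for (int m = 0; m < L; ++m) {
        const int na = a.node[m], nb = b.node[m];
        if (na >= 0 && nb >= 0) {
          const int v = next_node[m]++;
          parent(na, m) = v;
          parent(nb, m) = v;
          node_time(v, m) = t;
          a.node[m] = v;
          if (--carriers[m] == 1) {  // v is this marker's grand MRCA
            a.node[m] = -1;
            ++n_done;
          }
        } else if (nb >= 0) {
          a.node[m] = nb;
        }
      }
      a.refresh();
      lin[j] = lin.back();
      lin.pop_back();
      if (a.empty()) {
        lin[i] = lin.back();
        lin.pop_back();
      }
    } else {
      // recombination: split one lineage, breakpoint ~ span-weighted
      double u = unif_rand() * span_total;
      int i = -1;
      for (int q = 0; q < k; ++q) {
        if (lin[q].span() == 0) continue;
        i = q;
        u -= lin[q].span();
        if (u <= 0) break;
      }
      const Lineage &a = lin[i];
      const int brk = a.lo + rand_below(a.span());  // between brk and brk+1
      Lineage left, right;
      left.node.assign(L, -1);
      right.node.assign(L, -1);
      for (int m = 0; m < L; ++m) {
        if (a.node[m] < 0) continue;
        if (m <= brk) left.node[m] = a.node[m];
        else right.node[m] = a.node[m];
      }
      left.refresh();
      right.refresh();
      lin[i] = left;
      lin.push_back(right);
    }
  }

  return List::create(_["parent"] = parent, _["time"] = node_time,
                      _["n_leaves"] = nh);
}

// Leaf counts below every node of one marginal tree.
// [[Rcpp::export(name = ".leaf_counts_cpp")]]
IntegerVector leaf_counts_cpp(IntegerVector parent, NumericVector node_time,
                              int n_leaves) {
  const int n = parent.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return node_time[a] < node_time[b];
  });
  IntegerVector cnt(n, 0);
  for (int i = 0; i < n_leaves; ++i) cnt[i] = 1;
  for (int idx = 0; idx < n; ++idx) {
    const int v = ord[idx];
    if (parent[v] >= 0) cnt[parent[v]] += cnt[v];
  }
  return cnt;
}

// Drop one mutation on a branch of a marginal tree, branch chosen with
// probability proportional to its length among branches whose descendant
// clade has minor-allele frequency inside [min_maf, max_maf]. Returns the
// 0/1 allele column over leaves, or an empty vector when no branch is
// eligible (caller resamples the genealogy).
// [[Rcpp::export(name = ".place_mutation_cpp")]]
IntegerVector place_mutation_cpp(IntegerVector parent, NumericVector node_time,
                                 int n_leaves, double min_maf, double max_maf) {
  const int n = parent.size();
  IntegerVector cnt = leaf_counts_cpp(parent, node_time, n_leaves);

  const double eps = 1e-12;
  double total = 0.0;
  std::vector<double> w(n, 0.0);
  for (int v = 0; v < n; ++v) {
    if (parent[v] < 0) continue;  // root carries no branch
    const int kk = cnt[v];
    const double maf = (double)std::min(kk, n_leaves - kk) / n_leaves;
    if (maf >= min_maf - eps && maf <= max_maf + eps) {
      w[v] = node_time[parent[v]] - node_time[v];
      total += w[v];
    }
  }
  if (total <= 0) return IntegerVector(0);

  double u = unif_rand() * total;
  int chosen = -1;
  for (int v = 0; v < n; ++v) {
    if (w[v] <= 0) continue;
    u -= w[v];
    chosen = v;
    if (u <= 0) break;
  }

  // leaves under `chosen` get the derived allele
  std::vector<std::vector<int>> children(n);
  for (int v = 0; v < n; ++v)
    if (parent[v] >= 0) children[parent[v]].push_back(v);
  IntegerVector col(n_leaves, 0);
  std::vector<int> stack{chosen};
  while (!stack.empty()) {
    const int v = stack.back();
    stack.pop_back();
    if (v < n_leaves) col[v] = 1;
    else for (int c : children[v]) stack.push_back(c);
  }
  return col;
}
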