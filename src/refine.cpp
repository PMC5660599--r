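#include <Rcpp.h>
#include <set>
#include <vector>
using namespace Rcpp;

// Constrained agglomerative local search over disjoint clusters.
//
// At each iteration three move families are evaluated: merging two clusters,
// removing one protein from a multi-protein cluster (it becomes a singleton),
// and switching one protein from its cluster to another. The move with the
// largest integrated gain is applied, but only moves that increase BOTH the
// expression LLR and the interaction LLR qualify; iteration stops when no
// move qualifies or when max_iter is reached.
//
// E        dense symmetric matrix of per-pair expression LLRs with a ZERO
//          diagonal (0 = no evidence; the zero diagonal is assumed by the
//          cached cluster row sums)
// edge_a/b 0-based endpoints of network edges, edge_w their interaction LLRs
//          (non-edges carry interaction LLR 0, so only cluster pairs joined
//          by an edge can gain interaction score: merge candidates and
//          switch targets are restricted accordingly)
// init     0-based initial cluster assignment (from greedy seeding)
//
// For speed each cluster keeps a cached sum vector
//   csum[c][x] = sum over members m of c of E(m, x)
// so merge deltas cost O(min cluster size) and remove/switch deltas O(1).
// Enumeration order is fixed (cluster index pairs, then cluster/member
// order, then gene/target order) and the best move is taken by strict
// comparison, so results are deterministic for identical inputs.

struct Move {
  int kind;        // 0 none, 1 merge, 2 remove, 3 switch
  int p1, p2;      // merge: clusters; remove: gene,-; switch: gene,target
  double de, di;
  double total() const { return de + di; }
};

// [[Rcpp::export]]
List refine_clusters_cpp(NumericMatrix E,
                         IntegerVector edge_a, IntegerVector edge_b,
                         NumericVector edge_w,
                         IntegerVector init, int max_iter) {
  const int n = E.nrow();
  std::vector<std::vector<std::pair<int, double> > > adj(n);
  const int m = edge_a.size();
  for (int k = 0; k < m; ++k) {
    adj[edge_a[k]].push_back(std::make_pair(edge_b[k], edge_w[k]));
    adj[edge_b[k]].push_back(std::make_pair(edge_a[k], edge_w[k]));
  }

  int nc = 0;
  for (int i = 0; i < n; ++i) nc = std::max(nc, init[i] + 1);
  std::vector<std::vector<int> > members(nc);
  std::vector<int> assign(n);
  for (int i = 0; i < n; ++i) {
    assign[i] = init[i];
    members[init[i]].push_back(i);
  }
  std::vector<std::vector<double> > csum(nc, std::vector<double>(n, 0.0));
  for (int c = 0; c < nc; ++c)
    for (size_t x = 0; x < members[c].size(); ++x) {
      const int g = members[c][x];
      for (int j = 0; j < n; ++j) csum[c][j] += E(g, j);
    }

  // interaction LLR between a gene and a cluster via the adjacency list
  // (edges are sparse, so this is cheap)
  std::vector<int> log_iter, log_kind;
  std::vector<double> log_de, log_di;
  bool capped = false;

  for (int iter = 1; ; ++iter) {
    if (iter > max_iter) { capped = true; break; }
    Move best; best.kind = 0; best.de = 0; best.di = 0;

    // ---- merges: cluster pairs connected by at least one edge ----
    std::set<std::pair<int, int> > cand;
    for (int k = 0; k < m; ++k) {
      int ca = assign[edge_a[k]], cb = assign[edge_b[k]];
      if (ca != cb) cand.insert(std::make_pair(std::min(ca, cb), std::max(ca, cb)));
    }
    for (std::set<std::pair<int, int> >::const_iterator it = cand.begin();
         it != cand.end(); ++it) {
      int a = it->first, b = it->second;
      if (members[a].size() > members[b].size()) std::swap(a, b);
      const std::vector<int>& A = members[a];  // smaller cluster
      double de = 0.0, di = 0.0;
      for (size_t x = 0; x < A.size(); ++x) de += csum[b][A[x]];
      for (size_t x = 0; x < A.size(); ++x) {
        const std::vector<std::pair<int, double> >& nb = adj[A[x]];
        for (size_t e = 0; e < nb.size(); ++e)
          if (assign[nb[e].first] == b) di += nb[e].second;
      }
      if (de > 0 && di > 0 && de + di > best.total()) {
        best.kind = 1; best.p1 = it->first; best.p2 = it->second;
        best.de = de; best.di = di;
      }
    }

    // ---- removals: any member of a multi-protein cluster ----
    for (int c = 0; c < (int)members.size(); ++c) {
      if (members[c].size() < 2) continue;
      for (size_t x = 0; x < members[c].size(); ++x) {
        int g = members[c][x];
        double de = -csum[c][g];   // E(g, g) = 0
        if (de <= 0) continue;
        double di = 0.0;
        const std::vector<std::pair<int, double> >& nb = adj[g];
        for (size_t e = 0; e < nb.size(); ++e)
          if (assign[nb[e].first] == c) di -= nb[e].second;
        if (di > 0 && de + di > best.total()) {
          best.kind = 2; best.p1 = g; best.p2 = -1;
          best.de = de; best.di = di;
        }
      }
    }

    // ---- switches: relocate a protein to a cluster holding one of its
    // interaction partners (singleton sources are merges, handled above) ----
    for (int g = 0; g < n; ++g) {
      int c = assign[g];
      if (members[c].size() < 2) continue;
      double loss_e = csum[c][g], loss_i = 0.0;
      const std::vector<std::pair<int, double> >& nb = adj[g];
      std::set<int> targets;
      for (size_t e = 0; e < nb.size(); ++e) {
        if (assign[nb[e].first] == c) loss_i += nb[e].second;
        else targets.insert(assign[nb[e].first]);
      }
      for (std::set<int>::const_iterator t = targets.begin();
           t != targets.end(); ++t) {
        double de = csum[*t][g] - loss_e;
        if (de <= 0) continue;
        double gain_i = 0.0;
        for (size_t e = 0; e < nb.size(); ++e)
          if (assign[nb[e].first] == *t) gain_i += nb[e].second;
        double di = gain_i - loss_i;
        if (di > 0 && de + di > best.total()) {
          best.kind = 3; best.p1 = g; best.p2 = *t;
          best.de = de; best.di = di;
        }
      }
    }

    if (best.kind == 0) break;

    if (best.kind == 1) {                      // merge p2 into p1
      std::vector<int>& A = members[best.p1];
      std::vector<int>& B = members[best.p2];
      for (size_t y = 0; y < B.size(); ++y) {
        assign[B[y]] = best.p1;
        A.push_back(B[y]);
      }
      B.clear();
      std::vector<double>& sa = csum[best.p1];
      std::vector<double>& sb = csum[best.p2];
      for (int j = 0; j < n; ++j) sa[j] += sb[j];
      std::vector<double>().swap(sb);          // release
    } else if (best.kind == 2) {               // remove -> new singleton
      int g = best.p1, c = assign[g];
      std::vector<int>& C = members[c];
      C.erase(std::find(C.begin(), C.end(), g));
      for (int j = 0; j < n; ++j) csum[c][j] -= E(g, j);
      members.push_back(std::vector<int>(1, g));
      csum.push_back(std::vector<double>(n));
      for (int j = 0; j < n; ++j) csum.back()[j] = E(g, j);
      assign[g] = (int)members.size() - 1;
    } else {                                   // switch g to target
      int g = best.p1, c = assign[g];
      std::vector<int>& C = members[c];
      C.erase(std::find(C.begin(), C.end(), g));
      members[best.p2].push_back(g);
      for (int j = 0; j < n; ++j) {
        csum[c][j] -= E(g, j);
        csum[best.p2][j] += E(g, j);
      }
      assign[g] = best.p2;
    }
    log_iter.push_back(iter);
    log_kind.push_back(best.kind);
    log_de.push_back(best.de);
    log_di.push_back(best.di);
  }

  // renumber clusters densely in order of first member
  std::vector<int> newid(members.size(), -1);
  IntegerVector out_assign(n);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int c = assign[i];
    if (newid[c] < 0) newid[c] = next++;
    out_assign[i] = newid[c];
  }

  CharacterVector kinds(log_kind.size());
  for (size_t k = 0; k < log_kind.size(); ++k) {
    kinds[k] = log_kind[k] == 1 ? "merge" : (log_kind[k] == 2 ? "remove" : "switch");
  }
  return List::create(
    _["assign"] = out_assign,
    _["log"] = DataFrame::create(
      _["iteration"] = wrap(log_iter),
      _["move"] = kinds,
      _["delta_llr_expr"] = wrap(log_de),
      _["delta_llr_int"] = wrap(log_di),
      _["stringsAsFactors"] = false),
    _["capped"] = capped);
}
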