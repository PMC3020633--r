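#include <Rcpp.h>
using namespace Rcpp;

// Event-driven structured coalescent.
//
// Time is measured in units of 4*N_ref generations, tips at 0, increasing
// into the past.  Within a deme of relative size x each lineage pair
// coalesces at rate 2/x; a lineage sitting in deme `from` of an active
// migration phase jumps (backward in time) to deme `to` at the phase's
// per-lineage rate.  At a split time every lineage of the derived deme is
// moved into the ancestral deme.  Splits and phase boundaries partition
// time into intervals of constant rates; at equal times splits are applied
// before migration-phase toggles (boundary list puts splits first).
//
// Randomness comes from R's RNG stream (unif_rand/exp_rand), so set.seed()
// in R fully determines the output.

namespace {

struct Boundary {
  double time;
  int kind;   // 0 = split (processed first on ties), 1 = phase toggle
  int index;  // split index; unused for toggles
};

} // namespace

// [[Rcpp::export(name = ".sim_tree_cpp")]]
List sim_tree_cpp(int n_demes,
                  NumericVector deme_size,
                  NumericVector split_time,
                  IntegerVector split_derived,
                  IntegerVector split_ancestral,
                  NumericVector mig_start,
                  NumericVector mig_end,
                  IntegerVector mig_from,
                  IntegerVector mig_to,
                  NumericVector mig_rate,
                  IntegerVector sample_count) {
  const int n_mig = mig_start.size();
  const int n_split = split_time.size();

  int n_tips = 0;
  for (int d = 0; d < n_demes; ++d) n_tips += sample_count[d];
  if (n_tips < 2) stop("at least two sampled lineages are required");

  const int n_nodes = 2 * n_tips - 1;
  IntegerVector parent(n_nodes, -1);
  NumericVector node_time(n_nodes, 0.0);
  IntegerVector tip_deme(n_tips);

  // active lineages: node index + current deme
  std::vector<int> lin_node(n_tips), lin_deme(n_tips);
  {
    int k = 0;
    for (int d = 0; d < n_demes; ++d)
      for (int i = 0; i < sample_count[d]; ++i) {
        tip_deme[k] = d;
        lin_node[k] = k;
        lin_deme[k] = d;
        ++k;
      }
  }
  int n_active = n_tips;
  int next_node = n_tips;

  // boundaries sorted by (time, kind): splits precede toggles at ties
  std::vector<Boundary> bnd;
  bnd.reserve(n_split + 2 * n_mig);
  for (int s = 0; s < n_split; ++s) bnd.push_back({split_time[s], 0, s});
  for (int m = 0; m < n_mig; ++m) {
    bnd.push_back({mig_start[m], 1, m});
    bnd.push_back({mig_end[m], 1, m});
  }
  std::sort(bnd.begin(), bnd.end(), [](const Boundary& a, const Boundary& b) {
    if (a.time != b.time) return a.time < b.time;
    return a.kind < b.kind;
  });

  std::vector<int> deme_n(n_demes, 0);
  for (int i = 0; i < n_active; ++i) deme_n[lin_deme[i]]++;

  double t = 0.0;
  size_t next_bnd = 0;
  RNGScope scope;

  std::vector<double> coal_rate(n_demes), phase_rate(n_mig);

  while (n_active > 1) {
    // rates for the current interval
    double total = 0.0;
    for (int d = 0; d < n_demes; ++d) {
      double r = deme_n[d] > 1
        ? (double)deme_n[d] * (deme_n[d] - 1) / deme_size[d] : 0.0;
      coal_rate[d] = r;
      total += r;
    }
    for (int m = 0; m < n_mig; ++m) {
      double r = 0.0;
      if (mig_start[m] <= t && t < mig_end[m] && deme_n[mig_from[m]] > 0)
        r = mig_rate[m] * deme_n[mig_from[m]];
      phase_rate[m] = r;
      total += r;
    }

    double t_next = next_bnd < bnd.size() ? bnd[next_bnd].time : R_PosInf;
    double wait = total > 0.0 ? exp_rand() / total : R_PosInf;

    if (t + wait >= t_next) {
      if (!R_FINITE(t_next))
        stop("coalescence unreachable: lineages remain in demes that never merge");
      t = t_next;
      // apply every boundary scheduled at this instant (splits first)
      while (next_bnd < bnd.size() && bnd[next_bnd].time == t_next) {
        if (bnd[next_bnd].kind == 0) {
          int s = bnd[next_bnd].index;
          int from = split_derived[s], to = split_ancestral[s];
          for (int i = 0; i < n_active; ++i)
            if (lin_deme[i] == from) lin_deme[i] = to;
          deme_n[to] += deme_n[from];
          deme_n[from] = 0;
        }
        ++next_bnd; // toggles change nothing beyond the rate recompute
      }
      continue;
    }

    t += wait;
    double u = unif_rand() * total;
    int done = 0;
    for (int d = 0; d < n_demes && !done; ++d) {
      if (u < coal_rate[d]) {
        // choose an unordered pair of lineages in deme d uniformly
        int k = deme_n[d];
        int a = (int)(unif_rand() * k); if (a == k) a = k - 1;
        int b = (int)(unif_rand() * (k - 1)); if (b == k - 1) b = k - 2;
        if (b >= a) ++b;
        int ia = -1, ib = -1, seen = 0;
        for (int i = 0; i < n_active; ++i) {
          if (lin_deme[i] == d) {
            if (seen == a) ia = i;
            if (seen == b) ib = i;
            ++seen;
          }
        }
        int node = next_node++;
        node_time[node] = t;
        parent[lin_node[ia]] = node;
        parent[lin_node[ib]] = node;
        lin_node[ia] = node;
        // drop lineage ib
        lin_node[ib] = lin_node[n_active - 1];
        lin_deme[ib] = lin_deme[n_active - 1];
        --n_active;
        deme_n[d]--;
        done = 1;
        break;
      }
      u -= coal_rate[d];
    }
    if (!done) {
      for (int m = 0; m < n_mig; ++m) {
        if (u < phase_rate[m]) {
          int d = mig_from[m];
          int k = deme_n[d];
          int a = (int)(unif_rand() * k); if (a == k) a = k - 1;
          int seen = 0;
          for (int i = 0; i < n_active; ++i) {
            if (lin_deme[i] == d) {
              if (seen == a) { lin_deme[i] = mig_to[m]; break; }
              ++seen;
            }
          }
          deme_n[d]--;
          deme_n[mig_to[m]]++;
          done = 1;
          break;
        }
        u -= phase_rate[m];
      }
    }
    if (!done) stop("internal error: event selection fell through");
  }

  return List::create(_["parent"] = parent,
                      _["node_time"] = node_time,
                      _["tip_deme"] = tip_deme,
                      _["n_tips"] = n_tips);
}

// Minimum number of deep coalescences (extra lineages) of a rooted gene
// tree fitted to a rooted species tree, multiple alleles per species
// allowed, species absent from the gene tree allowed, polytomies allowed
// in either tree.
//
// For each species-tree edge -- identified with the species cluster C below
// it -- k(C) is the number of maximal gene-tree clades whose tips map
// entirely into C; the edge contributes max(0, k(C) - 1).
//
// `parent`: per-node parent index, -1 at the root; tips are nodes
// 0..n_tips-1.  `tip_species`: species index per tip.  `clusters`: one row
// per species-tree edge, TRUE for species in the cluster.

// [[Rcpp::export(name = ".dc_count_cpp")]]
int dc_count_cpp(IntegerVector parent,
                 int n_tips,
                 IntegerVector tip_species,
                 LogicalMatrix clusters) {
  const int n_nodes = parent.size();
  const int n_clusters = clusters.nrow();
  const int n_species = clusters.ncol();

  // per-node species presence, propagated tip -> root
  std::vector<uint64_t> mask(n_nodes, 0);
  if (n_species > 64) stop("more than 64 species is not supported");
  for (int i = 0; i < n_tips; ++i) {
    uint64_t bit = (uint64_t)1 << tip_species[i];
    int v = i;
    while (v != -1 && !(mask[v] & bit)) {
      mask[v] |= bit;
      v = parent[v];
    }
  }

  int total = 0;
  for (int c = 0; c < n_clusters; ++c) {
    uint64_t cmask = 0;
    for (int s = 0; s < n_species; ++s)
      if (clusters(c, s)) cmask |= (uint64_t)1 << s;
    int k = 0;
    for (int v = 0; v < n_nodes; ++v) {
      if (mask[v] == 0 || (mask[v] & ~cmask)) continue;   // not inside C
      int p = parent[v];
      if (p == -1 || (mask[p] & ~cmask)) ++k;             // maximal inside C
    }
    if (k > 1) total += k - 1;
  }
  return total;
}
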