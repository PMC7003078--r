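#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// Founder haplotypes under a star-shaped pure-drift divergence model.
//
// The 1-Morgan map is cut into n_windows equal windows; each window carries an
// independent structured Kingman coalescent (complete linkage within a window,
// free recombination between windows).  Time is measured in within-deme
// pair-coalescence units (rate 1 for a random pair); all demes and the
// ancestral population share the same size, so a pair coalesces at rate 1
// both before and after the merge at split_time.  Mutations fall on branches
// at rate theta_window / 2 per lineage per unit time (infinite sites), which
// gives an expected within-deme per-site diversity of theta.
//
// Uses R's RNG throughout so set.seed() makes panels reproducible.

// [[Rcpp::export]]
List cpp_founder_sim(IntegerVector deme_sizes, double split_time,
                     double theta_window, int n_windows) {
  int S = deme_sizes.size();
  int n = 0;
  for (int d = 0; d < S; ++d) n += deme_sizes[d];
  int n_nodes = 2 * n - 1;

  std::vector<double> ntime(n_nodes);
  std::vector<int> lchild(n_nodes), rchild(n_nodes), parent(n_nodes);

  // accumulated across windows
  std::vector<double> mut_pos;           // absolute map position in [0,1)
  std::vector<size_t> mut_off;           // offsets into mut_tips
  std::vector<int> mut_tips;             // concatenated derived tip indices
  mut_off.push_back(0);

  std::vector<int> act, pool, stack, cum_edges;
  std::vector<double> cumlen;

  for (int w = 0; w < n_windows; ++w) {
    std::fill(parent.begin(), parent.end(), -1);
    std::fill(lchild.begin(), lchild.end(), -1);
    std::fill(rchild.begin(), rchild.end(), -1);
    std::fill(ntime.begin(), ntime.begin() + n, 0.0);

    int next_node = n;
    pool.clear();
    int tip0 = 0;
    // phase 1: independent within-deme coalescence until split_time
    for (int d = 0; d < S; ++d) {
      act.clear();
      for (int i = 0; i < deme_sizes[d]; ++i) act.push_back(tip0 + i);
      tip0 += deme_sizes[d];
      double t = 0.0;
      while ((int)act.size() > 1) {
        double k = (double)act.size();
        double dt = exp_rand() / (k * (k - 1.0) / 2.0);
        if (t + dt >= split_time) break;
        t += dt;
        int i = (int)(unif_rand() * act.size());
        int ci = act[i]; act[i] = act.back(); act.pop_back();
        int j = (int)(unif_rand() * act.size());
        int cj = act[j];
        int v = next_node++;
        ntime[v] = t; lchild[v] = ci; rchild[v] = cj;
        parent[ci] = v; parent[cj] = v;
        act[j] = v;
      }
      for (size_t i = 0; i < act.size(); ++i) pool.push_back(act[i]);
    }
    // phase 2: merged ancestral population
    double t = split_time;
    while ((int)pool.size() > 1) {
      double k = (double)pool.size();
      t += exp_rand() / (k * (k - 1.0) / 2.0);
      int i = (int)(unif_rand() * pool.size());
      int ci = pool[i]; pool[i] = pool.back(); pool.pop_back();
      int j = (int)(unif_rand() * pool.size());
      int cj = pool[j];
      int v = next_node++;
      ntime[v] = t; lchild[v] = ci; rchild[v] = cj;
      parent[ci] = v; parent[cj] = v;
      pool[j] = v;
    }

    // branch lengths (every node but the root has a parent)
    cumlen.clear(); cum_edges.clear();
    double tot = 0.0;
    for (int v = 0; v < next_node; ++v) {
      if (parent[v] >= 0) {
        tot += ntime[parent[v]] - ntime[v];
        cumlen.push_back(tot);
        cum_edges.push_back(v);
      }
    }
    int nmut = (int)R::rpois(theta_window / 2.0 * tot);
    for (int m = 0; m < nmut; ++m) {
      double r = unif_rand() * tot;
      int e = (int)(std::lower_bound(cumlen.begin(), cumlen.end(), r) -
                    cumlen.begin());
      if (e >= (int)cum_edges.size()) e = (int)cum_edges.size() - 1;
      int v = cum_edges[e];
      mut_pos.push_back((w + unif_rand()) / (double)n_windows);
      // collect tips below v
      stack.clear(); stack.push_back(v);
      while (!stack.empty()) {
        int u = stack.back(); stack.pop_back();
        if (u < n) mut_tips.push_back(u);
        else { stack.push_back(lchild[u]); stack.push_back(rchild[u]); }
      }
      mut_off.push_back(mut_tips.size());
    }
  }

  int M = (int)mut_pos.size();
  NumericVector positions(M);
  IntegerVector ord(M);
  {
    std::vector<int> idx(M);
    for (int i = 0; i < M; ++i) idx[i] = i;
    std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
      return mut_pos[a] < mut_pos[b];
    });
    for (int r = 0; r < M; ++r) { ord[r] = idx[r]; positions[r] = mut_pos[idx[r]]; }
  }
  RawMatrix geno(M, n);
  std::memset(RAW(geno), 0, (size_t)M * n);
  for (int r = 0; r < M; ++r) {
    int i = ord[r];
    for (size_t k = mut_off[i]; k < mut_off[i + 1]; ++k)
      RAW(geno)[(size_t)mut_tips[k] * M + r] = 1;
  }
  return List::create(_["positions"] = positions, _["geno"] = geno);
}

// Assemble gamete allele columns: column j of the output takes rows
// [0, cut_j) from X[, acol_j] and rows [cut_j, M) from X[, bcol_j].
// A clonal copy is the special case cut_j = M (bcol then unused).
// acol/bcol are 1-based.

// [[Rcpp::export]]
RawMatrix cpp_splice_columns(RawMatrix X, IntegerVector acol,
                             IntegerVector bcol, IntegerVector cut) {
  size_t M = X.nrow();
  int n = acol.size();
  RawMatrix out(M, n);
  for (int j = 0; j < n; ++j) {
    size_t c = (size_t)cut[j];
    if (c > 0)
      std::memcpy(&RAW(out)[(size_t)j * M],
                  &RAW(X)[(size_t)(acol[j] - 1) * M], c);
    if (c < M)
      std::memcpy(&RAW(out)[(size_t)j * M + c],
                  &RAW(X)[(size_t)(bcol[j] - 1) * M + c], M - c);
  }
  return out;
}

// Per-row count of non-zero entries over a subset of columns (1-based).

// [[Rcpp::export]]
IntegerVector cpp_row_alt_counts(RawMatrix X, IntegerVector cols) {
  size_t M = X.nrow();
  IntegerVector out(M);
  for (int j = 0; j < cols.size(); ++j) {
    const Rbyte* p = &RAW(X)[(size_t)(cols[j] - 1) * M];
    for (size_t r = 0; r < M; ++r) out[r] += (p[r] != 0);
  }
  return out;
}

// Per-row count of individuals whose two chromosome columns differ
// (heterozygote counts). cols1/cols2 are 1-based, same length.

// [[Rcpp::export]]
IntegerVector cpp_row_het_counts(RawMatrix X, IntegerVector cols1,
                                 IntegerVector cols2) {
  size_t M = X.nrow();
  IntegerVector out(M);
  for (int j = 0; j < cols1.size(); ++j) {
    const Rbyte* a = &RAW(X)[(size_t)(cols1[j] - 1) * M];
    const Rbyte* b = &RAW(X)[(size_t)(cols2[j] - 1) * M];
    for (size_t r = 0; r < M; ++r) out[r] += (a[r] != b[r]);
  }
  return out;
}
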