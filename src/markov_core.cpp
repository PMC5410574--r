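#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Sequences arrive 1-based (R alphabet indices); everything here is 0-based.

static inline int rand_below(int n) {
  // uniform integer in [0, n) from R's RNG stream
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

static void count_pairs(const std::vector<int>& s, int m, std::vector<double>& O) {
  std::fill(O.begin(), O.end(), 0.0);
  for (size_t t = 0; t + 1 < s.size(); ++t) O[s[t] * m + s[t + 1]] += 1.0;
}

// chi2-style divergence of pair counts from the order-0 (independence)
// expectation E[i,j] = n * p_i * p_j with marginals over the whole sequence
// and n = number of adjacent pairs.
static double indep_stat(const std::vector<int>& s, int m, std::vector<double>& O) {
  const int L = (int)s.size();
  std::vector<double> p(m, 0.0);
  for (int t = 0; t < L; ++t) p[s[t]] += 1.0;
  for (int i = 0; i < m; ++i) p[i] /= L;
  count_pairs(s, m, O);
  const double n = L - 1.0;
  double stat = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j) {
      double E = n * p[i] * p[j];
      if (E > 0) {
        double d = O[i * m + j] - E;
        stat += d * d / E;
      }
    }
  return stat;
}

// [[Rcpp::export(name = ".pairCountsC")]]
IntegerMatrix pair_counts_c(IntegerVector seq, int m) {
  IntegerMatrix N(m, m);
  for (int t = 0; t + 1 < seq.size(); ++t) N(seq[t] - 1, seq[t + 1] - 1)++;
  return N;
}

// [[Rcpp::export(name = ".indepChi2C")]]
double indep_chi2_c(IntegerVector seq, int m) {
  std::vector<int> s(seq.size());
  for (int t = 0; t < seq.size(); ++t) s[t] = seq[t] - 1;
  std::vector<double> O(m * m);
  return indep_stat(s, m, O);
}

// Null distribution of the independence divergence under uniform random
// permutation surrogates (symbol histogram preserved exactly).
// [[Rcpp::export(name = ".permNullC")]]
NumericVector perm_null_c(IntegerVector seq, int m, int nsur) {
  const int L = seq.size();
  std::vector<int> s(L);
  for (int t = 0; t < L; ++t) s[t] = seq[t] - 1;
  std::vector<double> O(m * m);
  NumericVector out(nsur);
  for (int r = 0; r < nsur; ++r) {
    for (int i = L - 1; i > 0; --i) {
      int j = rand_below(i + 1);
      std::swap(s[i], s[j]);
    }
    out[r] = indep_stat(s, m, O);
  }
  return out;
}

// ---- Whittle surrogate: uniform Eulerian trail with the input's pair counts.
// Wilson loop-erased random walk samples the "last exit" arborescence toward
// the final symbol with probability proportional to the product of edge
// counts; remaining out-edge instances are shuffled uniformly per vertex.
// Uniform over instance-level trails implies uniform over token sequences
// because every sequence with these pair counts corresponds to exactly
// prod_{i,j} N(i,j)! instance orderings.
static void whittle_draw(const std::vector<int>& s, int m, std::vector<int>& out) {
  const int L = (int)s.size();
  out.resize(L);
  if (L < 3) { out = s; return; }
  std::vector<int> N(m * m, 0), rowsum(m, 0);
  for (int t = 0; t + 1 < L; ++t) {
    N[s[t] * m + s[t + 1]]++;
    rowsum[s[t]]++;
  }
  const int root = s[L - 1], first = s[0];

  // Wilson's algorithm on the count-weighted digraph
  std::vector<int> nxt(m, -1);
  std::vector<char> intree(m, 0);
  intree[root] = 1;
  for (int v = 0; v < m; ++v) {
    if (rowsum[v] == 0 || intree[v]) continue;
    int u = v;
    while (!intree[u]) {
      double r = unif_rand() * rowsum[u];
      double acc = 0.0;
      int w = -1;
      for (int j = 0; j < m; ++j) {
        acc += N[u * m + j];
        if (r < acc) { w = j; break; }
      }
      if (w < 0) w = m - 1;  // numerical guard
      nxt[u] = w;
      u = w;
    }
    u = v;
    while (!intree[u]) { intree[u] = 1; u = nxt[u]; }
  }

  // Per-vertex out-edge lists: shuffle non-arborescence instances, put the
  // arborescence edge last (root shuffles everything).
  std::vector<std::vector<int> > edges(m);
  for (int v = 0; v < m; ++v) {
    if (rowsum[v] == 0) continue;
    std::vector<int>& e = edges[v];
    e.reserve(rowsum[v]);
    for (int j = 0; j < m; ++j)
      for (int c = 0; c < N[v * m + j]; ++c) e.push_back(j);
    int keep = (int)e.size();
    if (v != root) {
      // remove one instance of the arborescence edge, re-append after shuffle
      for (size_t i = 0; i < e.size(); ++i)
        if (e[i] == nxt[v]) { std::swap(e[i], e.back()); e.pop_back(); break; }
      keep = (int)e.size();
    }
    for (int i = keep - 1; i > 0; --i) {
      int j = rand_below(i + 1);
      std::swap(e[i], e[j]);
    }
    if (v != root) e.push_back(nxt[v]);
  }

  std::vector<int> pos(m, 0);
  int cur = first;
  out[0] = first;
  for (int t = 1; t < L; ++t) {
    int w = edges[cur][pos[cur]++];
    out[t] = w;
    cur = w;
  }
}

// [[Rcpp::export(name = ".whittleC")]]
IntegerVector whittle_c(IntegerVector seq, int m) {
  std::vector<int> s(seq.size()), out;
  for (int t = 0; t < seq.size(); ++t) s[t] = seq[t] - 1;
  whittle_draw(s, m, out);
  IntegerVector res(out.size());
  for (size_t t = 0; t < out.size(); ++t) res[t] = out[t] + 1;
  return res;
}

// chi2-style divergence of triplet counts from their order-1 expectation
// E[i,j,k] = N3row(i,j) * P(k | j), P(k | j) from the full pair counts.
static double triplet_stat(const std::vector<int>& s, int m,
                           std::vector<double>& N3, std::vector<double>& N2,
                           std::vector<double>& N3row, std::vector<double>& rs) {
  const int L = (int)s.size();
  std::fill(N3.begin(), N3.end(), 0.0);
  std::fill(N2.begin(), N2.end(), 0.0);
  std::fill(N3row.begin(), N3row.end(), 0.0);
  std::fill(rs.begin(), rs.end(), 0.0);
  for (int t = 0; t + 1 < L; ++t) {
    N2[s[t] * m + s[t + 1]] += 1.0;
    rs[s[t]] += 1.0;
  }
  for (int t = 0; t + 2 < L; ++t) {
    N3[(s[t] * m + s[t + 1]) * m + s[t + 2]] += 1.0;
    N3row[s[t] * m + s[t + 1]] += 1.0;
  }
  double stat = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j) {
      double nij = N3row[i * m + j];
      if (nij == 0.0) continue;
      for (int k = 0; k < m; ++k) {
        double njk = N2[j * m + k];
        if (njk == 0.0) continue;
        double E = nij * njk / rs[j];
        double d = N3[(i * m + j) * m + k] - E;
        stat += d * d / E;
      }
    }
  return stat;
}

// [[Rcpp::export(name = ".tripletStatC")]]
double triplet_stat_c(IntegerVector seq, int m) {
  std::vector<int> s(seq.size());
  for (int t = 0; t < seq.size(); ++t) s[t] = seq[t] - 1;
  std::vector<double> N3((size_t)m * m * m), N2(m * m), N3row(m * m), rs(m);
  return triplet_stat(s, m, N3, N2, N3row, rs);
}

// Null distribution of the triplet divergence over Whittle surrogates.
// [[Rcpp::export(name = ".order2NullC")]]
NumericVector order2_null_c(IntegerVector seq, int m, int nsur) {
  std::vector<int> s(seq.size()), sur;
  for (int t = 0; t < seq.size(); ++t) s[t] = seq[t] - 1;
  std::vector<double> N3((size_t)m * m * m), N2(m * m), N3row(m * m), rs(m);
  NumericVector out(nsur);
  for (int r = 0; r < nsur; ++r) {
    whittle_draw(s, m, sur);
    out[r] = triplet_stat(sur, m, N3, N2, N3row, rs);
  }
  return out;
}

// First-order chain sampler; P given as row-cumulative probabilities.
// [[Rcpp::export(name = ".sampleChainC")]]
IntegerVector sample_chain_c(NumericMatrix cumP, int n, int start) {
  const int m = cumP.nrow();
  IntegerVector out(n);
  int cur = start - 1;
  out[0] = cur + 1;
  for (int t = 1; t < n; ++t) {
    double r = unif_rand();
    int j = 0;
    while (j < m - 1 && r >= cumP(cur, j)) ++j;
    cur = j;
    out[t] = cur + 1;
  }
  return out;
}
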