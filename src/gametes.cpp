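#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Draw a uniformly random k-subset of {0, ..., m-1} into `out` (Floyd's
// algorithm; k is expected to be small relative to m).
static void floyd_sample(int m, int k, std::vector<int>& out) {
  out.clear();
  for (int t = m - k; t < m; ++t) {
    int j = (int)(unif_rand() * (t + 1));
    if (j > t) j = t;
    if (std::find(out.begin(), out.end(), j) != out.end()) out.push_back(t);
    else out.push_back(j);
  }
}

// Crossover mosaic gametes for a batch of meioses.
//
// hap1/hap2: loci x parents allele matrices (values 1/2).
// parent:    1-based parent column per requested gamete.
// switch_prob: per-locus source-switch probability: 0.5 at the first locus of
//   every chromosome (fair-coin start), the Haldane recombination fraction of
//   the preceding interval elsewhere.
// chrom_start: 0-based index of each chromosome's first locus.
// r_max: per-chromosome upper bound of the interval switch probabilities.
//
// Interval switches are sampled exactly (independent Bernoulli per interval)
// by binomial thinning: a Binomial(m, r_max) count of candidate intervals is
// drawn with uniformly random positions, and each candidate is accepted with
// probability R_i / r_max. Uses R's RNG so results are governed by set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_meiosis_batch(const IntegerMatrix& hap1,
                                const IntegerMatrix& hap2,
                                const IntegerVector& parent,
                                const NumericVector& switch_prob,
                                const IntegerVector& chrom_start,
                                const NumericVector& r_max) {
  const int n_loci = hap1.nrow();
  const int n_gam = parent.size();
  const int n_chrom = chrom_start.size();
  if (hap2.nrow() != n_loci || switch_prob.size() != n_loci ||
      r_max.size() != n_chrom)
    stop("haplotype/map dimension mismatch");
  IntegerMatrix out(n_loci, n_gam);
  RNGScope scope;
  std::vector<int> cand, acc;
  cand.reserve(64);
  acc.reserve(64);
  for (int g = 0; g < n_gam; ++g) {
    const int p = parent[g] - 1;
    if (p < 0 || p >= hap1.ncol()) stop("parent index out of range");
    const int* h[2] = { hap1.begin() + (R_xlen_t)p * n_loci,
                        hap2.begin() + (R_xlen_t)p * n_loci };
    int* o = out.begin() + (R_xlen_t)g * n_loci;
    for (int c = 0; c < n_chrom; ++c) {
      const int s = chrom_start[c];
      const int e = (c + 1 < n_chrom) ? chrom_start[c + 1] : n_loci;
      const int m = e - s - 1;  // adjacent intervals in this chromosome
      int cur = (unif_rand() < 0.5) ? 1 : 0;
      acc.clear();
      const double rm = r_max[c];
      if (m > 0 && rm > 0.0) {
        int k = (int)R::rbinom((double)m, rm);
        floyd_sample(m, k, cand);
        for (int j : cand) {
          const int locus = s + 1 + j;  // switch acts before this locus
          const double ri = switch_prob[locus];
          if (ri >= rm || unif_rand() < ri / rm) acc.push_back(locus);
        }
        std::sort(acc.begin(), acc.end());
      }
      int pos = s;
      for (int sw : acc) {
        for (; pos < sw; ++pos) o[pos] = h[cur][pos];
        cur ^= 1;
      }
      for (; pos < e; ++pos) o[pos] = h[cur][pos];
    }
  }
  return out;
}

// Bidirectional per-locus mutation: each allele flips 1 <-> 2 independently
// with probability `rate` (sampled as a binomial flip count with uniform
// distinct positions, which is the same law).
// [[Rcpp::export]]
IntegerMatrix cpp_mutate_batch(const IntegerMatrix& gam, double rate) {
  if (rate < 0.0 || rate > 1.0) stop("mutation rate outside [0, 1]");
  IntegerMatrix out = clone(gam);
  const int n = out.nrow();
  const int ncol = out.ncol();
  if (rate == 0.0 || n == 0) return out;
  RNGScope scope;
  std::vector<int> flips;
  flips.reserve(64);
  for (int g = 0; g < ncol; ++g) {
    int* o = out.begin() + (R_xlen_t)g * n;
    if (rate == 1.0) {
      for (int l = 0; l < n; ++l) o[l] = 3 - o[l];
      continue;
    }
    int k = (int)R::rbinom((double)n, rate);
    floyd_sample(n, k, flips);
    for (int l : flips) o[l] = 3 - o[l];
  }
  return out;
}

// Tabular relationship recursion with a configurable paternal path
// coefficient pp (0.367 for the honey-bee dummy-sire pedigree, 0.5 recovers
// the classical Wright/Henderson numerator relationship matrix):
//   a(x, y) = 0.5 a(dam_x, y) + pp a(sire_x, y)   for y preceding x
//   a(x, x) = 1 + 2 * 0.5 * pp * a(dam_x, sire_x)
// dam/sire are 1-based indices into earlier rows, 0 for unknown; missing
// parent terms drop.
// [[Rcpp::export]]
NumericMatrix cpp_tabular_A(const IntegerVector& dam,
                            const IntegerVector& sire,
                            double pp) {
  const int n = dam.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    const int d = dam[i] - 1;
    const int s = sire[i] - 1;
    if (d >= i || s >= i) stop("pedigree not sorted parents-before-offspring");
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (d >= 0) v += 0.5 * A(j, d);
      if (s >= 0) v += pp * A(j, s);
      A(j, i) = v;
      A(i, j) = v;
    }
    double dg = 1.0;
    if (d >= 0 && s >= 0) dg += pp * A(d, s); // 2 * 0.5 * pp * a(d, s)
    A(i, i) = dg;
  }
  return A;
}
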