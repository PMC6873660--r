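#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Meiosis kernel for one chromosome.
//
// hap:     loci x 2N integer matrix of 0/1 alleles; columns 2i-1, 2i (1-based)
//          are the two haplotypes of individual i.
// parents: 1-based individual indices, one gamete produced per entry.
// pos:     genetic map positions in cM, non-decreasing.
// Crossover count per meiosis ~ Poisson(lambda), positions uniform on
// [0, chrom_len] (no interference). Mutations per gamete ~ Binomial(L, mu),
// each flipping the sampled allele at a uniformly drawn locus.
// Uses R's RNG throughout so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_gametes(const IntegerMatrix& hap, const IntegerVector& parents,
                          const NumericVector& pos, double chrom_len,
                          double lambda, double mu) {
  const int L = hap.nrow();
  const int m = parents.size();
  IntegerMatrix out(L, m);
  const int* hp = hap.begin();
  const double* pp = pos.begin();
  std::vector<double> xo;
  for (int j = 0; j < m; ++j) {
    const int p = parents[j] - 1;
    if (p < 0 || 2 * p + 1 >= hap.ncol())
      stop("parent index out of range");
    const int* h[2] = { hp + (std::size_t)(2 * p) * L,
                        hp + (std::size_t)(2 * p + 1) * L };
    int* o = out.begin() + (std::size_t)j * L;
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    int k = (lambda > 0.0) ? (int) R::rpois(lambda) : 0;
    xo.clear();
    for (int t = 0; t < k; ++t) xo.push_back(unif_rand() * chrom_len);
    std::sort(xo.begin(), xo.end());
    // copy contiguous segments between crossover breakpoints
    int start = 0;
    for (std::size_t xi = 0; xi < xo.size(); ++xi) {
      int end = (int)(std::upper_bound(pp + start, pp + L, xo[xi]) - pp);
      if (end > start)
        std::copy(h[cur] + start, h[cur] + end, o + start);
      start = end;
      cur ^= 1;
    }
    if (start < L) std::copy(h[cur] + start, h[cur] + L, o + start);
    if (mu > 0.0) {
      int nm = (int) R::rbinom((double) L, mu);
      for (int t = 0; t < nm; ++t) {
        int idx = (int) (unif_rand() * L);
        if (idx >= L) idx = L - 1;
        o[idx] = 1 - o[idx];
      }
    }
  }
  return out;
}

// Allelic dosage (0/1/2) for selected individuals at selected loci.
// Returns individuals x loci. ind and loci are 1-based.
// [[Rcpp::export]]
IntegerMatrix cpp_dosage(const IntegerMatrix& hap, const IntegerVector& ind,
                         const IntegerVector& loci) {
  const int n = ind.size(), L = loci.size();
  IntegerMatrix out(n, L);
  for (int j = 0; j < L; ++j) {
    const int l = loci[j] - 1;
    if (l < 0 || l >= hap.nrow()) stop("locus index out of range");
    for (int i = 0; i < n; ++i) {
      const int p = ind[i] - 1;
      out(i, j) = hap(l, 2 * p) + hap(l, 2 * p + 1);
    }
  }
  return out;
}
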