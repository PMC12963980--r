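#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weighted sum over unordered neighbour pairs, per gene:
//   num[g] = sum_e w[e] * xc(g, ei[e]) * xc(g, ej[e])
// xc is centered expression, genes x spots; ei/ej are 0-based spot indices.
// [[Rcpp::export]]
NumericVector moran_edge_num(const NumericMatrix& xc,
                             const IntegerVector& ei,
                             const IntegerVector& ej,
                             const NumericVector& w) {
  const int P = xc.nrow();
  const int E = ei.size();
  NumericVector num(P);
  double* out = REAL(num);
  const double* x = REAL(xc);
  for (int e = 0; e < E; ++e) {
    const double we = w[e];
    const double* xi = x + (size_t)ei[e] * P;
    const double* xj = x + (size_t)ej[e] * P;
    for (int g = 0; g < P; ++g) out[g] += we * xi[g] * xj[g];
  }
  return num;
}

// Permutation exceedance counts for Moran's I, all genes at once.
// perms: B x N matrix of 0-based spot permutations (one row per permutation
// of spot labels, shared across genes within a row). The permuted numerator
// uses the same edge loop as moran_edge_num, so comparisons against the
// observed numerator are consistent; denominators are permutation-invariant
// and drop out. Genes are processed in blocks to keep the working set in
// cache.
// [[Rcpp::export]]
IntegerVector moran_perm_exceed(const NumericMatrix& xc,
                                const IntegerVector& ei,
                                const IntegerVector& ej,
                                const NumericVector& w,
                                const IntegerMatrix& perms,
                                const NumericVector& num_obs) {
  const int P = xc.nrow();
  const int E = ei.size();
  const int B = perms.nrow();
  const int N = perms.ncol();
  IntegerVector count(P);
  std::vector<double> num(P);
  std::vector<int> pi(N);
  const double* x = REAL(xc);
  const int BLOCK = 768;
  for (int b = 0; b < B; ++b) {
    for (int s = 0; s < N; ++s) pi[s] = perms(b, s);
    std::fill(num.begin(), num.end(), 0.0);
    for (int g0 = 0; g0 < P; g0 += BLOCK) {
      const int g1 = std::min(P, g0 + BLOCK);
      for (int e = 0; e < E; ++e) {
        const double we = w[e];
        const double* xi = x + (size_t)pi[ei[e]] * P;
        const double* xj = x + (size_t)pi[ej[e]] * P;
        for (int g = g0; g < g1; ++g) num[g] += we * xi[g] * xj[g];
      }
    }
    for (int g = 0; g < P; ++g)
      if (num[g] >= num_obs[g]) ++count[g];
    if ((b & 31) == 0) Rcpp::checkUserInterrupt();
  }
  return count;
}
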