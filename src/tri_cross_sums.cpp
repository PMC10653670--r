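#include <Rcpp.h>
using namespace Rcpp;

// Permutation kernel for Mantel-type tests.
//
// For a symmetric zero-diagonal matrix A and fixed vectors V (columns over
// the strict upper triangle of A, in R's column-major upper.tri order),
// computes for each permutation p (row of `perms`, 1-based sample indices)
// the cross sums S[r, q] = sum_{i<j} A[p_i, p_j] * V[l(i,j), q].
//
// The permutation-invariant moments of A (sum, sum of squares) are computed
// once in R, so these cross sums are all a permuted correlation needs.
// [[Rcpp::export(rng = false)]]
NumericMatrix tri_cross_sums(const NumericMatrix& A, const NumericMatrix& V,
                             const IntegerMatrix& perms) {
  const int n = A.nrow();
  const int L = n * (n - 1) / 2;
  const int q = V.ncol();
  const int R = perms.nrow();
  if (V.nrow() != L) stop("V must have n*(n-1)/2 rows");
  if (perms.ncol() != n) stop("each permutation must have length n");
  NumericMatrix S(R, q);
  const double* a = A.begin();
  std::vector<int> p(n);
  for (int r = 0; r < R; ++r) {
    for (int k = 0; k < n; ++k) {
      int v = perms(r, k) - 1;
      if (v < 0 || v >= n) stop("permutation index out of range");
      p[k] = v;
    }
    std::vector<double> acc(q, 0.0);
    int l = 0;
    for (int j = 1; j < n; ++j) {
      const double* col = a + (size_t)p[j] * n;
      for (int i = 0; i < j; ++i, ++l) {
        const double t = col[p[i]];
        for (int m = 0; m < q; ++m) acc[m] += t * V(l, m);
      }
    }
    for (int m = 0; m < q; ++m) S(r, m) = acc[m];
  }
  return S;
}
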