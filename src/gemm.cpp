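// Preallocated-buffer matrix product: C <- A %*% t(B) without allocating a
// fresh result each optimizer step (the FC1 weight gradient is by far the
// largest per-step allocation otherwise).
#include <Rcpp.h>
#include <R_ext/BLAS.h>
using namespace Rcpp;

// [[Rcpp::export]]
void tcrossprod_into(NumericMatrix C, NumericMatrix A, NumericMatrix B) {
  int m = A.nrow(), k = A.ncol(), n = B.nrow();
  if (B.ncol() != k || C.nrow() != m || C.ncol() != n)
    stop("tcrossprod_into: dimension mismatch");
  double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "T", &m, &n, &k, &one, REAL(A), &m, REAL(B), &n,
                  &zero, REAL(C), &m FCONE FCONE);
}
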