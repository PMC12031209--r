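// Memory-bound kernels for the training loop. The matrix products stay in
// R/BLAS; these routines cover the parts where R-level vectorization would
// allocate large temporaries every optimizer step.
#include <Rcpp.h>
using namespace Rcpp;

// In-place Adam update. p, g, m, v must be exclusively owned by the caller.
// c1, c2 are the bias-correction factors 1 - beta^t.
// [[Rcpp::export]]
void adam_step(NumericVector p, NumericVector g, NumericVector m,
               NumericVector v, double lr, double b1, double b2,
               double eps, double c1, double c2) {
  R_xlen_t n = p.size();
  double *pp = REAL(p), *pg = REAL(g), *pm = REAL(m), *pv = REAL(v);
  for (R_xlen_t i = 0; i < n; ++i) {
    pm[i] = b1 * pm[i] + (1.0 - b1) * pg[i];
    pv[i] = b2 * pv[i] + (1.0 - b2) * pg[i] * pg[i];
    pp[i] -= lr * (pm[i] / c1) / (std::sqrt(pv[i] / c2) + eps);
  }
}

// im2col for (H, W, C, N)-ordered arrays (already padded). Output matrix has
// rows indexed by (h_out, w_out, n) with h_out fastest, and columns by
// (kh, kw, c) with kh fastest.
// [[Rcpp::export]]
NumericMatrix im2col_hwcn(NumericVector Xp, int Hp, int Wp, int C, int N,
                          int K, int Hout, int Wout) {
  NumericMatrix out(Hout * Wout * N, K * K * C);
  const double *x = REAL(Xp);
  double *o = REAL(out);
  const R_xlen_t R = (R_xlen_t)Hout * Wout * N;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        double *col = o + R * (kh + K * kw + K * K * c);
        for (int n = 0; n < N; ++n) {
          const double *plane = x + (R_xlen_t)Hp * Wp * (c + (R_xlen_t)C * n);
          for (int w = 0; w < Wout; ++w) {
            const double *src = plane + kh + (R_xlen_t)Hp * (w + kw);
            double *dst = col + (R_xlen_t)Hout * (w + Wout * n);
            for (int h = 0; h < Hout; ++h) dst[h] = src[h];
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add transpose of im2col_hwcn.
// [[Rcpp::export]]
NumericVector col2im_hwcn(NumericMatrix dcol, int Hp, int Wp, int C, int N,
                          int K, int Hout, int Wout) {
  NumericVector dXp((R_xlen_t)Hp * Wp * C * N);
  const double *dc = REAL(dcol);
  double *x = REAL(dXp);
  const R_xlen_t R = (R_xlen_t)Hout * Wout * N;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const double *col = dc + R * (kh + K * kw + K * K * c);
        for (int n = 0; n < N; ++n) {
          double *plane = x + (R_xlen_t)Hp * Wp * (c + (R_xlen_t)C * n);
          for (int w = 0; w < Wout; ++w) {
            double *dst = plane + kh + (R_xlen_t)Hp * (w + kw);
            const double *src = col + (R_xlen_t)Hout * (w + Wout * n);
            for (int h = 0; h < Hout; ++h) dst[h] += src[h];
          }
        }
      }
    }
  }
  dXp.attr("dim") = IntegerVector::create(Hp, Wp, C, N);
  return dXp;
}

// Permute a (H, W, N, C) matrix product result into (H, W, C, N) order and
// vice versa; equivalent to aperm(..., c(1, 2, 4, 3)) without the generic
// dispatch and attribute copying overhead.
// [[Rcpp::export]]
NumericVector swap34(NumericVector X, int H, int W, int D3, int D4) {
  NumericVector out((R_xlen_t)H * W * D3 * D4);
  const double *x = REAL(X);
  double *o = REAL(out);
  const R_xlen_t HW = (R_xlen_t)H * W;
  for (int d4 = 0; d4 < D4; ++d4)
    for (int d3 = 0; d3 < D3; ++d3) {
      const double *src = x + HW * (d3 + (R_xlen_t)D3 * d4);
      double *dst = o + HW * (d4 + (R_xlen_t)D4 * d3);
      std::copy(src, src + HW, dst);
    }
  out.attr("dim") = IntegerVector::create(H, W, D4, D3);
  return out;
}

// Fused batch-norm forward: returns Y and xhat for the backward pass.
// mu, inv_std are per-channel.
// [[Rcpp::export]]
List bn_fwd_hwcn(NumericVector X, int H, int W, int C, int N,
                 NumericVector gamma, NumericVector beta,
                 NumericVector mu, NumericVector inv_std) {
  R_xlen_t HW = (R_xlen_t)H * W, total = HW * C * N;
  NumericVector Y(total), xhat(total);
  const double *x = REAL(X);
  double *y = REAL(Y), *xh = REAL(xhat);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      R_xlen_t off = HW * (c + (R_xlen_t)C * n);
      double m = mu[c], is = inv_std[c], g = gamma[c], b = beta[c];
      for (R_xlen_t i = 0; i < HW; ++i) {
        double v = (x[off + i] - m) * is;
        xh[off + i] = v;
        y[off + i] = g * v + b;
      }
    }
  IntegerVector d = IntegerVector::create(H, W, C, N);
  Y.attr("dim") = d;
  xhat.attr("dim") = d;
  return List::create(_["Y"] = Y, _["xhat"] = xhat);
}

// Per-channel mean and (biased) variance over (H, W, N).
// [[Rcpp::export]]
List bn_stats_hwcn(NumericVector X, int H, int W, int C, int N) {
  R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector mu(C), va(C);
  const double *x = REAL(X);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      R_xlen_t off = HW * (c + (R_xlen_t)C * n);
      double s = 0, s2 = 0;
      for (R_xlen_t i = 0; i < HW; ++i) {
        double v = x[off + i];
        s += v; s2 += v * v;
      }
      mu[c] += s; va[c] += s2;
    }
  double m = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    mu[c] /= m;
    va[c] = va[c] / m - mu[c] * mu[c];
  }
  return List::create(_["mu"] = mu, _["va"] = va);
}

// Fused batch-norm backward.
// [[Rcpp::export]]
List bn_bwd_hwcn(NumericVector dOut, NumericVector xhat, int H, int W,
                 int C, int N, NumericVector gamma, NumericVector inv_std) {
  R_xlen_t HW = (R_xlen_t)H * W, total = HW * C * N;
  NumericVector dX(total), dgamma(C), dbeta(C);
  const double *dy = REAL(dOut), *xh = REAL(xhat);
  double *dx = REAL(dX);
  double m = (double)HW * N;
  // pass 1: per-channel sums
  std::vector<double> s_d(C, 0.0), s_dx(C, 0.0);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      R_xlen_t off = HW * (c + (R_xlen_t)C * n);
      double a = 0, b = 0;
      for (R_xlen_t i = 0; i < HW; ++i) {
        a += dy[off + i];
        b += dy[off + i] * xh[off + i];
      }
      s_d[c] += a; s_dx[c] += b;
    }
  for (int c = 0; c < C; ++c) { dbeta[c] = s_d[c]; dgamma[c] = s_dx[c]; }
  // pass 2: dX = inv_std*gamma/m * (m*dy - sum(dy) - xhat*sum(dy*xhat))
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      R_xlen_t off = HW * (c + (R_xlen_t)C * n);
      double k = inv_std[c] * gamma[c] / m;
      double sd = s_d[c], sdx = s_dx[c];
      for (R_xlen_t i = 0; i < HW; ++i)
        dx[off + i] = k * (m * dy[off + i] - sd - xh[off + i] * sdx);
    }
  dX.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
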