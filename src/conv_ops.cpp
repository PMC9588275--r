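#include <Rcpp.h>
#include <cmath>
#include <cstring>
#ifndef USE_FC_LEN_T
#define USE_FC_LEN_T
#endif
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// 2-D convolution (cross-correlation, as in deep-learning frameworks) on a
// single image, via im2col + BLAS dgemm. Layouts, all column-major R
// arrays:
//   x: [H, W, Cin]   w: [kh, kw, Cin, Cout]   y: [Ho, Wo, Cout]
// The patch matrix M is [Ho*Wo, kh*kw*Cin] with patch column index
// c = ki + kh*kj + kh*kw*ci, so y (flattened per channel) = M %*% W2 with
// W2 = [kh*kw*Cin, Cout] — the weight array reinterpreted in place.

static inline void tap_bounds(int k, int pad, int stride, int in_sz,
                              int out_sz, int &lo, int &hi) {
  // output indices o with 0 <= o*stride - pad + k <= in_sz - 1
  lo = (pad - k + stride - 1) / stride;
  if (lo < 0) lo = 0;
  hi = (in_sz - 1 + pad - k) / stride;
  if (hi > out_sz - 1) hi = out_sz - 1;
}

static void im2col(const double *x, int H, int W, int Cin, int kh, int kw,
                   int stride, int pad, int Ho, int Wo, double *M) {
  std::memset(M, 0, sizeof(double) * (size_t)Ho * Wo * kh * kw * Cin);
  for (int ci = 0; ci < Cin; ci++) {
    const double *xc = x + (size_t)ci * H * W;
    for (int kj = 0; kj < kw; kj++) {
      int wo_lo, wo_hi, ho_lo, ho_hi;
      tap_bounds(kj, pad, stride, W, Wo, wo_lo, wo_hi);
      for (int ki = 0; ki < kh; ki++) {
        tap_bounds(ki, pad, stride, H, Ho, ho_lo, ho_hi);
        double *Mc = M + (size_t)(ki + kh * (kj + kw * ci)) * Ho * Wo;
        for (int wo = wo_lo; wo <= wo_hi; wo++) {
          const double *__restrict__ src =
              xc + (size_t)(wo * stride - pad + kj) * H +
              (ho_lo * stride - pad + ki);
          double *__restrict__ dst = Mc + (size_t)wo * Ho + ho_lo;
          int n = ho_hi - ho_lo + 1;
          if (stride == 1) {
            std::memcpy(dst, src, sizeof(double) * n);
          } else {
            for (int t = 0; t < n; t++) dst[t] = src[t * stride];
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col
static void col2im(const double *M, int H, int W, int Cin, int kh, int kw,
                   int stride, int pad, int Ho, int Wo, double *dx) {
  for (int ci = 0; ci < Cin; ci++) {
    double *xc = dx + (size_t)ci * H * W;
    for (int kj = 0; kj < kw; kj++) {
      int wo_lo, wo_hi, ho_lo, ho_hi;
      tap_bounds(kj, pad, stride, W, Wo, wo_lo, wo_hi);
      for (int ki = 0; ki < kh; ki++) {
        tap_bounds(ki, pad, stride, H, Ho, ho_lo, ho_hi);
        const double *Mc = M + (size_t)(ki + kh * (kj + kw * ci)) * Ho * Wo;
        for (int wo = wo_lo; wo <= wo_hi; wo++) {
          double *__restrict__ dst = xc + (size_t)(wo * stride - pad + kj) * H +
                                     (ho_lo * stride - pad + ki);
          const double *__restrict__ src = Mc + (size_t)wo * Ho + ho_lo;
          int n = ho_hi - ho_lo + 1;
          if (stride == 1) {
            for (int t = 0; t < n; t++) dst[t] += src[t];
          } else {
            for (int t = 0; t < n; t++) dst[t * stride] += src[t];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector nn_conv2d(NumericVector x, IntegerVector xdim, NumericVector w,
                        IntegerVector wdim, NumericVector b, int stride,
                        int pad) {
  int H = xdim[0], W = xdim[1], Cin = xdim[2];
  int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho <= 0 || Wo <= 0)
    stop("conv output would be empty: input %dx%d too small for kernel %dx%d",
         H, W, kh, kw);
  int m = Ho * Wo, k = kh * kw * Cin;
  std::vector<double> M((size_t)m * k);
  im2col(x.begin(), H, W, Cin, kh, kw, stride, pad, Ho, Wo, M.data());
  NumericVector y(m * Cout);
  double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &m, &Cout, &k, &one, M.data(), &m, w.begin(), &k,
                  &zero, y.begin(), &m FCONE FCONE);
  for (int co = 0; co < Cout; co++) {
    double bias = b[co];
    if (bias != 0.0) {
      double *yc = y.begin() + (size_t)co * m;
      for (int i = 0; i < m; i++) yc[i] += bias;
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return y;
}

// Gradient of the convolution w.r.t. its input.
// [[Rcpp::export(rng = false)]]
NumericVector nn_conv2d_grad_input(NumericVector dy, IntegerVector ydim,
                                   NumericVector w, IntegerVector wdim,
                                   int stride, int pad, int H, int W) {
  int Ho = ydim[0], Wo = ydim[1], Cout = ydim[2];
  int kh = wdim[0], kw = wdim[1], Cin = wdim[2];
  int m = Ho * Wo, k = kh * kw * Cin;
  std::vector<double> dM((size_t)m * k);
  double one = 1.0, zero = 0.0;
  // dM = dY %*% t(W2)
  F77_CALL(dgemm)("N", "T", &m, &k, &Cout, &one, dy.begin(), &m, w.begin(),
                  &k, &zero, dM.data(), &m FCONE FCONE);
  NumericVector dx(H * W * Cin);
  col2im(dM.data(), H, W, Cin, kh, kw, stride, pad, Ho, Wo, dx.begin());
  dx.attr("dim") = IntegerVector::create(H, W, Cin);
  return dx;
}

// Gradients of the convolution w.r.t. weights and bias.
// [[Rcpp::export(rng = false)]]
List nn_conv2d_grad_weights(NumericVector x, IntegerVector xdim,
                            NumericVector dy, IntegerVector ydim, int kh,
                            int kw, int stride, int pad) {
  int H = xdim[0], W = xdim[1], Cin = xdim[2];
  int Ho = ydim[0], Wo = ydim[1], Cout = ydim[2];
  int m = Ho * Wo, k = kh * kw * Cin;
  std::vector<double> M((size_t)m * k);
  im2col(x.begin(), H, W, Cin, kh, kw, stride, pad, Ho, Wo, M.data());
  NumericVector dw(k * Cout), db(Cout);
  double one = 1.0, zero = 0.0;
  // dW2 = t(M) %*% dY
  F77_CALL(dgemm)("T", "N", &k, &Cout, &m, &one, M.data(), &m, dy.begin(),
                  &m, &zero, dw.begin(), &k FCONE FCONE);
  for (int co = 0; co < Cout; co++) {
    const double *dyc = dy.begin() + (size_t)co * m;
    double acc = 0.0;
    for (int i = 0; i < m; i++) acc += dyc[i];
    db[co] = acc;
  }
  dw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  return List::create(_["dw"] = dw, _["db"] = db);
}
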