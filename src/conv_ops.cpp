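#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// 3x3 convolution, stride 1, zero padding, via im2col + BLAS dgemm.
// Tensors are column-major [H, W, C] arrays flattened to vectors; weights
// are [3, 3, Cin, Cout] so that column r = (dh+1) + 3*(dw+1) + 9*ci of the
// (HW x 9Cin) patch matrix matches row r of the unrolled weight matrix.

// K is (H*W) x (9*Cin); column r holds the x channel shifted by (dh,dw)
static void im2col(const double *x, double *K, int H, int W, int Cin) {
  const R_xlen_t HW = (R_xlen_t)H * W;
  for (int ci = 0; ci < Cin; ++ci) {
    const double *xc = x + HW * ci;
    for (int dw = -1; dw <= 1; ++dw) {
      for (int dh = -1; dh <= 1; ++dh) {
        const int r = (dh + 1) + 3 * (dw + 1) + 9 * ci;
        double *Kc = K + HW * r;
        const int h0 = std::max(0, -dh), h1 = H - 1 - std::max(0, dh);
        const int n = h1 - h0 + 1;
        for (int w = 0; w < W; ++w) {
          double *dst = Kc + (R_xlen_t)H * w;
          const int ws = w + dw;
          if (ws < 0 || ws >= W) { std::memset(dst, 0, H * sizeof(double)); continue; }
          const double *src = xc + (R_xlen_t)H * ws;
          if (h0 > 0) dst[0] = 0.0;
          if (h1 < H - 1) dst[H - 1] = 0.0;
          std::memcpy(dst + h0, src + h0 + dh, n * sizeof(double));
        }
      }
    }
  }
}

// adjoint of im2col: scatter-add dK back into dx
static void col2im_acc(const double *dK, double *dx, int H, int W, int Cin) {
  const R_xlen_t HW = (R_xlen_t)H * W;
  for (int ci = 0; ci < Cin; ++ci) {
    double *dxc = dx + HW * ci;
    for (int dw = -1; dw <= 1; ++dw) {
      for (int dh = -1; dh <= 1; ++dh) {
        const int r = (dh + 1) + 3 * (dw + 1) + 9 * ci;
        const double *Kc = dK + HW * r;
        const int h0 = std::max(0, -dh), h1 = H - 1 - std::max(0, dh);
        for (int w = 0; w < W; ++w) {
          const int ws = w + dw;
          if (ws < 0 || ws >= W) continue;
          const double *src = Kc + (R_xlen_t)H * w;
          double *dst = dxc + (R_xlen_t)H * ws + dh;
          for (int h = h0; h <= h1; ++h) dst[h] += src[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3x3_fwd_cpp(NumericVector x, NumericVector wgt,
                              NumericVector bias, int H, int W,
                              int Cin, int Cout) {
  const int HW = H * W, K9 = 9 * Cin;
  NumericVector y((R_xlen_t)HW * Cout);
  std::vector<double> K((R_xlen_t)HW * K9);
  im2col(x.begin(), K.data(), H, W, Cin);
  const double one = 1.0, zero = 0.0;
  // y (HW x Cout) = K (HW x 9Cin) %*% wgt (9Cin x Cout)
  F77_CALL(dgemm)("N", "N", &HW, &Cout, &K9, &one, K.data(), &HW,
                  wgt.begin(), &K9, &zero, y.begin(), &HW FCONE FCONE);
  for (int co = 0; co < Cout; ++co) {
    double *yc = y.begin() + (R_xlen_t)HW * co;
    const double bv = bias[co];
    for (int i = 0; i < HW; ++i) yc[i] += bv;
  }
  return y;
}

// [[Rcpp::export]]
List conv3x3_bwd_cpp(NumericVector x, NumericVector wgt, NumericVector dy,
                     int H, int W, int Cin, int Cout) {
  const int HW = H * W, K9 = 9 * Cin;
  NumericVector dx((R_xlen_t)HW * Cin);
  NumericVector dwgt((R_xlen_t)K9 * Cout);
  NumericVector db(Cout);
  std::vector<double> K((R_xlen_t)HW * K9);
  im2col(x.begin(), K.data(), H, W, Cin);
  const double one = 1.0, zero = 0.0;
  // dW (9Cin x Cout) = K^T (9Cin x HW) %*% dy (HW x Cout)
  F77_CALL(dgemm)("T", "N", &K9, &Cout, &HW, &one, K.data(), &HW,
                  dy.begin(), &HW, &zero, dwgt.begin(), &K9 FCONE FCONE);
  // dK (HW x 9Cin) = dy (HW x Cout) %*% wgt^T (Cout x 9Cin), reusing K
  F77_CALL(dgemm)("N", "T", &HW, &K9, &Cout, &one, dy.begin(), &HW,
                  wgt.begin(), &K9, &zero, K.data(), &HW FCONE FCONE);
  col2im_acc(K.data(), dx.begin(), H, W, Cin);
  for (int co = 0; co < Cout; ++co) {
    const double *dyc = dy.begin() + (R_xlen_t)HW * co;
    double s = 0.0;
    for (int i = 0; i < HW; ++i) s += dyc[i];
    db[co] = s;
  }
  return List::create(_["dx"] = dx, _["dw"] = dwgt, _["db"] = db);
}
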