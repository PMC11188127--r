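// 2D convolution primitives for the frame-attention U-net.
//
// Tensors arrive flattened from R in (H, W, C, N) column-major order,
// where N indexes the (frame, batch) product: a conv layer is applied
// identically to every frame, so frames behave as extra batch items.
// Weights are (k, k, Cin, Cout); convolution is cross-correlation with
// zero "same" padding p = (k-1)/2 and an integer stride.
//
// im2col + BLAS gemm: the K = Cin*k*k patch rows are ordered
// (ki, kj, c) fastest-first, matching the column-major flattening of the
// weight array, so the weight vector can be wrapped as a K x Cout matrix
// without copying.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline void im2col_one(const double* xn, int H, int W, int C,
                              int k, int p, int stride,
                              int Ho, int Wo, arma::mat& col) {
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = xn + static_cast<size_t>(c) * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        int l = ho + Ho * wo;
        double* cp = col.colptr(l) + c * k * k;
        int hi0 = ho * stride - p;
        int wi0 = wo * stride - p;
        for (int kj = 0; kj < k; ++kj) {
          int wi = wi0 + kj;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xc + static_cast<size_t>(wi) * H;
          for (int ki = 0; ki < k; ++ki) {
            int hi = hi0 + ki;
            if (hi < 0 || hi >= H) continue;
            cp[ki + k * kj] = xcol[hi];
          }
        }
      }
    }
  }
}

static inline void col2im_one(const arma::mat& dcol, int H, int W, int C,
                              int k, int p, int stride,
                              int Ho, int Wo, double* dxn) {
  for (int c = 0; c < C; ++c) {
    double* dxc = dxn + static_cast<size_t>(c) * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        int l = ho + Ho * wo;
        const double* cp = dcol.colptr(l) + c * k * k;
        int hi0 = ho * stride - p;
        int wi0 = wo * stride - p;
        for (int kj = 0; kj < k; ++kj) {
          int wi = wi0 + kj;
          if (wi < 0 || wi >= W) continue;
          double* dxcol = dxc + static_cast<size_t>(wi) * H;
          for (int ki = 0; ki < k; ++ki) {
            int hi = hi0 + ki;
            if (hi < 0 || hi >= H) continue;
            dxcol[hi] += cp[ki + k * kj];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(const NumericVector& x, int H, int W, int C,
                            int N, const NumericVector& w, int k, int Cout,
                            const NumericVector& bias, int stride) {
  const int p = (k - 1) / 2;
  const int Ho = (H + 2 * p - k) / stride + 1;
  const int Wo = (W + 2 * p - k) / stride + 1;
  const int K = C * k * k;
  const int L = Ho * Wo;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector y(static_cast<R_xlen_t>(L) * Cout * N);
  arma::mat col(K, L);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + static_cast<R_xlen_t>(n) * H * W * C;
    im2col_one(xn, H, W, C, k, p, stride, Ho, Wo, col);
    arma::mat outm(y.begin() + static_cast<R_xlen_t>(n) * L * Cout,
                   L, Cout, false, true);
    outm = col.t() * Wm;
    for (int co = 0; co < Cout; ++co) outm.col(co) += bias[co];
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List conv2d_bw_cpp(const NumericVector& x, int H, int W, int C, int N,
                   const NumericVector& w, int k, int Cout,
                   const NumericVector& dy, int stride) {
  const int p = (k - 1) / 2;
  const int Ho = (H + 2 * p - k) / stride + 1;
  const int Wo = (W + 2 * p - k) / stride + 1;
  const int K = C * k * k;
  const int L = Ho * Wo;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector dx(x.size());
  NumericVector dw(w.size());
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat col(K, L), dcol(K, L);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + static_cast<R_xlen_t>(n) * H * W * C;
    im2col_one(xn, H, W, C, k, p, stride, Ho, Wo, col);
    arma::mat dYm(const_cast<double*>(dy.begin()) +
                    static_cast<R_xlen_t>(n) * L * Cout,
                  L, Cout, false, true);
    dWm += col * dYm;
    dbv += arma::sum(dYm, 0).t();
    dcol = Wm * dYm.t();
    col2im_one(dcol, H, W, C, k, p, stride, Ho, Wo,
               dx.begin() + static_cast<R_xlen_t>(n) * H * W * C);
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
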