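// 2-D convolution kernels (stride 1, odd kernels, "same" padding, optional
// dilation) used by the reverse-mode autodiff engine. Layouts are R
// column-major: x (H, W, Cin, N), w (kh, kw, Cin, Cout), y (H, W, Cout, N).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int dh, int dw, int ph, int pw,
                   arma::mat& cols) {
  int col = 0;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i, ++col) {
        double* dst = cols.colptr(col);
        for (int w = 0; w < W; ++w) {
          int sw = w + j * dw - pw;
          const bool w_ok = (sw >= 0 && sw < W);
          for (int h = 0; h < H; ++h) {
            int sh = h + i * dh - ph;
            dst[h + H * w] = (w_ok && sh >= 0 && sh < H)
              ? x[sh + H * (sw + W * c)] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& cols, int H, int W, int C,
                       int kh, int kw, int dh, int dw, int ph, int pw,
                       double* gx) {
  int col = 0;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i, ++col) {
        const double* src = cols.colptr(col);
        for (int w = 0; w < W; ++w) {
          int sw = w + j * dw - pw;
          if (sw < 0 || sw >= W) continue;
          for (int h = 0; h < H; ++h) {
            int sh = h + i * dh - ph;
            if (sh < 0 || sh >= H) continue;
            gx[sh + H * (sw + W * c)] += src[h + H * w];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, IntegerVector dil) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != C) stop("conv2d: input channel mismatch");
  const int dh = dil[0], dw = dil[1];
  const int ph = dh * (kh - 1) / 2, pw = dw * (kw - 1) / 2;

  NumericVector y(static_cast<R_xlen_t>(H) * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(w.begin(), kh * kw * C, Cout, false, true);
  arma::mat cols(H * W, kh * kw * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + static_cast<size_t>(H) * W * C * n,
           H, W, C, kh, kw, dh, dw, ph, pw, cols);
    arma::mat Ym(y.begin() + static_cast<size_t>(H) * W * Cout * n,
                 H * W, Cout, false, true);
    Ym = cols * Wm;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                IntegerVector dil) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int dh = dil[0], dw = dil[1];
  const int ph = dh * (kh - 1) / 2, pw = dw * (kw - 1) / 2;

  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  gx.attr("dim") = xd;
  NumericVector gw(static_cast<R_xlen_t>(kh) * kw * C * Cout);
  gw.attr("dim") = wd;

  arma::mat Wm(w.begin(), kh * kw * C, Cout, false, true);
  arma::mat Gw(gw.begin(), kh * kw * C, Cout, false, true);
  arma::mat cols(H * W, kh * kw * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + static_cast<size_t>(H) * W * C * n,
           H, W, C, kh, kw, dh, dw, ph, pw, cols);
    arma::mat Gy(const_cast<double*>(gy.begin()) +
                 static_cast<size_t>(H) * W * Cout * n,
                 H * W, Cout, false, true);
    Gw += cols.t() * Gy;
    arma::mat gcols = Gy * Wm.t();
    col2im_add(gcols, H, W, C, kh, kw, dh, dw, ph, pw,
               gx.begin() + static_cast<size_t>(H) * W * C * n);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}
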