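// Low-level kernels for the neural-network engine.
// Array layout everywhere: column-major (H, W, C, N).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int idx4(int h, int w, int c, int n, int H, int W, int C) {
  return h + H * (w + W * (c + C * n));
}

// Unfold (H,W,C,N) into a (k*k*C) x (Ho*Wo*N) matrix of receptive-field
// columns, zero-padded by `pad` on every side, sampled with `stride`.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(k * k * C, Ho * Wo * N);
  const double* px = x.begin();
  double* po = out.begin();
  const int rows = k * k * C;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int col = ho + Ho * (wo + Wo * n);
        double* dst = po + (size_t)col * rows;
        for (int c = 0; c < C; ++c) {
          for (int kw = 0; kw < k; ++kw) {
            const int w = wo * stride - pad + kw;
            for (int kh = 0; kh < k; ++kh) {
              const int h = ho * stride - pad + kh;
              const int r = kh + k * (kw + k * c);
              dst[r] = (h >= 0 && h < H && w >= 0 && w < W)
                         ? px[idx4(h, w, c, n, H, W, C)] : 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add columns back onto the (H,W,C,N) grid.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector x(H * W * C * N);
  double* px = x.begin();
  const double* pc = cols.begin();
  const int rows = k * k * C;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int col = ho + Ho * (wo + Wo * n);
        const double* src = pc + (size_t)col * rows;
        for (int c = 0; c < C; ++c) {
          for (int kw = 0; kw < k; ++kw) {
            const int w = wo * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h = ho * stride - pad + kh;
              if (h < 0 || h >= H) continue;
              px[idx4(h, w, c, n, H, W, C)] += src[kh + k * (kw + k * c)];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}

// Depth-wise convolution, stride 1, symmetric zero padding (shape preserved).
// w has layout (k, k, C).
// [[Rcpp::export]]
NumericVector dw_conv_fwd(NumericVector x, NumericVector w,
                          int H, int W, int C, int N, int k) {
  const int pad = (k - 1) / 2;
  NumericVector y(H * W * C * N);
  const double* px = x.begin();
  const double* pw = w.begin();
  double* py = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* wc = pw + (size_t)c * k * k;
      for (int wo = 0; wo < W; ++wo) {
        for (int ho = 0; ho < H; ++ho) {
          double acc = 0.0;
          for (int kw = 0; kw < k; ++kw) {
            const int wi = wo - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int hi = ho - pad + kh;
              if (hi < 0 || hi >= H) continue;
              acc += px[idx4(hi, wi, c, n, H, W, C)] * wc[kh + k * kw];
            }
          }
          py[idx4(ho, wo, c, n, H, W, C)] = acc;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return y;
}

// Gradients of the depth-wise convolution: returns list(dx, dw).
// [[Rcpp::export]]
List dw_conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                 int H, int W, int C, int N, int k) {
  const int pad = (k - 1) / 2;
  NumericVector dx(H * W * C * N);
  NumericVector dw(k * k * C);
  const double* px = x.begin();
  const double* pw = w.begin();
  const double* pdy = dy.begin();
  double* pdx = dx.begin();
  double* pdw = dw.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* wc = pw + (size_t)c * k * k;
      double* dwc = pdw + (size_t)c * k * k;
      for (int wo = 0; wo < W; ++wo) {
        for (int ho = 0; ho < H; ++ho) {
          const double g = pdy[idx4(ho, wo, c, n, H, W, C)];
          if (g == 0.0) continue;
          for (int kw = 0; kw < k; ++kw) {
            const int wi = wo - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int hi = ho - pad + kh;
              if (hi < 0 || hi >= H) continue;
              const int xi = idx4(hi, wi, c, n, H, W, C);
              pdx[xi] += g * wc[kh + k * kw];
              dwc[kh + k * kw] += g * px[xi];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  dw.attr("dim") = IntegerVector::create(k, k, C);
  return List::create(Named("dx") = dx, Named("dw") = dw);
}
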