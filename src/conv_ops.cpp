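// Convolution and max-pooling kernels for the CNN engine.
// Arrays use R's column-major layout: activations are H x W x C x N,
// convolution weights kh x kw x Cin x Cout. im2col row index is
// ki + kh*(kj + kw*ci), matching the flattened weight layout so the
// convolution reduces to one GEMM per sample.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void im2col(const double* x, int H, int W, int C,
                          int kh, int kw, int stride, int pad,
                          int Ho, int Wo, arma::mat& cols) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int p = ho + Ho * wo;
      double* col = cols.colptr(p);
      int h0 = ho * stride - pad, w0 = wo * stride - pad;
      for (int ci = 0; ci < C; ++ci) {
        for (int kj = 0; kj < kw; ++kj) {
          int wi = w0 + kj;
          for (int ki = 0; ki < kh; ++ki) {
            int hi = h0 + ki;
            int r = ki + kh * (kj + kw * ci);
            col[r] = (hi >= 0 && hi < H && wi >= 0 && wi < W)
                       ? x[hi + (size_t)H * (wi + (size_t)W * ci)]
                       : 0.0;
          }
        }
      }
    }
  }
}

static inline void col2im_acc(const arma::mat& cols, double* gx,
                              int H, int W, int C,
                              int kh, int kw, int stride, int pad,
                              int Ho, int Wo) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int p = ho + Ho * wo;
      const double* col = cols.colptr(p);
      int h0 = ho * stride - pad, w0 = wo * stride - pad;
      for (int ci = 0; ci < C; ++ci) {
        for (int kj = 0; kj < kw; ++kj) {
          int wi = w0 + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            int hi = h0 + ki;
            if (hi < 0 || hi >= H) continue;
            int r = ki + kh * (kj + kw * ci);
            gx[hi + (size_t)H * (wi + (size_t)W * ci)] += col[r];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, IntegerVector xdim,
                                 NumericVector w, IntegerVector wdim,
                                 int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cin = wdim[2], Cout = wdim[3];
  if (Cin != C) stop("conv2d: input channels (%d) do not match weights (%d)", C, Cin);
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");

  const arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  NumericVector out((size_t)Ho * Wo * Cout * N);
  arma::mat cols(kh * kw * Cin, Ho * Wo);

  const size_t in_slab = (size_t)H * W * C, out_slab = (size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * in_slab, H, W, C, kh, kw, stride, pad, Ho, Wo, cols);
    arma::mat om(out.begin() + n * out_slab, Ho * Wo, Cout, false, true);
    om = cols.t() * Wm;
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return out;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector gout, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cin = wdim[2], Cout = wdim[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;

  const arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  NumericVector gx((size_t)H * W * C * N);
  NumericVector gw((size_t)kh * kw * Cin * Cout);
  arma::mat gWm(gw.begin(), kh * kw * Cin, Cout, false, true);
  arma::mat cols(kh * kw * Cin, Ho * Wo);

  const size_t in_slab = (size_t)H * W * C, out_slab = (size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * in_slab, H, W, C, kh, kw, stride, pad, Ho, Wo, cols);
    const arma::mat G(const_cast<double*>(gout.begin()) + n * out_slab,
                      Ho * Wo, Cout, false, true);
    gWm += cols * G;
    arma::mat gcols = Wm * G.t();
    col2im_acc(gcols, gx.begin() + n * in_slab, H, W, C, kh, kw, stride, pad, Ho, Wo);
  }
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["grad_x"] = gx, _["grad_w"] = gw);
}

// [[Rcpp::export]]
List maxpool_forward_cpp(NumericVector x, IntegerVector xdim,
                         int k, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("maxpool: output size would be empty");

  NumericVector out((size_t)Ho * Wo * C * N);
  IntegerVector amax((size_t)Ho * Wo * C * N);  // 0-based index into the sample slab
  const size_t in_slab = (size_t)H * W * C, out_slab = (size_t)Ho * Wo * C;

  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + n * in_slab;
    double* os = out.begin() + n * out_slab;
    int* as = amax.begin() + n * out_slab;
    for (int ci = 0; ci < C; ++ci) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          int h0 = ho * stride - pad, w0 = wo * stride - pad;
          double best = R_NegInf; int besti = -1;
          for (int kj = 0; kj < k; ++kj) {
            int wi = w0 + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = h0 + ki;
              if (hi < 0 || hi >= H) continue;
              size_t idx = hi + (size_t)H * (wi + (size_t)W * ci);
              if (xs[idx] > best) { best = xs[idx]; besti = (int)idx; }
            }
          }
          size_t o = ho + (size_t)Ho * (wo + (size_t)Wo * ci);
          os[o] = best; as[o] = besti;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  amax.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_cpp(IntegerVector amax, NumericVector gout,
                                   IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t in_slab = (size_t)H * W * C;
  const size_t out_slab = (size_t)amax.size() / N;
  NumericVector gx(in_slab * N);
  for (int n = 0; n < N; ++n) {
    const int* as = amax.begin() + n * out_slab;
    const double* gs = gout.begin() + n * out_slab;
    double* gxs = gx.begin() + n * in_slab;
    for (size_t o = 0; o < out_slab; ++o) gxs[as[o]] += gs[o];
  }
  gx.attr("dim") = xdim;
  return gx;
}
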