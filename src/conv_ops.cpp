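// Hot paths of the convolution and pooling layers: patch extraction
// (im2col) and its transpose, layout conversion between the GEMM matrix
// and the [N, K, H, W] feature-map arrays, and block max pooling with
// argmax routing for backprop. The matrix products themselves stay in R's
// BLAS.

#include <Rcpp.h>
using namespace Rcpp;

// x: [N, C, H, W]; returns [(N*H_out*W) x (C*klen)] patch matrix whose
// column (c, r) holds x[n, c, h + r - 1, w] for row (n, h, w).
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int klen) {
  IntegerVector d = x.attr("dim");
  const int N = d[0], C = d[1], H = d[2], W = d[3];
  const int hout = H - klen + 1;
  const R_xlen_t rows = (R_xlen_t)N * hout * W;
  NumericMatrix P(rows, C * klen);
  const double* px = x.begin();
  double* pp = P.begin();
  for (int r = 0; r < klen; ++r) {
    for (int c = 0; c < C; ++c) {
      double* col = pp + ((R_xlen_t)(r * C + c)) * rows;
      for (int w = 0; w < W; ++w) {
        for (int h = 0; h < hout; ++h) {
          const double* src = px + (R_xlen_t)N * (c + (R_xlen_t)C * ((h + r) + (R_xlen_t)H * w));
          double* dst = col + (R_xlen_t)N * (h + (R_xlen_t)hout * w);
          for (int n = 0; n < N; ++n) dst[n] = src[n];
        }
      }
    }
  }
  return P;
}

// transpose of cpp_im2col: scatter-add patch gradients back to [N, C, H, W]
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dP, IntegerVector dims, int klen) {
  const int N = dims[0], C = dims[1], H = dims[2], W = dims[3];
  const int hout = H - klen + 1;
  const R_xlen_t rows = (R_xlen_t)N * hout * W;
  NumericVector dx((R_xlen_t)N * C * H * W);
  dx.attr("dim") = dims;
  const double* pp = dP.begin();
  double* px = dx.begin();
  for (int r = 0; r < klen; ++r) {
    for (int c = 0; c < C; ++c) {
      const double* col = pp + ((R_xlen_t)(r * C + c)) * rows;
      for (int w = 0; w < W; ++w) {
        for (int h = 0; h < hout; ++h) {
          double* dst = px + (R_xlen_t)N * (c + (R_xlen_t)C * ((h + r) + (R_xlen_t)H * w));
          const double* src = col + (R_xlen_t)N * (h + (R_xlen_t)hout * w);
          for (int n = 0; n < N; ++n) dst[n] += src[n];
        }
      }
    }
  }
  return dx;
}

// Z: [(N*hout*W) x K] GEMM output -> [N, K, hout, W] feature maps
// [[Rcpp::export]]
NumericVector cpp_mat_to_maps(NumericMatrix Z, int N, int hout, int W) {
  const int K = Z.ncol();
  NumericVector out((R_xlen_t)N * K * hout * W);
  out.attr("dim") = IntegerVector::create(N, K, hout, W);
  const double* pz = Z.begin();
  double* po = out.begin();
  for (int k = 0; k < K; ++k) {
    const double* col = pz + (R_xlen_t)k * N * hout * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < hout; ++h) {
        const double* src = col + (R_xlen_t)N * (h + (R_xlen_t)hout * w);
        double* dst = po + (R_xlen_t)N * (k + (R_xlen_t)K * (h + (R_xlen_t)hout * w));
        for (int n = 0; n < N; ++n) dst[n] = src[n];
      }
    }
  }
  return out;
}

// inverse layout conversion: [N, K, hout, W] -> [(N*hout*W) x K]
// [[Rcpp::export]]
NumericMatrix cpp_maps_to_mat(NumericVector a) {
  IntegerVector d = a.attr("dim");
  const int N = d[0], K = d[1], hout = d[2], W = d[3];
  NumericMatrix Z((R_xlen_t)N * hout * W, K);
  const double* pa = a.begin();
  double* pz = Z.begin();
  for (int k = 0; k < K; ++k) {
    double* col = pz + (R_xlen_t)k * N * hout * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < hout; ++h) {
        double* dst = col + (R_xlen_t)N * (h + (R_xlen_t)hout * w);
        const double* src = pa + (R_xlen_t)N * (k + (R_xlen_t)K * (h + (R_xlen_t)hout * w));
        for (int n = 0; n < N; ++n) dst[n] = src[n];
      }
    }
  }
  return Z;
}

// Non-overlapping block max pooling (stride = window, truncated edges).
// Returns pooled maps and 1-based linear argmax indices into x; ties break
// to the first element in column-major block order.
// [[Rcpp::export]]
List cpp_pool_fwd(NumericVector x, int ph_win, int pw_win) {
  IntegerVector d = x.attr("dim");
  const int N = d[0], K = d[1], H = d[2], W = d[3];
  const int ph = H / ph_win, pw = W / pw_win;
  NumericVector out((R_xlen_t)N * K * ph * pw);
  out.attr("dim") = IntegerVector::create(N, K, ph, pw);
  NumericVector amax((R_xlen_t)N * K * ph * pw);
  const double* px = x.begin();
  double* po = out.begin();
  double* pm = amax.begin();
  R_xlen_t o = 0;
  for (int pj = 0; pj < pw; ++pj) {
    for (int pi = 0; pi < ph; ++pi) {
      for (int k = 0; k < K; ++k) {
        for (int n = 0; n < N; ++n) {
          double best = R_NegInf;
          R_xlen_t besti = 0;
          for (int b = 0; b < pw_win; ++b) {
            const int w = pj * pw_win + b;
            for (int a = 0; a < ph_win; ++a) {
              const int h = pi * ph_win + a;
              const R_xlen_t idx = n + (R_xlen_t)N * (k + (R_xlen_t)K * (h + (R_xlen_t)H * w));
              if (px[idx] > best) { best = px[idx]; besti = idx; }
            }
          }
          po[o] = best;
          pm[o] = (double)(besti + 1);
          ++o;
        }
      }
    }
  }
  // out is filled in (n, k, pi, pj) column-major order already
  return List::create(Named("a") = out, Named("argmax") = amax);
}

// route pooled-gradient entries back to their argmax positions
// [[Rcpp::export]]
NumericVector cpp_pool_bwd(NumericVector da, NumericVector amax, IntegerVector dims) {
  NumericVector dx((R_xlen_t)dims[0] * dims[1] * dims[2] * dims[3]);
  dx.attr("dim") = dims;
  const double* pd = da.begin();
  const double* pm = amax.begin();
  double* px = dx.begin();
  const R_xlen_t n = da.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    px[(R_xlen_t)pm[i] - 1] += pd[i];
  }
  return dx;
}

// relu(Z + bias) with the bias broadcast over each column's block
// [[Rcpp::export]]
NumericMatrix cpp_bias_relu(NumericMatrix Z, NumericVector b) {
  const R_xlen_t n = Z.nrow();
  const int K = Z.ncol();
  NumericMatrix A(n, K);
  for (int k = 0; k < K; ++k) {
    const double bk = b[k];
    const double* src = Z.begin() + (R_xlen_t)k * n;
    double* dst = A.begin() + (R_xlen_t)k * n;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double v = src[i] + bk;
      dst[i] = v > 0 ? v : 0;
    }
  }
  return A;
}

// da * (a > 0): relu gradient routed through stored activations
// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector da, NumericVector a) {
  const R_xlen_t n = da.size();
  NumericVector out(n);
  if (da.hasAttribute("dim")) out.attr("dim") = da.attr("dim");
  for (R_xlen_t i = 0; i < n; ++i) out[i] = a[i] > 0 ? da[i] : 0;
  return out;
}

// inverted dropout using R's RNG stream (deterministic under set.seed)
// [[Rcpp::export]]
List cpp_dropout(NumericVector a, double rate) {
  const R_xlen_t n = a.size();
  const double scale = 1.0 / (1.0 - rate);
  NumericVector out(n), mask(n);
  if (a.hasAttribute("dim")) {
    out.attr("dim") = a.attr("dim");
    mask.attr("dim") = a.attr("dim");
  }
  for (R_xlen_t i = 0; i < n; ++i) {
    if (unif_rand() >= rate) {
      mask[i] = scale;
      out[i] = a[i] * scale;
    }
  }
  return List::create(Named("a") = out, Named("mask") = mask);
}

// elementwise product preserving dims (dropout backward)
// [[Rcpp::export]]
NumericVector cpp_mul(NumericVector x, NumericVector y) {
  const R_xlen_t n = x.size();
  NumericVector out(n);
  if (x.hasAttribute("dim")) out.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < n; ++i) out[i] = x[i] * y[i];
  return out;
}
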