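// Hot numeric kernels for madrnet: dilated 2-D convolution (forward and
// backward via im2col + GEMM), 2x2 stride-2 transposed convolution, and
// 2x2 max-pooling with argmax routing.
//
// Array layout everywhere: column-major doubles with dim (H, W, C, N).
// Convolution weights: dim (k, k, C_in, C_out); transposed-conv weights:
// dim (2, 2, C_in, C_out). "Same" zero padding with pad = d*(k-1)/2, which
// requires k odd (enforced on the R side).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline NumericVector arr4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline IntegerVector iarr4(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline void dims4(const NumericVector& x, int& d1, int& d2, int& d3, int& d4) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-D array");
  d1 = d[0]; d2 = d[1]; d3 = d[2]; d4 = d[3];
}

// Fill col (H*W x k*k*C) with the dilated receptive field of sample n.
static void im2col_dilated(const double* x, int H, int W, int C, int n,
                           int k, int d, arma::mat& col) {
  const int half = (k - 1) / 2;
  const double* xs = x + (size_t)n * H * W * C;
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* plane = xs + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      const int dw = (kj - half) * d;
      for (int ki = 0; ki < k; ++ki) {
        const int dh = (ki - half) * d;
        double* dst = col.colptr(ki + k * kj + k * k * c);
        for (int w = 0; w < W; ++w) {
          const int iw = w + dw;
          if (iw < 0 || iw >= W) continue;
          const double* src = plane + (size_t)iw * H;
          double* out = dst + (size_t)w * H;
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          for (int h = h0; h < h1; ++h) out[h] = src[h + dh];
        }
      }
    }
  }
}

// Scatter-add of gcol (H*W x k*k*C) back into gx for sample n (col2im).
static void col2im_dilated(const arma::mat& gcol, int H, int W, int C, int n,
                           int k, int d, double* gx) {
  const int half = (k - 1) / 2;
  double* xs = gx + (size_t)n * H * W * C;
  for (int c = 0; c < C; ++c) {
    double* plane = xs + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      const int dw = (kj - half) * d;
      for (int ki = 0; ki < k; ++ki) {
        const int dh = (ki - half) * d;
        const double* src0 = gcol.colptr(ki + k * kj + k * k * c);
        for (int w = 0; w < W; ++w) {
          const int iw = w + dw;
          if (iw < 0 || iw >= W) continue;
          double* dst = plane + (size_t)iw * H;
          const double* src = src0 + (size_t)w * H;
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          for (int h = h0; h < h1; ++h) dst[h + dh] += src[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b, int d) {
  int H, W, C, N, k, k2, Cw, O;
  dims4(x, H, W, C, N);
  dims4(w, k, k2, Cw, O);
  if (k != k2) stop("kernel must be square");
  if (Cw != C) stop("weight/input channel mismatch");
  NumericVector y = arr4(H, W, O, N);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * C, O, false, true);
  arma::mat col((size_t)H * W, (size_t)k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col_dilated(x.begin(), H, W, C, n, k, d, col);
    arma::mat ym(y.begin() + (size_t)n * H * W * O, (size_t)H * W, O, false, true);
    ym = col * Wm;
    for (int o = 0; o < O; ++o) ym.col(o) += b[o];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, int d, NumericVector gy) {
  int H, W, C, N, k, k2, Cw, O;
  dims4(x, H, W, C, N);
  dims4(w, k, k2, Cw, O);
  if (Cw != C) stop("weight/input channel mismatch");
  NumericVector gx = arr4(H, W, C, N);
  NumericVector gw = arr4(k, k, C, O);
  NumericVector gb(O);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * C, O, false, true);
  arma::mat Gw(gw.begin(), (size_t)k * k * C, O, false, true);
  arma::vec Gb(gb.begin(), O, false, true);
  arma::mat col((size_t)H * W, (size_t)k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col_dilated(x.begin(), H, W, C, n, k, d, col);
    arma::mat gym(const_cast<double*>(gy.begin()) + (size_t)n * H * W * O,
                  (size_t)H * W, O, false, true);
    Gw += col.t() * gym;
    Gb += arma::sum(gym, 0).t();
    arma::mat gcol = gym * Wm.t();
    col2im_dilated(gcol, H, W, C, n, k, d, gx.begin());
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 stride-2 transposed convolution: y[2h+i, 2w+j, o, n] =
//   sum_c x[h, w, c, n] * w[i, j, c, o] + b[o]. Non-overlapping taps.
// [[Rcpp::export]]
NumericVector cpp_convt2_fw(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, C, N, two, two2, Cw, O;
  dims4(x, H, W, C, N);
  dims4(w, two, two2, Cw, O);
  if (two != 2 || two2 != 2) stop("transposed kernel must be 2x2");
  if (Cw != C) stop("weight/input channel mismatch");
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = arr4(Ho, Wo, O, N);
  // Wm: (C x 4*O), row c, col (i + 2j + 4o)
  arma::mat Wm(C, 4 * O);
  for (int o = 0; o < O; ++o)
    for (int j = 0; j < 2; ++j)
      for (int i = 0; i < 2; ++i)
        for (int c = 0; c < C; ++c)
          Wm(c, i + 2 * j + 4 * o) = w[i + 2 * (j + 2 * ((size_t)c + (size_t)C * o))];
  for (int n = 0; n < N; ++n) {
    arma::mat xm(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                 (size_t)H * W, C, false, true);
    arma::mat ym = xm * Wm;  // (H*W x 4*O)
    double* yn = y.begin() + (size_t)n * Ho * Wo * O;
    for (int o = 0; o < O; ++o) {
      double* plane = yn + (size_t)o * Ho * Wo;
      for (int j = 0; j < 2; ++j)
        for (int i = 0; i < 2; ++i) {
          const double* src = ym.colptr(i + 2 * j + 4 * o);
          for (int w2 = 0; w2 < W; ++w2) {
            double* dst = plane + (size_t)(2 * w2 + j) * Ho;
            const double* s = src + (size_t)w2 * H;
            for (int h = 0; h < H; ++h) dst[2 * h + i] = s[h] + b[o];
          }
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2_bw(NumericVector x, NumericVector w, NumericVector gy) {
  int H, W, C, N, two, two2, Cw, O;
  dims4(x, H, W, C, N);
  dims4(w, two, two2, Cw, O);
  if (Cw != C) stop("weight/input channel mismatch");
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx = arr4(H, W, C, N);
  NumericVector gw = arr4(2, 2, C, O);
  NumericVector gb(O);
  arma::mat Wm(C, 4 * O);
  for (int o = 0; o < O; ++o)
    for (int j = 0; j < 2; ++j)
      for (int i = 0; i < 2; ++i)
        for (int c = 0; c < C; ++c)
          Wm(c, i + 2 * j + 4 * o) = w[i + 2 * (j + 2 * ((size_t)c + (size_t)C * o))];
  arma::mat Gwm(C, 4 * O, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    // gather gy into (H*W x 4*O)
    arma::mat gym((size_t)H * W, 4 * O);
    const double* gyn = gy.begin() + (size_t)n * Ho * Wo * O;
    for (int o = 0; o < O; ++o) {
      const double* plane = gyn + (size_t)o * Ho * Wo;
      for (int j = 0; j < 2; ++j)
        for (int i = 0; i < 2; ++i) {
          double* dst = gym.colptr(i + 2 * j + 4 * o);
          for (int w2 = 0; w2 < W; ++w2) {
            const double* src = plane + (size_t)(2 * w2 + j) * Ho;
            double* dd = dst + (size_t)w2 * H;
            for (int h = 0; h < H; ++h) dd[h] = src[2 * h + i];
          }
          gb[o] += arma::accu(arma::vec(dst, (size_t)H * W, false, true));
        }
    }
    arma::mat xm(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                 (size_t)H * W, C, false, true);
    arma::mat gxm(gx.begin() + (size_t)n * H * W * C, (size_t)H * W, C, false, true);
    gxm = gym * Wm.t();
    Gwm += xm.t() * gym;
  }
  for (int o = 0; o < O; ++o)
    for (int j = 0; j < 2; ++j)
      for (int i = 0; i < 2; ++i)
        for (int c = 0; c < C; ++c)
          gw[i + 2 * (j + 2 * ((size_t)c + (size_t)C * o))] = Gwm(c, i + 2 * j + 4 * o);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("max-pooling needs even H and W");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = arr4(Ho, Wo, C, N);
  IntegerVector idx = iarr4(Ho, Wo, C, N);
  size_t p = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* plane = x.begin() + ((size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          double best = plane[2 * h + (size_t)(2 * w) * H];
          int bi = 0;
          for (int j = 0; j < 2; ++j)
            for (int i = 0; i < 2; ++i) {
              const double v = plane[2 * h + i + (size_t)(2 * w + j) * H];
              if (v > best) { best = v; bi = i + 2 * j; }
            }
          // column-major output order is (h, w, c, n) => recompute position
          const size_t q = (size_t)h + (size_t)Ho * (w + (size_t)Wo * (c + (size_t)C * n));
          y[q] = best; idx[q] = bi; ++p;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(IntegerVector idx, NumericVector gy, int H, int W) {
  int Ho, Wo, C, N;
  dims4(gy, Ho, Wo, C, N);
  NumericVector gx = arr4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* plane = gx.begin() + ((size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          const size_t q = (size_t)h + (size_t)Ho * (w + (size_t)Wo * (c + (size_t)C * n));
          const int bi = idx[q];
          plane[2 * h + (bi % 2) + (size_t)(2 * w + bi / 2) * H] += gy[q];
        }
    }
  return gx;
}
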