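// Compiled tensor kernels for the segmentation network.
//
// Layout conventions (R column-major):
//   activations: dim (H, W, C, N)
//   conv weights: dim (KH, KW, Cin, Cout)
//   transposed-conv weights: dim (KH, KW, Cout, Cin)
// All kernels compute in single precision (im2col + sgemm); the R interface
// uses double arrays.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::fvec as_f(const NumericVector& v) {
  arma::fvec out(v.size());
  const double* p = v.begin();
  for (arma::uword i = 0; i < out.n_elem; ++i) out[i] = static_cast<float>(p[i]);
  return out;
}

static NumericVector to_r(const arma::fvec& v, const IntegerVector& dim) {
  NumericVector out(v.n_elem);
  double* p = out.begin();
  for (arma::uword i = 0; i < v.n_elem; ++i) p[i] = static_cast<double>(v[i]);
  out.attr("dim") = dim;
  return out;
}

static int out_size(int H, int K, int s, int p, int d) {
  return (H + 2 * p - (d * (K - 1) + 1)) / s + 1;
}

// Valid output range [lo, hi] such that o*s + off lies in [0, limit).
static inline void run_bounds(int off, int s, int limit, int n_out,
                              int& lo, int& hi) {
  lo = (off >= 0) ? 0 : ((-off + s - 1) / s);
  hi = (limit - 1 - off >= 0) ? (limit - 1 - off) / s : -1;
  if (hi > n_out - 1) hi = n_out - 1;
  if (lo > n_out) lo = n_out;
}

// Gather image patches into a column-major matrix with leading dimension ld,
// writing the block of rows starting at row_off (rows: out pixels
// ho + wo*Ho; cols: kh + KH*(kw + KW*c)).
static void im2col_block(const float* x, int H, int W, int C,
                         int KH, int KW, int s, int p, int d,
                         int Ho, int Wo, float* Mbase, size_t ld,
                         size_t row_off) {
  for (int c = 0; c < C; ++c) {
    const float* plane = x + static_cast<size_t>(c) * H * W;
    for (int kw = 0; kw < KW; ++kw) {
      int off_w = kw * d - p;
      int wlo, whi;
      run_bounds(off_w, s, W, Wo, wlo, whi);
      for (int kh = 0; kh < KH; ++kh) {
        int off_h = kh * d - p;
        int hlo, hhi;
        run_bounds(off_h, s, H, Ho, hlo, hhi);
        float* col = Mbase + static_cast<size_t>(kh + KH * (kw + KW * c)) * ld
          + row_off;
        for (int wo = 0; wo < Wo; ++wo) {
          float* dst = col + static_cast<size_t>(wo) * Ho;
          if (wo < wlo || wo > whi || hlo > hhi) {
            std::fill(dst, dst + Ho, 0.0f);
            continue;
          }
          const float* src = plane + (static_cast<size_t>(wo) * s + off_w) * H;
          std::fill(dst, dst + hlo, 0.0f);
          std::fill(dst + hhi + 1, dst + Ho, 0.0f);
          if (s == 1) {
            std::memcpy(dst + hlo, src + hlo + off_h,
                        static_cast<size_t>(hhi - hlo + 1) * sizeof(float));
          } else {
            for (int ho = hlo; ho <= hhi; ++ho) dst[ho] = src[ho * s + off_h];
          }
        }
      }
    }
  }
}

static void im2col(const float* x, int H, int W, int C,
                   int KH, int KW, int s, int p, int d,
                   int Ho, int Wo, arma::fmat& M) {
  im2col_block(x, H, W, C, KH, KW, s, p, d, Ho, Wo, M.memptr(), M.n_rows, 0);
}

// Scatter-add a row block of M back onto the image (adjoint of im2col_block).
static void col2im_block(float* x, int H, int W, int C,
                         int KH, int KW, int s, int p, int d,
                         int Ho, int Wo, const float* Mbase, size_t ld,
                         size_t row_off) {
  for (int c = 0; c < C; ++c) {
    float* plane = x + static_cast<size_t>(c) * H * W;
    for (int kw = 0; kw < KW; ++kw) {
      int off_w = kw * d - p;
      int wlo, whi;
      run_bounds(off_w, s, W, Wo, wlo, whi);
      for (int kh = 0; kh < KH; ++kh) {
        int off_h = kh * d - p;
        int hlo, hhi;
        run_bounds(off_h, s, H, Ho, hlo, hhi);
        if (hlo > hhi) continue;
        const float* col = Mbase
          + static_cast<size_t>(kh + KH * (kw + KW * c)) * ld + row_off;
        for (int wo = wlo; wo <= whi; ++wo) {
          const float* src = col + static_cast<size_t>(wo) * Ho;
          float* dstp = plane + (static_cast<size_t>(wo) * s + off_w) * H;
          if (s == 1) {
            float* base = dstp + off_h;
            for (int ho = hlo; ho <= hhi; ++ho) base[ho] += src[ho];
          } else {
            for (int ho = hlo; ho <= hhi; ++ho) dstp[ho * s + off_h] += src[ho];
          }
        }
      }
    }
  }
}

static void col2im(float* x, int H, int W, int C,
                   int KH, int KW, int s, int p, int d,
                   int Ho, int Wo, const arma::fmat& M) {
  col2im_block(x, H, W, C, KH, KW, s, p, d, Ho, Wo, M.memptr(), M.n_rows, 0);
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weight expects %d", C, Cin);
  int Ho = out_size(H, KH, stride, pad, dil);
  int Wo = out_size(W, KW, stride, pad, dil);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");

  arma::fvec xf = as_f(x);
  arma::fvec wf = as_f(w);
  arma::fvec bf = as_f(b);
  arma::fmat Wm(wf.memptr(), KH * KW * Cin, Cout, false, true);

  arma::fvec yf(static_cast<arma::uword>(Ho) * Wo * Cout * N);
  arma::fmat M(static_cast<arma::uword>(Ho) * Wo, static_cast<arma::uword>(KH) * KW * Cin);
  for (int n = 0; n < N; ++n) {
    const float* xn = xf.memptr() + static_cast<size_t>(n) * H * W * C;
    im2col(xn, H, W, C, KH, KW, stride, pad, dil, Ho, Wo, M);
    arma::fmat Y(yf.memptr() + static_cast<size_t>(n) * Ho * Wo * Cout,
                 static_cast<arma::uword>(Ho) * Wo, Cout, false, true);
    Y = M * Wm;
    if (bf.n_elem == static_cast<arma::uword>(Cout)) Y.each_row() += bf.t();
  }
  return to_r(yf, IntegerVector::create(Ho, Wo, Cout, N));
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, int pad, int dil, bool need_dx, bool has_bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = out_size(H, KH, stride, pad, dil);
  int Wo = out_size(W, KW, stride, pad, dil);

  arma::fvec xf = as_f(x);
  arma::fvec wf = as_f(w);
  arma::fvec dyf = as_f(dy);
  arma::fmat Wm(wf.memptr(), KH * KW * Cin, Cout, false, true);

  arma::fmat dW(KH * KW * Cin, Cout, arma::fill::zeros);
  arma::fvec db(Cout, arma::fill::zeros);
  arma::fvec dxf;
  if (need_dx) dxf.zeros(xf.n_elem);

  arma::fmat M(static_cast<arma::uword>(Ho) * Wo, static_cast<arma::uword>(KH) * KW * Cin);
  for (int n = 0; n < N; ++n) {
    const float* xn = xf.memptr() + static_cast<size_t>(n) * H * W * C;
    im2col(xn, H, W, C, KH, KW, stride, pad, dil, Ho, Wo, M);
    arma::fmat dYn(dyf.memptr() + static_cast<size_t>(n) * Ho * Wo * Cout,
                   static_cast<arma::uword>(Ho) * Wo, Cout, false, true);
    dW += M.t() * dYn;
    if (has_bias) db += arma::sum(dYn, 0).t();
    if (need_dx) {
      arma::fmat dM = dYn * Wm.t();
      float* dxn = dxf.memptr() + static_cast<size_t>(n) * H * W * C;
      col2im(dxn, H, W, C, KH, KW, stride, pad, dil, Ho, Wo, dM);
    }
  }
  List out = List::create(
    Named("dw") = to_r(arma::fvec(dW.memptr(), dW.n_elem), wd),
    Named("db") = has_bias ? (SEXP)to_r(db, IntegerVector::create(Cout)) : R_NilValue,
    Named("dx") = need_dx ? (SEXP)to_r(dxf, xd) : R_NilValue);
  return out;
}

typedef std::vector<arma::fmat> ColCache;

// Forward pass that additionally hands back the per-sample im2col matrices
// for reuse in the backward pass (training path).
// [[Rcpp::export]]
List cpp_conv2d_fw_cached(NumericVector x, NumericVector w, NumericVector b,
                          int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weight expects %d", C, Cin);
  int Ho = out_size(H, KH, stride, pad, dil);
  int Wo = out_size(W, KW, stride, pad, dil);

  arma::fvec xf = as_f(x);
  arma::fvec wf = as_f(w);
  arma::fvec bf = as_f(b);
  arma::fmat Wm(wf.memptr(), KH * KW * Cin, Cout, false, true);

  // all samples stacked into one matrix -> a single GEMM per layer
  size_t HoWo = static_cast<size_t>(Ho) * Wo;
  XPtr<ColCache> cache(new ColCache(), true);
  cache->emplace_back(HoWo * N, static_cast<arma::uword>(KH) * KW * Cin);
  arma::fmat& M = cache->front();
  for (int n = 0; n < N; ++n) {
    const float* xn = xf.memptr() + static_cast<size_t>(n) * H * W * C;
    im2col_block(xn, H, W, C, KH, KW, stride, pad, dil, Ho, Wo,
                 M.memptr(), M.n_rows, n * HoWo);
  }
  arma::fmat Yall = M * Wm;  // (N*HoWo) x Cout
  bool has_b = bf.n_elem == static_cast<arma::uword>(Cout);
  arma::fvec yf(HoWo * Cout * N);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const float* src = Yall.colptr(co) + n * HoWo;
      float* dst = yf.memptr() + (static_cast<size_t>(n) * Cout + co) * HoWo;
      if (has_b) {
        float bc = bf[co];
        for (size_t i = 0; i < HoWo; ++i) dst[i] = src[i] + bc;
      } else {
        std::memcpy(dst, src, HoWo * sizeof(float));
      }
    }
  }
  return List::create(Named("y") = to_r(yf, IntegerVector::create(Ho, Wo, Cout, N)),
                      Named("cols") = cache);
}

// Backward pass consuming the cached im2col matrices.
// [[Rcpp::export]]
List cpp_conv2d_bw_cached(SEXP cols, IntegerVector xdim, NumericVector w,
                          NumericVector dy, int stride, int pad, int dil,
                          bool need_dx, bool has_bias) {
  XPtr<ColCache> cache(cols);
  IntegerVector wd = w.attr("dim");
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = out_size(H, KH, stride, pad, dil);
  int Wo = out_size(W, KW, stride, pad, dil);

  arma::fvec wf = as_f(w);
  arma::fvec dyf = as_f(dy);
  arma::fmat Wm(wf.memptr(), KH * KW * Cin, Cout, false, true);

  size_t HoWo = static_cast<size_t>(Ho) * Wo;
  const arma::fmat& M = cache->front();

  // restack dy into (N*HoWo) x Cout to mirror the cached column matrix
  arma::fmat dYall(HoWo * N, Cout);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      std::memcpy(dYall.colptr(co) + n * HoWo,
                  dyf.memptr() + (static_cast<size_t>(n) * Cout + co) * HoWo,
                  HoWo * sizeof(float));
    }
  }
  arma::fmat dW = M.t() * dYall;
  arma::fvec db(Cout, arma::fill::zeros);
  if (has_bias) db = arma::sum(dYall, 0).t();
  arma::fvec dxf;
  if (need_dx) {
    dxf.zeros(static_cast<arma::uword>(H) * W * C * N);
    arma::fmat dM = dYall * Wm.t();
    for (int n = 0; n < N; ++n) {
      float* dxn = dxf.memptr() + static_cast<size_t>(n) * H * W * C;
      col2im_block(dxn, H, W, C, KH, KW, stride, pad, dil, Ho, Wo,
                   dM.memptr(), dM.n_rows, n * HoWo);
    }
  }
  return List::create(
    Named("dw") = to_r(arma::fvec(dW.memptr(), dW.n_elem), wd),
    Named("db") = has_bias ? (SEXP)to_r(db, IntegerVector::create(Cout)) : R_NilValue,
    Named("dx") = need_dx ? (SEXP)to_r(dxf, xdim) : R_NilValue);
}

// Transposed convolution: out = (H - 1) * stride - 2 * pad + KH + opad.
// [[Rcpp::export]]
NumericVector cpp_convt2d_fw(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad, int opad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], Cout = wd[2], Cin = wd[3];
  if (Cin != C) stop("convt2d: input has %d channels, weight expects %d", C, Cin);
  int Ho = (H - 1) * stride - 2 * pad + KH + opad;
  int Wo = (W - 1) * stride - 2 * pad + KW + opad;

  arma::fvec xf = as_f(x);
  arma::fvec wf = as_f(w);
  arma::fvec bf = as_f(b);
  arma::fmat Wm(wf.memptr(), KH * KW * Cout, Cin, false, true);

  arma::fvec yf(static_cast<arma::uword>(Ho) * Wo * Cout * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::fmat Xn(xf.memptr() + static_cast<size_t>(n) * H * W * C,
                  static_cast<arma::uword>(H) * W, C, false, true);
    arma::fmat cols = Xn * Wm.t();  // (H*W) x (KH*KW*Cout)
    float* yn = yf.memptr() + static_cast<size_t>(n) * Ho * Wo * Cout;
    col2im(yn, Ho, Wo, Cout, KH, KW, stride, pad, 1, H, W, cols);
    if (bf.n_elem == static_cast<arma::uword>(Cout)) {
      for (int c = 0; c < Cout; ++c) {
        float* plane = yn + static_cast<size_t>(c) * Ho * Wo;
        for (int i = 0; i < Ho * Wo; ++i) plane[i] += bf[c];
      }
    }
  }
  return to_r(yf, IntegerVector::create(Ho, Wo, Cout, N));
}

// [[Rcpp::export]]
List cpp_convt2d_bw(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, int opad, bool need_dx, bool has_bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], Cout = wd[2], Cin = wd[3];
  int Ho = (H - 1) * stride - 2 * pad + KH + opad;
  int Wo = (W - 1) * stride - 2 * pad + KW + opad;

  arma::fvec xf = as_f(x);
  arma::fvec wf = as_f(w);
  arma::fvec dyf = as_f(dy);
  arma::fmat Wm(wf.memptr(), KH * KW * Cout, Cin, false, true);

  arma::fmat dW(KH * KW * Cout, Cin, arma::fill::zeros);
  arma::fvec db(Cout, arma::fill::zeros);
  arma::fvec dxf;
  if (need_dx) dxf.zeros(xf.n_elem);

  arma::fmat dcols(static_cast<arma::uword>(H) * W, static_cast<arma::uword>(KH) * KW * Cout);
  for (int n = 0; n < N; ++n) {
    const float* dyn = dyf.memptr() + static_cast<size_t>(n) * Ho * Wo * Cout;
    im2col(dyn, Ho, Wo, Cout, KH, KW, stride, pad, 1, H, W, dcols);
    arma::fmat Xn(xf.memptr() + static_cast<size_t>(n) * H * W * C,
                  static_cast<arma::uword>(H) * W, C, false, true);
    dW += dcols.t() * Xn;
    if (need_dx) {
      arma::fmat dXn(dxf.memptr() + static_cast<size_t>(n) * H * W * C,
                     static_cast<arma::uword>(H) * W, C, false, true);
      dXn = dcols * Wm;
    }
    if (has_bias) {
      for (int c = 0; c < Cout; ++c) {
        const float* plane = dyn + static_cast<size_t>(c) * Ho * Wo;
        double s = 0;
        for (int i = 0; i < Ho * Wo; ++i) s += plane[i];
        db[c] += static_cast<float>(s);
      }
    }
  }
  return List::create(
    Named("dw") = to_r(arma::fvec(dW.memptr(), dW.n_elem), wd),
    Named("db") = has_bias ? (SEXP)to_r(db, IntegerVector::create(Cout)) : R_NilValue,
    Named("dx") = need_dx ? (SEXP)to_r(dxf, xd) : R_NilValue);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_size(H, k, stride, pad, 1);
  int Wo = out_size(W, k, stride, pad, 1);
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  IntegerVector idx(y.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = xp + (static_cast<size_t>(n) * C + c) * H * W;
      size_t ob = (static_cast<size_t>(n) * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          int bi = -1;
          for (int kw = 0; kw < k; ++kw) {
            int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              double v = plane[hi + static_cast<size_t>(wi) * H];
              if (v > best) { best = v; bi = hi + wi * H; }
            }
          }
          yp[ob + ho + static_cast<size_t>(wo) * Ho] = (bi >= 0) ? best : 0.0;
          ip[ob + ho + static_cast<size_t>(wo) * Ho] = bi;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(IntegerVector idx, NumericVector dy, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1];
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* plane = dxp + (static_cast<size_t>(n) * C + c) * H * W;
      size_t ob = (static_cast<size_t>(n) * C + c) * Ho * Wo;
      for (size_t i = 0; i < static_cast<size_t>(Ho) * Wo; ++i) {
        int bi = ip[ob + i];
        if (bi >= 0) plane[bi] += dyp[ob + i];
      }
    }
  }
  dx.attr("dim") = xdim;
  return dx;
}

// Batch normalization over (H, W, N) per channel.
// [[Rcpp::export]]
List cpp_bn_fw(NumericVector x, NumericVector gamma, NumericVector beta,
               NumericVector rmean, NumericVector rvar,
               double momentum, double eps, bool training) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t HW = static_cast<size_t>(H) * W;
  double m = static_cast<double>(HW) * N;
  NumericVector y(x.size());
  NumericVector smean(C), sinvstd(C), nrmean(clone(rmean)), nrvar(clone(rvar));
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    double mu, var;
    if (training) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* plane = xp + (static_cast<size_t>(n) * C + c) * HW;
        for (size_t i = 0; i < HW; ++i) { s += plane[i]; s2 += plane[i] * plane[i]; }
      }
      mu = s / m;
      var = s2 / m - mu * mu;
      if (var < 0) var = 0;
      double unb = (m > 1) ? var * m / (m - 1) : var;
      nrmean[c] = (1 - momentum) * nrmean[c] + momentum * mu;
      nrvar[c] = (1 - momentum) * nrvar[c] + momentum * unb;
    } else {
      mu = rmean[c];
      var = rvar[c];
    }
    double invstd = 1.0 / std::sqrt(var + eps);
    smean[c] = mu;
    sinvstd[c] = invstd;
    double g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      const double* plane = xp + (static_cast<size_t>(n) * C + c) * HW;
      double* oplane = yp + (static_cast<size_t>(n) * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) oplane[i] = g * (plane[i] - mu) * invstd + b;
    }
  }
  y.attr("dim") = xd;
  return List::create(Named("y") = y, Named("mean") = smean, Named("invstd") = sinvstd,
                      Named("rmean") = nrmean, Named("rvar") = nrvar);
}

// [[Rcpp::export]]
List cpp_bn_bw(NumericVector x, NumericVector gamma, NumericVector smean,
               NumericVector sinvstd, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t HW = static_cast<size_t>(H) * W;
  double m = static_cast<double>(HW) * N;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (int c = 0; c < C; ++c) {
    double mu = smean[c], invstd = sinvstd[c], g = gamma[c];
    double sdy = 0, sdyx = 0;
    for (int n = 0; n < N; ++n) {
      const double* plane = xp + (static_cast<size_t>(n) * C + c) * HW;
      const double* dplane = dyp + (static_cast<size_t>(n) * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) {
        sdy += dplane[i];
        sdyx += dplane[i] * (plane[i] - mu) * invstd;
      }
    }
    dbeta[c] = sdy;
    dgamma[c] = sdyx;
    double k = g * invstd / m;
    for (int n = 0; n < N; ++n) {
      const double* plane = xp + (static_cast<size_t>(n) * C + c) * HW;
      const double* dplane = dyp + (static_cast<size_t>(n) * C + c) * HW;
      double* oplane = dxp + (static_cast<size_t>(n) * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) {
        double xhat = (plane[i] - mu) * invstd;
        oplane[i] = k * (m * dplane[i] - sdy - xhat * sdyx);
      }
    }
  }
  dx.attr("dim") = xd;
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma, Named("dbeta") = dbeta);
}

// 4-connected component labelling of a binary matrix (iterative flood fill).
// [[Rcpp::export]]
IntegerMatrix cpp_label4(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * H);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % H, pj = p / H;
        const int di[4] = {1, -1, 0, 0};
        const int dj[4] = {0, 0, 1, -1};
        for (int t = 0; t < 4; ++t) {
          int qi = pi + di[t], qj = pj + dj[t];
          if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
          if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * H);
          }
        }
      }
    }
  }
  return lab;
}
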