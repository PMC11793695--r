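// Low-level numerical kernels for the voxel-flow network.
// All image tensors are R arrays with dim (H, W, C, N), column-major.
// Convolution weights have dim (kh, kw, Cin, Cout); flattening the first
// three dims column-major gives the im2col row order used below.

#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;

static inline int conv_out(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static IntegerVector dim4(SEXP a) {
  IntegerVector d = as<IntegerVector>(Rf_getAttrib(a, R_DimSymbol));
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  return d;
}

// Batched im2col, transposed layout: one (Ho*Wo*N) x (C*kh*kw) matrix so
// the innermost output-row loop is contiguous (memcpy-able for stride 1).
static void im2col_all(const double* x, int H, int W, int C, int N,
                       int kh, int kw, int stride, int pad,
                       int Ho, int Wo, arma::mat& colT) {
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)H * W * C * n;
    size_t joff = (size_t)Ho * Wo * n;
    for (int c = 0; c < C; ++c) {
      for (int ikw = 0; ikw < kw; ++ikw) {
        for (int ikh = 0; ikh < kh; ++ikh) {
          int r = ikh + kh * (ikw + kw * c);
          double* dst0 = colT.colptr(r) + joff;
          for (int ow = 0; ow < Wo; ++ow) {
            int iw = ow * stride - pad + ikw;
            double* dst = dst0 + (size_t)Ho * ow;
            if (iw < 0 || iw >= W) {
              std::fill(dst, dst + Ho, 0.0);
              continue;
            }
            const double* xcol = xn + (size_t)H * (iw + (size_t)W * c);
            if (stride == 1) {
              int ih0 = -pad + ikh;             // ih for oh = 0
              int lo = std::max(0, -ih0);       // first valid oh
              int hi = std::min(Ho, H - ih0);   // one past last valid oh
              if (lo > 0) std::fill(dst, dst + std::min(lo, Ho), 0.0);
              if (hi < Ho) std::fill(dst + std::max(hi, 0), dst + Ho, 0.0);
              if (hi > lo)
                std::memcpy(dst + lo, xcol + ih0 + lo,
                            (size_t)(hi - lo) * sizeof(double));
            } else {
              for (int oh = 0; oh < Ho; ++oh) {
                int ih = oh * stride - pad + ikh;
                dst[oh] = (ih >= 0 && ih < H) ? xcol[ih] : 0.0;
              }
            }
          }
        }
      }
    }
  }
}

// scatter-add of the transposed col matrix back into image layout
static void col2im_all(const arma::mat& colT, double* gx, int H, int W,
                       int C, int N, int kh, int kw, int stride, int pad,
                       int Ho, int Wo) {
  for (int n = 0; n < N; ++n) {
    double* gxn = gx + (size_t)H * W * C * n;
    size_t joff = (size_t)Ho * Wo * n;
    for (int c = 0; c < C; ++c) {
      for (int ikw = 0; ikw < kw; ++ikw) {
        for (int ikh = 0; ikh < kh; ++ikh) {
          int r = ikh + kh * (ikw + kw * c);
          const double* src0 = colT.colptr(r) + joff;
          for (int ow = 0; ow < Wo; ++ow) {
            int iw = ow * stride - pad + ikw;
            if (iw < 0 || iw >= W) continue;
            const double* src = src0 + (size_t)Ho * ow;
            double* gcol = gxn + (size_t)H * (iw + (size_t)W * c);
            if (stride == 1) {
              int ih0 = -pad + ikh;
              int lo = std::max(0, -ih0);
              int hi = std::min(Ho, H - ih0);
              for (int oh = lo; oh < hi; ++oh) gcol[ih0 + oh] += src[oh];
            } else {
              for (int oh = 0; oh < Ho; ++oh) {
                int ih = oh * stride - pad + ikh;
                if (ih >= 0 && ih < H) gcol[ih] += src[oh];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  IntegerVector dx = dim4(x), dw = dim4(w);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int kh = dw[0], kw = dw[1], K = dw[3];
  if (dw[2] != C) stop("conv2d: channel mismatch");
  int Ho = conv_out(H, kh, stride, pad), Wo = conv_out(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size < 1");
  NumericVector y(Ho * Wo * K * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, K, N);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, K, false, true);
  arma::mat colT((size_t)Ho * Wo * N, kh * kw * C);
  im2col_all(x.begin(), H, W, C, N, kh, kw, stride, pad, Ho, Wo, colT);
  arma::mat ym = colT * Wm;  // (Ho*Wo*N) x K
  for (int n = 0; n < N; ++n) {
    double* yn = y.begin() + (size_t)Ho * Wo * K * n;
    for (int k = 0; k < K; ++k) {
      const double* src = ym.colptr(k) + (size_t)Ho * Wo * n;
      double* dst = yn + (size_t)Ho * Wo * k;
      double bk = b[k];
      for (int j = 0; j < Ho * Wo; ++j) dst[j] = src[j] + bk;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad) {
  IntegerVector dx = dim4(x), dw = dim4(w), dg = dim4(gy);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int kh = dw[0], kw = dw[1], K = dw[3];
  int Ho = dg[0], Wo = dg[1];
  NumericVector gx(x.size());
  gx.attr("dim") = dx;
  NumericVector gw(w.size());
  gw.attr("dim") = dw;
  NumericVector gb(K);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, K, false, true);
  arma::mat Gw(gw.begin(), kh * kw * C, K, false, true);
  arma::mat colT((size_t)Ho * Wo * N, kh * kw * C);
  im2col_all(x.begin(), H, W, C, N, kh, kw, stride, pad, Ho, Wo, colT);
  arma::mat gymT((size_t)Ho * Wo * N, K);
  for (int n = 0; n < N; ++n) {
    const double* gn = gy.begin() + (size_t)Ho * Wo * K * n;
    for (int k = 0; k < K; ++k) {
      const double* src = gn + (size_t)Ho * Wo * k;
      double* dst = gymT.colptr(k) + (size_t)Ho * Wo * n;
      double acc = 0;
      for (int j = 0; j < Ho * Wo; ++j) {
        dst[j] = src[j];
        acc += src[j];
      }
      gb[k] += acc;
    }
  }
  Gw = colT.t() * gymT;
  arma::mat gcolT = gymT * Wm.t();  // (Ho*Wo*N) x (kh*kw*C)
  col2im_all(gcolT, gx.begin(), H, W, C, N, kh, kw, stride, pad, Ho, Wo);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution forward: adjoint of cpp_conv2d_fwd.
// Weight dim (kh, kw, Cout, Cin); input x has Cin channels, output Cout.
// [[Rcpp::export]]
NumericVector cpp_deconv2d_fwd(NumericVector x, NumericVector w,
                               NumericVector b, int stride, int pad) {
  IntegerVector dx = dim4(x), dw = dim4(w);
  int Ho = dx[0], Wo = dx[1], Cin = dx[2], N = dx[3];
  int kh = dw[0], kw = dw[1], Cout = dw[2];
  if (dw[3] != Cin) stop("deconv2d: channel mismatch");
  int H = (Ho - 1) * stride - 2 * pad + kh;
  int W = (Wo - 1) * stride - 2 * pad + kw;
  if (H < 1 || W < 1) stop("deconv2d: output size < 1");
  NumericVector y(H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cout, Cin, false, true);
  arma::mat xmT((size_t)Ho * Wo * N, Cin);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)Ho * Wo * Cin * n;
    for (int c = 0; c < Cin; ++c)
      std::memcpy(xmT.colptr(c) + (size_t)Ho * Wo * n,
                  xn + (size_t)Ho * Wo * c,
                  (size_t)Ho * Wo * sizeof(double));
  }
  arma::mat gcolT = xmT * Wm.t();  // (Ho*Wo*N) x (kh*kw*Cout)
  col2im_all(gcolT, y.begin(), H, W, Cout, N, kh, kw, stride, pad, Ho, Wo);
  for (int n = 0; n < N; ++n) {
    double* yn = y.begin() + (size_t)H * W * Cout * n;
    for (int c = 0; c < Cout; ++c) {
      double* dst = yn + (size_t)H * W * c;
      for (int j = 0; j < H * W; ++j) dst[j] += b[c];
    }
  }
  return y;
}

// Bilinear resize, half-pixel-center convention, clamp-to-edge.
static inline void src_coord(int o, double scale, int in_n, int& i0, int& i1,
                             double& f) {
  double s = (o + 0.5) * scale - 0.5;
  if (s < 0) s = 0;
  if (s > in_n - 1) s = in_n - 1;
  i0 = (int)std::floor(s);
  i1 = i0 + 1 < in_n ? i0 + 1 : in_n - 1;
  f = s - i0;
}

// [[Rcpp::export]]
NumericVector cpp_resize_fwd(NumericVector x, int Ho, int Wo) {
  IntegerVector dx = dim4(x);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  double sy = (double)H / Ho, sx = (double)W / Wo;
  NumericVector y(Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xn = x.begin() + (size_t)H * W * (c + C * n);
      double* yn = y.begin() + (size_t)Ho * Wo * (c + C * n);
      for (int ow = 0; ow < Wo; ++ow) {
        int w0, w1; double fx;
        src_coord(ow, sx, W, w0, w1, fx);
        for (int oh = 0; oh < Ho; ++oh) {
          int h0, h1; double fy;
          src_coord(oh, sy, H, h0, h1, fy);
          yn[oh + Ho * ow] =
              (1 - fy) * ((1 - fx) * xn[h0 + H * w0] + fx * xn[h0 + H * w1]) +
              fy * ((1 - fx) * xn[h1 + H * w0] + fx * xn[h1 + H * w1]);
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bwd(NumericVector gy, int H, int W) {
  IntegerVector dg = dim4(gy);
  int Ho = dg[0], Wo = dg[1], C = dg[2], N = dg[3];
  double sy = (double)H / Ho, sx = (double)W / Wo;
  NumericVector gx(H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* gxn = gx.begin() + (size_t)H * W * (c + C * n);
      const double* gn = gy.begin() + (size_t)Ho * Wo * (c + C * n);
      for (int ow = 0; ow < Wo; ++ow) {
        int w0, w1; double fx;
        src_coord(ow, sx, W, w0, w1, fx);
        for (int oh = 0; oh < Ho; ++oh) {
          int h0, h1; double fy;
          src_coord(oh, sy, H, h0, h1, fy);
          double g = gn[oh + Ho * ow];
          gxn[h0 + H * w0] += (1 - fy) * (1 - fx) * g;
          gxn[h0 + H * w1] += (1 - fy) * fx * g;
          gxn[h1 + H * w0] += fy * (1 - fx) * g;
          gxn[h1 + H * w1] += fy * fx * g;
        }
      }
    }
  return gx;
}

// Backward warping: out(y, x) = bilinear sample of img at
// (x + flow[,,1,], y + flow[,,2,]) with clamp-to-edge. flow dim (H, W, 2, N).
static inline void warp_coords(double s, int n, int& i0, int& i1, double& f,
                               bool& clamped) {
  clamped = false;
  if (s <= 0) { s = 0; clamped = true; }
  if (s >= n - 1) { s = n - 1; clamped = true; }
  i0 = (int)std::floor(s);
  i1 = i0 + 1 < n ? i0 + 1 : n - 1;
  f = s - i0;
}

// [[Rcpp::export]]
NumericVector cpp_warp_fwd(NumericVector img, NumericVector flow) {
  IntegerVector di = dim4(img), df = dim4(flow);
  int H = di[0], W = di[1], C = di[2], N = di[3];
  if (df[0] != H || df[1] != W || df[2] != 2 || df[3] != N)
    stop("warp: flow must have dim (H, W, 2, N) matching the image");
  NumericVector y(img.size());
  y.attr("dim") = di;
  for (int n = 0; n < N; ++n) {
    const double* fl = flow.begin() + (size_t)H * W * 2 * n;
    for (int x = 0; x < W; ++x)
      for (int yy = 0; yy < H; ++yy) {
        double sx = x + fl[yy + H * x];
        double sy = yy + fl[yy + H * x + H * W];
        int x0, x1, y0, y1; double fx, fy; bool cl;
        warp_coords(sx, W, x0, x1, fx, cl);
        warp_coords(sy, H, y0, y1, fy, cl);
        for (int c = 0; c < C; ++c) {
          const double* im = img.begin() + (size_t)H * W * (c + C * n);
          y[yy + H * (x + W * (c + C * n))] =
              (1 - fy) * ((1 - fx) * im[y0 + H * x0] + fx * im[y0 + H * x1]) +
              fy * ((1 - fx) * im[y1 + H * x0] + fx * im[y1 + H * x1]);
        }
      }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_warp_bwd(NumericVector img, NumericVector flow, NumericVector gy) {
  IntegerVector di = dim4(img);
  int H = di[0], W = di[1], C = di[2], N = di[3];
  NumericVector gimg(img.size());
  gimg.attr("dim") = di;
  NumericVector gflow(flow.size());
  gflow.attr("dim") = flow.attr("dim");
  for (int n = 0; n < N; ++n) {
    const double* fl = flow.begin() + (size_t)H * W * 2 * n;
    double* gf = gflow.begin() + (size_t)H * W * 2 * n;
    for (int x = 0; x < W; ++x)
      for (int yy = 0; yy < H; ++yy) {
        double sx = x + fl[yy + H * x];
        double sy = yy + fl[yy + H * x + H * W];
        int x0, x1, y0, y1; double fx, fy; bool clx, cly;
        warp_coords(sx, W, x0, x1, fx, clx);
        warp_coords(sy, H, y0, y1, fy, cly);
        double gsx = 0, gsy = 0;
        for (int c = 0; c < C; ++c) {
          const double* im = img.begin() + (size_t)H * W * (c + C * n);
          double* gi = gimg.begin() + (size_t)H * W * (c + C * n);
          double g = gy[yy + H * (x + W * (c + C * n))];
          gi[y0 + H * x0] += (1 - fy) * (1 - fx) * g;
          gi[y0 + H * x1] += (1 - fy) * fx * g;
          gi[y1 + H * x0] += fy * (1 - fx) * g;
          gi[y1 + H * x1] += fy * fx * g;
          gsx += g * ((1 - fy) * (im[y0 + H * x1] - im[y0 + H * x0]) +
                      fy * (im[y1 + H * x1] - im[y1 + H * x0]));
          gsy += g * ((1 - fx) * (im[y1 + H * x0] - im[y0 + H * x0]) +
                      fx * (im[y1 + H * x1] - im[y0 + H * x1]));
        }
        if (!clx) gf[yy + H * x] += gsx;
        if (!cly) gf[yy + H * x + H * W] += gsy;
      }
  }
  return List::create(_["gimg"] = gimg, _["gflow"] = gflow);
}
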