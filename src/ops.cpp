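// Low-level numerical kernels for the built-in autodiff engine.
// Tensor layout everywhere: 4-D R arrays with dim = c(H, W, C, N), column-major,
// i.e. element (h, w, c, n) sits at h + H*(w + W*(c + C*n)).

#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// im2col with row order (kh fastest, then kw, then c) to match the memory
// layout of a (kh, kw, Cin, Cout) weight array flattened to (kh*kw*Cin, Cout).
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad_h, int pad_w,
                   int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int row = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int win = wo * stride - pad_w + j;
          for (int ho = 0; ho < Ho; ++ho) {
            int hin = ho * stride - pad_h + i;
            double v = 0.0;
            if (hin >= 0 && hin < H && win >= 0 && win < W)
              v = x[hin + H * (win + W * c)];
            col(row, ho + Ho * wo) = v;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, int H, int W, int C,
                       int kh, int kw, int stride, int pad_h, int pad_w,
                       int Ho, int Wo, double* gx) {
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int row = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int win = wo * stride - pad_w + j;
          if (win < 0 || win >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hin = ho * stride - pad_h + i;
            if (hin < 0 || hin >= H) continue;
            gx[hin + H * (win + W * c)] += col(row, ho + Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad_h, int pad_w) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, kernel expects %d", C, Cin);
  int Ho = out_size(H, kh, stride, pad_h), Wo = out_size(W, kw, stride, pad_w);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  arma::mat col(kh * kw * Cin, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad_h, pad_w, Ho, Wo, col);
    arma::mat Y = col.t() * Wm;  // (Ho*Wo) x Cout
    double* yp = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      double bias = b[co];
      for (int p = 0; p < Ho * Wo; ++p) yp[p + Ho * Wo * co] = Y(p, co) + bias;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad_h, int pad_w) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = out_size(H, kh, stride, pad_h), Wo = out_size(W, kw, stride, pad_w);
  NumericVector gx(x.size()), gw(w.size()), gb(Cout);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  arma::mat gWm(gw.begin(), kh * kw * Cin, Cout, false, true);
  arma::mat col(kh * kw * Cin, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* gyp = gy.begin() + (size_t)n * Ho * Wo * Cout;
    arma::mat gY(const_cast<double*>(gyp), Ho * Wo, Cout, false, true);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad_h, pad_w, Ho, Wo, col);
    gWm += col * gY;
    arma::mat gcol = Wm * gY.t();  // (kh*kw*Cin) x (Ho*Wo)
    col2im_add(gcol, H, W, C, kh, kw, stride, pad_h, pad_w, Ho, Wo,
               gx.begin() + (size_t)n * H * W * C);
    for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(gY.col(co));
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Backward-warp an image stack by a flow field with border-replicate bilinear
// sampling: out(r, c) = img(r + Vy(r,c), c + Vx(r,c)).
// flow has 2 channels: 0 = x (column) displacement, 1 = y (row) displacement.
// [[Rcpp::export]]
NumericVector cpp_warp_fw(NumericVector img, NumericVector flow) {
  IntegerVector id = img.attr("dim"), fd = flow.attr("dim");
  int H = id[0], W = id[1], C = id[2], N = id[3];
  if (fd[0] != H || fd[1] != W || fd[2] != 2 || fd[3] != N)
    stop("warp: flow must be H x W x 2 x N matching the image");
  NumericVector out(img.size());
  out.attr("dim") = id;
  for (int n = 0; n < N; ++n) {
    const double* fp = flow.begin() + (size_t)n * H * W * 2;
    const double* ip = img.begin() + (size_t)n * H * W * C;
    double* op = out.begin() + (size_t)n * H * W * C;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double sx = clampd(w + fp[h + H * (w + W * 0)], 0.0, W - 1.0);
        double sy = clampd(h + fp[h + H * (w + W * 1)], 0.0, H - 1.0);
        int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
        int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
        double ax = sx - x0, ay = sy - y0;
        for (int c = 0; c < C; ++c) {
          const double* icp = ip + (size_t)H * W * c;
          double v00 = icp[y0 + H * x0], v01 = icp[y0 + H * x1];
          double v10 = icp[y1 + H * x0], v11 = icp[y1 + H * x1];
          op[h + H * (w + W * c)] =
            (1 - ay) * ((1 - ax) * v00 + ax * v01) + ay * ((1 - ax) * v10 + ax * v11);
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_warp_bw(NumericVector img, NumericVector flow, NumericVector gout) {
  IntegerVector id = img.attr("dim");
  int H = id[0], W = id[1], C = id[2], N = id[3];
  NumericVector gimg(img.size()), gflow(flow.size());
  gimg.attr("dim") = id;
  gflow.attr("dim") = flow.attr("dim");
  for (int n = 0; n < N; ++n) {
    const double* fp = flow.begin() + (size_t)n * H * W * 2;
    const double* ip = img.begin() + (size_t)n * H * W * C;
    const double* gp = gout.begin() + (size_t)n * H * W * C;
    double* gip = gimg.begin() + (size_t)n * H * W * C;
    double* gfp = gflow.begin() + (size_t)n * H * W * 2;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double rx = w + fp[h + H * (w + W * 0)];
        double ry = h + fp[h + H * (w + W * 1)];
        bool inx = rx > 0.0 && rx < W - 1.0;  // clamp kills the gradient
        bool iny = ry > 0.0 && ry < H - 1.0;
        double sx = clampd(rx, 0.0, W - 1.0), sy = clampd(ry, 0.0, H - 1.0);
        int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
        int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
        double ax = sx - x0, ay = sy - y0;
        double gx_acc = 0.0, gy_acc = 0.0;
        for (int c = 0; c < C; ++c) {
          const double* icp = ip + (size_t)H * W * c;
          double* gicp = gip + (size_t)H * W * c;
          double g = gp[h + H * (w + W * c)];
          double v00 = icp[y0 + H * x0], v01 = icp[y0 + H * x1];
          double v10 = icp[y1 + H * x0], v11 = icp[y1 + H * x1];
          gicp[y0 + H * x0] += g * (1 - ay) * (1 - ax);
          gicp[y0 + H * x1] += g * (1 - ay) * ax;
          gicp[y1 + H * x0] += g * ay * (1 - ax);
          gicp[y1 + H * x1] += g * ay * ax;
          gx_acc += g * ((1 - ay) * (v01 - v00) + ay * (v11 - v10));
          gy_acc += g * ((1 - ax) * (v10 - v00) + ax * (v11 - v01));
        }
        if (inx) gfp[h + H * (w + W * 0)] += gx_acc;
        if (iny) gfp[h + H * (w + W * 1)] += gy_acc;
      }
    }
  }
  return List::create(_["gimg"] = gimg, _["gflow"] = gflow);
}

// Bilinear resize to an arbitrary size (half-pixel centers, border clamp).
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  double sh = (double)H / Ho, sw = (double)W / Wo;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yp = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        double sx = clampd((wo + 0.5) * sw - 0.5, 0.0, W - 1.0);
        int x0 = (int)std::floor(sx), x1 = std::min(x0 + 1, W - 1);
        double ax = sx - x0;
        for (int ho = 0; ho < Ho; ++ho) {
          double sy = clampd((ho + 0.5) * sh - 0.5, 0.0, H - 1.0);
          int y0 = (int)std::floor(sy), y1 = std::min(y0 + 1, H - 1);
          double ay = sy - y0;
          yp[ho + Ho * wo] =
            (1 - ay) * ((1 - ax) * xp[y0 + H * x0] + ax * xp[y0 + H * x1]) +
            ay * ((1 - ax) * xp[y1 + H * x0] + ax * xp[y1 + H * x1]);
        }
      }
    }
  }
  return y;
}

// Adjoint of cpp_resize_bilinear (needed for the 2x decoder upsampling).
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_bw(NumericVector gy, int H, int W) {
  IntegerVector yd = gy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  double sh = (double)H / Ho, sw = (double)W / Wo;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* gyp = gy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* gxp = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        double sx = clampd((wo + 0.5) * sw - 0.5, 0.0, W - 1.0);
        int x0 = (int)std::floor(sx), x1 = std::min(x0 + 1, W - 1);
        double ax = sx - x0;
        for (int ho = 0; ho < Ho; ++ho) {
          double sy = clampd((ho + 0.5) * sh - 0.5, 0.0, H - 1.0);
          int y0 = (int)std::floor(sy), y1 = std::min(y0 + 1, H - 1);
          double ay = sy - y0;
          double g = gyp[ho + Ho * wo];
          gxp[y0 + H * x0] += g * (1 - ay) * (1 - ax);
          gxp[y0 + H * x1] += g * (1 - ay) * ax;
          gxp[y1 + H * x0] += g * ay * (1 - ax);
          gxp[y1 + H * x1] += g * ay * ax;
        }
      }
    }
  }
  return gx;
}

// 2x2 average pooling (used to build multi-scale reconstruction targets).
// [[Rcpp::export]]
NumericVector cpp_avgpool2(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xp = x.begin() + cn * H * W;
    double* yp = y.begin() + cn * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        yp[ho + Ho * wo] = 0.25 * (xp[2 * ho + H * (2 * wo)] + xp[2 * ho + 1 + H * (2 * wo)] +
                                   xp[2 * ho + H * (2 * wo + 1)] + xp[2 * ho + 1 + H * (2 * wo + 1)]);
  }
  return y;
}

// Separable Gaussian filtering with zero padding; self-adjoint because the
// kernel is symmetric, so the same routine backpropagates gradients.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector x, NumericVector k) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int K = k.size(), r = K / 2;
  NumericVector tmp(x.size()), y(x.size());
  y.attr("dim") = xd;
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xp = x.begin() + cn * H * W;
    double* tp = tmp.begin() + cn * H * W;
    double* yp = y.begin() + cn * H * W;
    for (int w = 0; w < W; ++w)  // vertical pass
      for (int h = 0; h < H; ++h) {
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int hh = h + t;
          if (hh >= 0 && hh < H) acc += k[t + r] * xp[hh + H * w];
        }
        tp[h + H * w] = acc;
      }
    for (int w = 0; w < W; ++w)  // horizontal pass
      for (int h = 0; h < H; ++h) {
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int ww = w + t;
          if (ww >= 0 && ww < W) acc += k[t + r] * tp[h + H * ww];
        }
        yp[h + H * w] = acc;
      }
  }
  return y;
}

// Temporal convolution for sequence models: x has dims (D, T, Cin, N) and is
// convolved along T with a length-L kernel (dims (L, Cin, Cout)), 'same'
// zero padding. Implemented as L strided-view GEMMs; D rides along as the
// fast dimension so no im2col materialization is needed.
// [[Rcpp::export]]
NumericVector cpp_tconv_fw(NumericVector x, NumericVector k, NumericVector b) {
  IntegerVector xd = x.attr("dim"), kd = k.attr("dim");
  int D = xd[0], T = xd[1], Cin = xd[2], N = xd[3];
  int L = kd[0], kci = kd[1], Cout = kd[2];
  if (kci != Cin) stop("tconv: channel mismatch");
  int r = (L - 1) / 2;
  NumericVector y((size_t)D * T * Cout * N);
  y.attr("dim") = IntegerVector::create(D, T, Cout, N);
  const double one = 1.0;
  std::vector<double> Kl(Cin * Cout);
  for (int n = 0; n < N; ++n) {
    double* Xp = const_cast<double*>(x.begin()) + (size_t)n * D * T * Cin;
    double* Yp = y.begin() + (size_t)n * D * T * Cout;
    for (int co = 0; co < Cout; ++co)
      std::fill(Yp + (size_t)D * T * co, Yp + (size_t)D * T * (co + 1), b[co]);
    int ld = D * T;
    // T-blocked dgemm with beta = 1: accumulates in place, no temporaries
    const int TB = 16;
    for (int tb = 0; tb < T; tb += TB) {
      int tbe = std::min(T, tb + TB);
      for (int l = 0; l < L; ++l) {
        int sh = l - r;  // source t = dest t + sh
        int t0 = std::max(tb, -sh), t1 = std::min(tbe, T - sh);
        if (t0 >= t1) continue;
        for (int ci = 0; ci < Cin; ++ci)
          for (int co = 0; co < Cout; ++co)
            Kl[ci + Cin * co] = k[l + L * (ci + Cin * co)];
        int m = D * (t1 - t0);
        F77_CALL(dgemm)("N", "N", &m, &Cout, &Cin, &one,
                        Xp + (size_t)D * (t0 + sh), &ld, Kl.data(), &Cin,
                        &one, Yp + (size_t)D * t0, &ld FCONE FCONE);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_tconv_bw(NumericVector x, NumericVector k, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), kd = k.attr("dim");
  int D = xd[0], T = xd[1], Cin = xd[2], N = xd[3];
  int L = kd[0], Cout = kd[2];
  int r = (L - 1) / 2;
  NumericVector gx(x.size()), gk(k.size()), gb(Cout);
  gx.attr("dim") = xd;
  gk.attr("dim") = kd;
  const double one = 1.0;
  std::vector<double> Kl(Cin * Cout), GKl(Cin * Cout);
  for (int n = 0; n < N; ++n) {
    double* Xp = const_cast<double*>(x.begin()) + (size_t)n * D * T * Cin;
    double* GXp = gx.begin() + (size_t)n * D * T * Cin;
    double* GYp = const_cast<double*>(gy.begin()) + (size_t)n * D * T * Cout;
    int ld = D * T;
    for (int co = 0; co < Cout; ++co)
      for (size_t i = 0; i < (size_t)D * T; ++i)
        gb[co] += GYp[i + (size_t)D * T * co];
    const int TB = 16;
    for (int tb = 0; tb < T; tb += TB) {
      int tbe = std::min(T, tb + TB);
      for (int l = 0; l < L; ++l) {
        int sh = l - r;
        int t0 = std::max(tb, -sh), t1 = std::min(tbe, T - sh);
        if (t0 >= t1) continue;
        for (int ci = 0; ci < Cin; ++ci)
          for (int co = 0; co < Cout; ++co)
            Kl[ci + Cin * co] = k[l + L * (ci + Cin * co)];
        int m = D * (t1 - t0);
        // gX += gY * K^T
        F77_CALL(dgemm)("N", "T", &m, &Cin, &Cout, &one,
                        GYp + (size_t)D * t0, &ld, Kl.data(), &Cin,
                        &one, GXp + (size_t)D * (t0 + sh), &ld FCONE FCONE);
        // gK += X^T * gY
        const double zero = 0.0;
        F77_CALL(dgemm)("T", "N", &Cin, &Cout, &m, &one,
                        Xp + (size_t)D * (t0 + sh), &ld,
                        GYp + (size_t)D * t0, &ld,
                        &zero, GKl.data(), &Cin FCONE FCONE);
        for (int ci = 0; ci < Cin; ++ci)
          for (int co = 0; co < Cout; ++co)
            gk[l + L * (ci + Cin * co)] += GKl[ci + Cin * co];
      }
    }
  }
  return List::create(_["gx"] = gx, _["gk"] = gk, _["gb"] = gb);
}
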