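// Core tensor ops for the segmentation networks.
//
// Layout conventions (column-major R arrays):
//   feature maps  x : (H, W, C, N)
//   conv weights  w : (K, K, Cin/groups, Cout)        -- same padding, odd K
//   transposed 2x2 stride-2 weights : (2, 2, Cin, Cout)
// All forward passes have matching backward passes returning gradients with
// identical shapes.  Grouped convolution is computed per (sample, group) via
// im2col + GEMM; im2col is tiled over output pixels to bound memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector make4(int d1, int d2, int d3, int d4) {
  NumericVector v((R_xlen_t)d1 * d2 * d3 * d4);
  v.attr("dim") = IntegerVector::create(d1, d2, d3, d4);
  return v;
}

static IntegerVector make4i(int d1, int d2, int d3, int d4) {
  IntegerVector v((R_xlen_t)d1 * d2 * d3 * d4);
  v.attr("dim") = IntegerVector::create(d1, d2, d3, d4);
  return v;
}

static inline IntegerVector dims_of(const NumericVector& a, int want) {
  IntegerVector d = a.attr("dim");
  if (d.size() != want) stop("expected a %d-d array", want);
  return d;
}

// Fill `cols` (rows = K*K*Cg, ncol = tile width) for output pixels
// [p0, p0+tw) of sample n, group g.  Pixel p maps to (h = p %% H, w = p / H).
static void im2col_tile(const double* x, int H, int W, int C, int n,
                        int c0, int Cg, int K, int pad,
                        int p0, int tw, arma::mat& cols) {
  const double* xs = x + (size_t)n * H * W * C;
  for (int t = 0; t < tw; ++t) {
    int p = p0 + t;
    int w = p / H, h = p % H;
    double* col = cols.colptr(t);
    for (int ci = 0; ci < Cg; ++ci) {
      const double* xc = xs + (size_t)(c0 + ci) * H * W;
      for (int kw = 0; kw < K; ++kw) {
        int ww = w + kw - pad;
        bool wok = (ww >= 0 && ww < W);
        for (int kh = 0; kh < K; ++kh) {
          int hh = h + kh - pad;
          double v = 0.0;
          if (wok && hh >= 0 && hh < H) v = xc[hh + (size_t)ww * H];
          col[kh + K * (kw + K * ci)] = v;
        }
      }
    }
  }
}

// scatter-accumulate of dcols back into padded input gradient
static void col2im_tile(double* dx, int H, int W, int C, int n,
                        int c0, int Cg, int K, int pad,
                        int p0, int tw, const arma::mat& dcols) {
  double* xs = dx + (size_t)n * H * W * C;
  for (int t = 0; t < tw; ++t) {
    int p = p0 + t;
    int w = p / H, h = p % H;
    const double* col = dcols.colptr(t);
    for (int ci = 0; ci < Cg; ++ci) {
      double* xc = xs + (size_t)(c0 + ci) * H * W;
      for (int kw = 0; kw < K; ++kw) {
        int ww = w + kw - pad;
        if (ww < 0 || ww >= W) continue;
        for (int kh = 0; kh < K; ++kh) {
          int hh = h + kh - pad;
          if (hh < 0 || hh >= H) continue;
          xc[hh + (size_t)ww * H] += col[kh + K * (kw + K * ci)];
        }
      }
    }
  }
}

static int tile_width(int rows) {
  int tw = (int)(((size_t)1 << 22) / (size_t)std::max(rows, 1));
  return std::max(256, std::min(tw, 16384));
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w, int groups) {
  IntegerVector xd = dims_of(x, 4), wd = dims_of(w, 4);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int K = wd[0], Cg = wd[2], Cout = wd[3];
  if (wd[1] != K) stop("kernel must be square");
  if (K % 2 == 0) stop("kernel size must be odd");
  if (C % groups != 0 || Cout % groups != 0) stop("groups must divide channels");
  if (Cg != C / groups)
    stop("weight depth %d does not match in_channels/groups = %d", Cg, C / groups);
  int pad = (K - 1) / 2, Cog = Cout / groups, HW = H * W;
  NumericVector y = make4(H, W, Cout, N);
  int rows = K * K * Cg, tw0 = tile_width(rows);
  arma::mat cols(rows, tw0);
  for (int g = 0; g < groups; ++g) {
    // (K*K*Cg) x Cog weight matrix for this group, shared across samples
    arma::mat Wg(const_cast<double*>(&w[0]) + (size_t)g * Cog * rows,
                 rows, Cog, false, true);
    for (int n = 0; n < N; ++n) {
      double* yn = &y[0] + (size_t)n * HW * Cout + (size_t)g * Cog * HW;
      for (int p0 = 0; p0 < HW; p0 += tw0) {
        int twc = std::min(tw0, HW - p0);
        arma::mat ct(cols.memptr(), rows, twc, false, true);
        im2col_tile(&x[0], H, W, C, n, g * Cg, Cg, K, pad, p0, twc, ct);
        arma::mat Yt(yn + p0, twc, Cog, false, true);
        // y slice for channel o is contiguous of length HW; but rows of Yt
        // stride HW apart -> cannot alias; compute then copy
        arma::mat R = ct.t() * Wg; // twc x Cog
        for (int o = 0; o < Cog; ++o)
          std::copy(R.colptr(o), R.colptr(o) + twc, yn + (size_t)o * HW + p0);
      }
    }
  }
  return y;
}

// [[Rcpp::export(rng = false)]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int groups) {
  IntegerVector xd = dims_of(x, 4), wd = dims_of(w, 4), yd = dims_of(dy, 4);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int K = wd[0], Cg = wd[2], Cout = wd[3];
  if (yd[0] != H || yd[1] != W || yd[2] != Cout || yd[3] != N)
    stop("dy shape mismatch");
  int pad = (K - 1) / 2, Cog = Cout / groups, HW = H * W;
  NumericVector dx = make4(H, W, C, N);
  NumericVector dw = make4(K, K, Cg, Cout);
  int rows = K * K * Cg, tw0 = tile_width(rows);
  arma::mat cols(rows, tw0);
  for (int g = 0; g < groups; ++g) {
    arma::mat Wg(const_cast<double*>(&w[0]) + (size_t)g * Cog * rows,
                 rows, Cog, false, true);
    arma::mat dWg(&dw[0] + (size_t)g * Cog * rows, rows, Cog, false, true);
    for (int n = 0; n < N; ++n) {
      const double* dyn = &dy[0] + (size_t)n * HW * Cout + (size_t)g * Cog * HW;
      for (int p0 = 0; p0 < HW; p0 += tw0) {
        int twc = std::min(tw0, HW - p0);
        arma::mat ct(cols.memptr(), rows, twc, false, true);
        im2col_tile(&x[0], H, W, C, n, g * Cg, Cg, K, pad, p0, twc, ct);
        arma::mat dYt(twc, Cog);
        for (int o = 0; o < Cog; ++o)
          std::copy(dyn + (size_t)o * HW + p0, dyn + (size_t)o * HW + p0 + twc,
                    dYt.colptr(o));
        dWg += ct * dYt;               // (rows x twc)(twc x Cog)
        arma::mat dct = Wg * dYt.t();  // rows x twc
        col2im_tile(&dx[0], H, W, C, n, g * Cg, Cg, K, pad, p0, twc, dct);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// 2x2 stride-2 transposed convolution: y[2i+a, 2j+b, o] = b_o +
//   sum_c x[i,j,c] * w[a,b,c,o]
// [[Rcpp::export(rng = false)]]
NumericVector cpp_convtr2_forward(NumericVector x, NumericVector w,
                                  NumericVector bias) {
  IntegerVector xd = dims_of(x, 4), wd = dims_of(w, 4);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ci = wd[2], Co = wd[3];
  if (wd[0] != 2 || wd[1] != 2 || Ci != C) stop("weight shape mismatch");
  if (bias.size() != Co) stop("bias length mismatch");
  int HW = H * W, Ho = 2 * H, Wo = 2 * W;
  NumericVector y = make4(Ho, Wo, Co, N);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(&x[0]) + (size_t)n * HW * C, HW, C,
                false, true);
    for (int a = 0; a < 2; ++a) {
      for (int b = 0; b < 2; ++b) {
        arma::mat Wab(Ci, Co);
        for (int o = 0; o < Co; ++o)
          for (int c = 0; c < Ci; ++c)
            Wab(c, o) = w[a + 2 * (b + 2 * (c + (size_t)Ci * o))];
        arma::mat Yab = X * Wab; // HW x Co
        double* yn = &y[0] + (size_t)n * Ho * Wo * Co;
        for (int o = 0; o < Co; ++o) {
          double* yc = yn + (size_t)o * Ho * Wo;
          const double* src = Yab.colptr(o);
          double bo = bias[o];
          // each output position is written by exactly one (a, b) pass
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              yc[(2 * i + a) + (size_t)(2 * j + b) * Ho] =
                src[i + (size_t)j * H] + bo;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(rng = false)]]
List cpp_convtr2_backward(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = dims_of(x, 4), wd = dims_of(w, 4), yd = dims_of(dy, 4);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ci = wd[2], Co = wd[3];
  if (yd[0] != 2 * H || yd[1] != 2 * W || yd[2] != Co || yd[3] != N)
    stop("dy shape mismatch");
  int HW = H * W, Ho = 2 * H, Wo = 2 * W;
  NumericVector dx = make4(H, W, C, N);
  NumericVector dw = make4(2, 2, Ci, Co);
  NumericVector db(Co);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(&x[0]) + (size_t)n * HW * C, HW, C,
                false, true);
    arma::mat dX(&dx[0] + (size_t)n * HW * C, HW, C, false, true);
    const double* dyn = &dy[0] + (size_t)n * Ho * Wo * Co;
    for (int a = 0; a < 2; ++a) {
      for (int b = 0; b < 2; ++b) {
        arma::mat dYab(HW, Co);
        for (int o = 0; o < Co; ++o) {
          const double* dyc = dyn + (size_t)o * Ho * Wo;
          double* dst = dYab.colptr(o);
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              dst[i + (size_t)j * H] = dyc[(2 * i + a) + (size_t)(2 * j + b) * Ho];
        }
        arma::mat Wab(Ci, Co);
        for (int o = 0; o < Co; ++o)
          for (int c = 0; c < Ci; ++c)
            Wab(c, o) = w[a + 2 * (b + 2 * (c + (size_t)Ci * o))];
        dX += dYab * Wab.t();
        arma::mat dWab = X.t() * dYab; // Ci x Co
        for (int o = 0; o < Co; ++o)
          for (int c = 0; c < Ci; ++c)
            dw[a + 2 * (b + 2 * (c + (size_t)Ci * o))] += dWab(c, o);
      }
    }
    for (int o = 0; o < Co; ++o) {
      const double* dyc = dyn + (size_t)o * Ho * Wo;
      double s = 0.0;
      for (int p = 0; p < Ho * Wo; ++p) s += dyc[p];
      db[o] += s;
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(rng = false)]]
List cpp_maxpool2_forward(NumericVector x) {
  IntegerVector xd = dims_of(x, 4);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 != 0 || W % 2 != 0) stop("spatial dims must be even for 2x2 pooling");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y = make4(Ho, Wo, C, N);
  IntegerVector idx = make4i(Ho, Wo, C, N); // 0-based linear index into x
  size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = &x[0] + ((size_t)n * C + c) * H * W;
      size_t base = ((size_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          int h0 = 2 * i, w0 = 2 * j;
          size_t best = h0 + (size_t)w0 * H;
          double bv = xc[best];
          int cand_h[3] = {h0 + 1, h0, h0 + 1};
          int cand_w[3] = {w0, w0 + 1, w0 + 1};
          for (int t = 0; t < 3; ++t) {
            size_t li = cand_h[t] + (size_t)cand_w[t] * H;
            if (xc[li] > bv) { bv = xc[li]; best = li; }
          }
          y[q] = bv;
          idx[q] = (int)(base + best);
          ++q;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_maxpool2_backward(NumericVector dy, IntegerVector idx,
                                    IntegerVector xdim) {
  NumericVector dx = make4(xdim[0], xdim[1], xdim[2], xdim[3]);
  for (R_xlen_t p = 0; p < dy.size(); ++p) dx[idx[p]] += dy[p];
  return dx;
}

// Batch normalization over (H, W, N) per channel.
// [[Rcpp::export(rng = false)]]
List cpp_bn_forward(NumericVector x, NumericVector gamma, NumericVector beta,
                    NumericVector use_mean, NumericVector use_var, double eps,
                    bool training) {
  IntegerVector xd = dims_of(x, 4);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int HW = H * W;
  double m = (double)HW * N;
  NumericVector y = make4(H, W, C, N);
  NumericVector mean(C), var(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* xc = &x[0] + ((size_t)n * C + c) * HW;
        for (int p = 0; p < HW; ++p) { s += xc[p]; s2 += xc[p] * xc[p]; }
      }
      mean[c] = s / m;
      var[c] = s2 / m - mean[c] * mean[c];
      if (var[c] < 0) var[c] = 0;
    }
  } else {
    mean = clone(use_mean);
    var = clone(use_var);
  }
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(var[c] + eps);
    double g = gamma[c], b = beta[c], mu = mean[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = &x[0] + ((size_t)n * C + c) * HW;
      double* yc = &y[0] + ((size_t)n * C + c) * HW;
      for (int p = 0; p < HW; ++p) yc[p] = g * (xc[p] - mu) * inv + b;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export(rng = false)]]
List cpp_bn_backward(NumericVector x, NumericVector dy, NumericVector gamma,
                     NumericVector mean, NumericVector var, double eps,
                     bool training) {
  IntegerVector xd = dims_of(x, 4);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int HW = H * W;
  double m = (double)HW * N;
  NumericVector dx = make4(H, W, C, N);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(var[c] + eps);
    double mu = mean[c], g = gamma[c];
    double sd_ = 0.0, sdx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = &x[0] + ((size_t)n * C + c) * HW;
      const double* dc = &dy[0] + ((size_t)n * C + c) * HW;
      for (int p = 0; p < HW; ++p) {
        sd_ += dc[p];
        sdx += dc[p] * (xc[p] - mu) * inv;
      }
    }
    dbeta[c] = sd_;
    dgamma[c] = sdx;
    if (training) {
      // batch statistics depend on x
      for (int n = 0; n < N; ++n) {
        const double* xc = &x[0] + ((size_t)n * C + c) * HW;
        const double* dc = &dy[0] + ((size_t)n * C + c) * HW;
        double* dxc = &dx[0] + ((size_t)n * C + c) * HW;
        for (int p = 0; p < HW; ++p) {
          double xhat = (xc[p] - mu) * inv;
          dxc[p] = g * inv / m * (m * dc[p] - sd_ - xhat * sdx);
        }
      }
    } else {
      for (int n = 0; n < N; ++n) {
        const double* dc = &dy[0] + ((size_t)n * C + c) * HW;
        double* dxc = &dx[0] + ((size_t)n * C + c) * HW;
        for (int p = 0; p < HW; ++p) dxc[p] = g * inv * dc[p];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
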