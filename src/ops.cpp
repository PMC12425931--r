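// Low-level numerical kernels for the network.
//
// Activation tensors are stored "folded": a (H*W*N) x C numeric matrix whose
// row index is r = h + H*w + H*W*n (h fastest, image index n slowest), so each
// column holds N stacked H x W images, column-major. This keeps channel-wise
// operations (1x1 convs, batch norm, softmax) as plain matrix algebra on the
// R side and lets the spatial kernels below walk contiguous memory.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---- depthwise convolution (same zero padding, odd kernel) ----------------

// w: (k*k) x C, element (ki + k*kj, c)
// [[Rcpp::export]]
NumericMatrix cpp_dwconv_fwd(const NumericMatrix& x, const NumericMatrix& w,
                             int H, int W, int N, int k) {
  const int C = x.ncol();
  const int HW = H * W;
  const int p = (k - 1) / 2;
  NumericMatrix y(x.nrow(), C);
  for (int c = 0; c < C; ++c) {
    const double* __restrict xc = &x(0, c);
    const double* __restrict wc = &w(0, c);
    double* __restrict yc = &y(0, c);
    for (int n = 0; n < N; ++n) {
      const double* __restrict xn = xc + (size_t)n * HW;
      double* __restrict yn = yc + (size_t)n * HW;
      for (int j = 0; j < W; ++j) {
        double* __restrict ycol = yn + (size_t)H * j;
        for (int kj = 0; kj < k; ++kj) {
          const int jc = j + kj - p;
          if (jc < 0 || jc >= W) continue;
          const double* __restrict xcol = xn + (size_t)H * jc;
          for (int ki = 0; ki < k; ++ki) {
            const double wv = wc[ki + k * kj];
            const int off = ki - p;
            const int h0 = off < 0 ? -off : 0;
            const int h1 = off > 0 ? H - off : H;
            const double* __restrict xs = xcol + off;
            for (int h = h0; h < h1; ++h) ycol[h] += wv * xs[h];
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv_bwd(const NumericMatrix& x, const NumericMatrix& w,
                    const NumericMatrix& gy, int H, int W, int N, int k) {
  const int C = x.ncol();
  const int HW = H * W;
  const int p = (k - 1) / 2;
  NumericMatrix gx(x.nrow(), C);
  NumericMatrix gw(k * k, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    const double* gyc = &gy(0, c);
    const double* wc = &w(0, c);
    double* gxc = &gx(0, c);
    double* gwc = &gw(0, c);
    for (int n = 0; n < N; ++n) {
      const double* xn = xc + (size_t)n * HW;
      const double* gn = gyc + (size_t)n * HW;
      double* gxn = gxc + (size_t)n * HW;
      for (int j = 0; j < W; ++j) {
        const double* gcol = gn + (size_t)H * j;
        for (int kj = 0; kj < k; ++kj) {
          const int jc = j + kj - p;
          if (jc < 0 || jc >= W) continue;
          const double* xcol = xn + (size_t)H * jc;
          double* gxcol = gxn + (size_t)H * jc;
          for (int ki = 0; ki < k; ++ki) {
            const int off = ki - p;
            const int h0 = std::max(0, -off);
            const int h1 = std::min(H, H - off);
            const double wv = wc[ki + k * kj];
            double acc = 0.0;
            for (int h = h0; h < h1; ++h) {
              const double g = gcol[h];
              acc += xcol[h + off] * g;
              gxcol[h + off] += wv * g;
            }
            gwc[ki + k * kj] += acc;
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// ---- im2col / col2im for standard (optionally dilated) convolution --------

// cols: (H*W*N) x (C*k*k); patch column index q = ki + k*kj + k*k*c, matching
// an R weight array of dim c(k, k, C_in, C_out) flattened to a matrix.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& x, int H, int W, int N,
                         int k, int dil) {
  const int C = x.ncol();
  const int HW = H * W;
  const int p = dil * (k - 1) / 2;
  NumericMatrix cols((size_t)HW * N, C * k * k);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double* col = &cols(0, ki + k * kj + k * k * c);
        const int oi = ki * dil - p;
        const int oj = kj * dil - p;
        for (int n = 0; n < N; ++n) {
          const double* xn = xc + (size_t)n * HW;
          double* cn = col + (size_t)n * HW;
          for (int j = 0; j < W; ++j) {
            const int jc = j + oj;
            if (jc < 0 || jc >= W) continue;
            const int h0 = std::max(0, -oi);
            const int h1 = std::min(H, H - oi);
            const double* xcol = xn + (size_t)H * jc + oi;
            double* ccol = cn + (size_t)H * j;
            for (int h = h0; h < h1; ++h) ccol[h] = xcol[h];
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& gcols, int H, int W, int N,
                         int C, int k, int dil) {
  const int HW = H * W;
  const int p = dil * (k - 1) / 2;
  NumericMatrix gx((size_t)HW * N, C);
  for (int c = 0; c < C; ++c) {
    double* gxc = &gx(0, c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double* col = &gcols(0, ki + k * kj + k * k * c);
        const int oi = ki * dil - p;
        const int oj = kj * dil - p;
        for (int n = 0; n < N; ++n) {
          const double* cn = col + (size_t)n * HW;
          double* gxn = gxc + (size_t)n * HW;
          for (int j = 0; j < W; ++j) {
            const int jc = j + oj;
            if (jc < 0 || jc >= W) continue;
            const int h0 = std::max(0, -oi);
            const int h1 = std::min(H, H - oi);
            double* gxcol = gxn + (size_t)H * jc + oi;
            const double* ccol = cn + (size_t)H * j;
            for (int h = h0; h < h1; ++h) gxcol[h] += ccol[h];
          }
        }
      }
    }
  }
  return gx;
}

// ---- 2x2 max pooling (stride 2) -------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool2_fwd(const NumericMatrix& x, int H, int W, int N) {
  const int C = x.ncol();
  const int Ho = H / 2, Wo = W / 2;
  const int HW = H * W, HWo = Ho * Wo;
  NumericMatrix y((size_t)HWo * N, C);
  IntegerMatrix idx((size_t)HWo * N, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    double* yc = &y(0, c);
    int* ic = &idx(0, c);
    for (int n = 0; n < N; ++n) {
      const double* xn = xc + (size_t)n * HW;
      double* yn = yc + (size_t)n * HWo;
      int* in = ic + (size_t)n * HWo;
      for (int j = 0; j < Wo; ++j) {
        for (int h = 0; h < Ho; ++h) {
          int best = 2 * h + H * (2 * j);
          double bv = xn[best];
          const int cand[3] = {2 * h + 1 + H * (2 * j),
                               2 * h + H * (2 * j + 1),
                               2 * h + 1 + H * (2 * j + 1)};
          for (int t = 0; t < 3; ++t)
            if (xn[cand[t]] > bv) { bv = xn[cand[t]]; best = cand[t]; }
          yn[h + Ho * j] = bv;
          in[h + Ho * j] = best + n * HW;  // row index in the input matrix
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool2_bwd(const NumericMatrix& gy, const IntegerMatrix& idx,
                               int nrow_in) {
  const int C = gy.ncol();
  NumericMatrix gx(nrow_in, C);
  for (int c = 0; c < C; ++c) {
    const double* g = &gy(0, c);
    const int* ic = &idx(0, c);
    double* gxc = &gx(0, c);
    const int n = gy.nrow();
    for (int r = 0; r < n; ++r) gxc[ic[r]] += g[r];
  }
  return gx;
}

// ---- 2x bilinear upsampling (half-pixel centres, clamped edges) -----------

static inline void bilin_coef(int out, int in, std::vector<int>& i0,
                              std::vector<int>& i1, std::vector<double>& a) {
  i0.resize(out); i1.resize(out); a.resize(out);
  const double scale = (double)in / out;
  for (int i = 0; i < out; ++i) {
    double src = (i + 0.5) * scale - 0.5;
    if (src < 0) src = 0;
    if (src > in - 1) src = in - 1;
    int lo = (int)std::floor(src);
    int hi = std::min(lo + 1, in - 1);
    i0[i] = lo; i1[i] = hi; a[i] = src - lo;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_upsample2_fwd(const NumericMatrix& x, int H, int W, int N) {
  const int C = x.ncol();
  const int Ho = 2 * H, Wo = 2 * W;
  const int HW = H * W, HWo = Ho * Wo;
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> ra, ca;
  bilin_coef(Ho, H, r0, r1, ra);
  bilin_coef(Wo, W, c0, c1, ca);
  NumericMatrix y((size_t)HWo * N, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    double* yc = &y(0, c);
    for (int n = 0; n < N; ++n) {
      const double* xn = xc + (size_t)n * HW;
      double* yn = yc + (size_t)n * HWo;
      for (int j = 0; j < Wo; ++j) {
        const double* xl = xn + (size_t)H * c0[j];
        const double* xr = xn + (size_t)H * c1[j];
        const double b = ca[j];
        double* ycol = yn + (size_t)Ho * j;
        for (int i = 0; i < Ho; ++i) {
          const double a = ra[i];
          ycol[i] = (1 - a) * ((1 - b) * xl[r0[i]] + b * xr[r0[i]]) +
                    a * ((1 - b) * xl[r1[i]] + b * xr[r1[i]]);
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_upsample2_bwd(const NumericMatrix& gy, int H, int W, int N) {
  const int C = gy.ncol();
  const int Ho = 2 * H, Wo = 2 * W;
  const int HW = H * W, HWo = Ho * Wo;
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> ra, ca;
  bilin_coef(Ho, H, r0, r1, ra);
  bilin_coef(Wo, W, c0, c1, ca);
  NumericMatrix gx((size_t)HW * N, C);
  for (int c = 0; c < C; ++c) {
    const double* gc = &gy(0, c);
    double* gxc = &gx(0, c);
    for (int n = 0; n < N; ++n) {
      const double* gn = gc + (size_t)n * HWo;
      double* gxn = gxc + (size_t)n * HW;
      for (int j = 0; j < Wo; ++j) {
        double* xl = gxn + (size_t)H * c0[j];
        double* xr = gxn + (size_t)H * c1[j];
        const double b = ca[j];
        const double* gcol = gn + (size_t)Ho * j;
        for (int i = 0; i < Ho; ++i) {
          const double a = ra[i];
          const double g = gcol[i];
          xl[r0[i]] += (1 - a) * (1 - b) * g;
          xr[r0[i]] += (1 - a) * b * g;
          xl[r1[i]] += a * (1 - b) * g;
          xr[r1[i]] += a * b * g;
        }
      }
    }
  }
  return gx;
}

// ---- row-wise softmax (over channels, numerically stabilised) -------------

// [[Rcpp::export]]
NumericMatrix cpp_row_softmax(const NumericMatrix& x) {
  // column-sweep implementation (cache-friendly for tall matrices)
  const int n = x.nrow(), C = x.ncol();
  NumericMatrix y(n, C);
  std::vector<double> mx(n), s(n, 0.0);
  {
    const double* __restrict x0 = &x(0, 0);
    for (int r = 0; r < n; ++r) mx[r] = x0[r];
  }
  for (int c = 1; c < C; ++c) {
    const double* __restrict xc = &x(0, c);
    for (int r = 0; r < n; ++r) if (xc[r] > mx[r]) mx[r] = xc[r];
  }
  for (int c = 0; c < C; ++c) {
    const double* __restrict xc = &x(0, c);
    double* __restrict yc = &y(0, c);
    for (int r = 0; r < n; ++r) { const double e = std::exp(xc[r] - mx[r]); yc[r] = e; s[r] += e; }
  }
  for (int r = 0; r < n; ++r) s[r] = 1.0 / s[r];
  for (int c = 0; c < C; ++c) {
    double* __restrict yc = &y(0, c);
    for (int r = 0; r < n; ++r) yc[r] *= s[r];
  }
  return y;
}

// concatenate matrices with equal row counts along columns
// [[Rcpp::export]]
NumericMatrix cpp_cbind_all(const List& mats) {
  int C = 0; int n = 0;
  for (int i = 0; i < mats.size(); ++i) {
    NumericMatrix m = mats[i];
    n = m.nrow(); C += m.ncol();
  }
  NumericMatrix y(n, C);
  int off = 0;
  for (int i = 0; i < mats.size(); ++i) {
    NumericMatrix m = mats[i];
    std::copy(m.begin(), m.end(), y.begin() + (size_t)n * off);
    off += m.ncol();
  }
  return y;
}

// [[Rcpp::export]]
List cpp_row_max(const NumericMatrix& x) {
  const int n = x.nrow(), C = x.ncol();
  NumericVector v(n);
  IntegerVector idx(n);
  for (int r = 0; r < n; ++r) {
    double mx = x(r, 0); int mi = 0;
    for (int c = 1; c < C; ++c) if (x(r, c) > mx) { mx = x(r, c); mi = c; }
    v[r] = mx; idx[r] = mi + 1;
  }
  return List::create(_["value"] = v, _["idx"] = idx);
}

// ---- per-(image, channel) broadcast helpers -------------------------------

// y(r, c) = x(r, c) * z(n(r), c), z is N x C
// [[Rcpp::export]]
NumericMatrix cpp_nc_scale(const NumericMatrix& x, const NumericMatrix& z,
                           int HW, int N) {
  const int C = x.ncol();
  NumericMatrix y(x.nrow(), C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    double* yc = &y(0, c);
    for (int n = 0; n < N; ++n) {
      const double f = z(n, c);
      const double* xn = xc + (size_t)n * HW;
      double* yn = yc + (size_t)n * HW;
      for (int r = 0; r < HW; ++r) yn[r] = f * xn[r];
    }
  }
  return y;
}

// out(n, c) = sum_hw a(r, c) * b(r, c)
// [[Rcpp::export]]
NumericMatrix cpp_nc_dot(const NumericMatrix& a, const NumericMatrix& b,
                         int HW, int N) {
  const int C = a.ncol();
  NumericMatrix out(N, C);
  for (int c = 0; c < C; ++c) {
    const double* ac = &a(0, c);
    const double* bc = &b(0, c);
    for (int n = 0; n < N; ++n) {
      const double* an = ac + (size_t)n * HW;
      const double* bn = bc + (size_t)n * HW;
      double s = 0.0;
      for (int r = 0; r < HW; ++r) s += an[r] * bn[r];
      out(n, c) = s;
    }
  }
  return out;
}

// y(r, c) = x(r, c) + z(n(r), c)
// [[Rcpp::export]]
NumericMatrix cpp_nc_add(const NumericMatrix& x, const NumericMatrix& z,
                         int HW, int N) {
  const int C = x.ncol();
  NumericMatrix y(x.nrow(), C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    double* yc = &y(0, c);
    for (int n = 0; n < N; ++n) {
      const double f = z(n, c);
      const double* xn = xc + (size_t)n * HW;
      double* yn = yc + (size_t)n * HW;
      for (int r = 0; r < HW; ++r) yn[r] = xn[r] + f;
    }
  }
  return y;
}

// ---- single-image resizing (data pipeline) --------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(const NumericMatrix& x, int oh, int ow) {
  const int H = x.nrow(), W = x.ncol();
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> ra, ca;
  bilin_coef(oh, H, r0, r1, ra);
  bilin_coef(ow, W, c0, c1, ca);
  NumericMatrix y(oh, ow);
  for (int j = 0; j < ow; ++j) {
    const double b = ca[j];
    for (int i = 0; i < oh; ++i) {
      const double a = ra[i];
      y(i, j) = (1 - a) * ((1 - b) * x(r0[i], c0[j]) + b * x(r0[i], c1[j])) +
                a * ((1 - b) * x(r1[i], c0[j]) + b * x(r1[i], c1[j]));
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_nearest(const NumericMatrix& x, int oh, int ow) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix y(oh, ow);
  for (int j = 0; j < ow; ++j) {
    int sj = (int)std::floor((j + 0.5) * (double)W / ow);
    if (sj > W - 1) sj = W - 1;
    for (int i = 0; i < oh; ++i) {
      int si = (int)std::floor((i + 0.5) * (double)H / oh);
      if (si > H - 1) si = H - 1;
      y(i, j) = x(si, sj);
    }
  }
  return y;
}

// ---- separable Gaussian blur (clamped edges; phantom generator) -----------

// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(const NumericMatrix& x, double sigma) {
  const int H = x.nrow(), W = x.ncol();
  if (sigma <= 0) return clone(x);
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * rad + 1);
  double s = 0.0;
  for (int t = -rad; t <= rad; ++t) {
    ker[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + rad];
  }
  for (double& v : ker) v /= s;
  NumericMatrix tmp(H, W), y(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int t = -rad; t <= rad; ++t) {
        int ii = std::min(H - 1, std::max(0, i + t));
        acc += ker[t + rad] * x(ii, j);
      }
      tmp(i, j) = acc;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int t = -rad; t <= rad; ++t) {
        int jj = std::min(W - 1, std::max(0, j + t));
        acc += ker[t + rad] * tmp(i, jj);
      }
      y(i, j) = acc;
    }
  return y;
}

// ---- fused elementwise helpers (hot paths) --------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_relu_fwd(const NumericMatrix& x) {
  NumericMatrix y(x.nrow(), x.ncol());
  const double* xp = x.begin(); double* yp = y.begin();
  const size_t n = (size_t)x.nrow() * x.ncol();
  for (size_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_relu_bwd(const NumericMatrix& g, const NumericMatrix& y) {
  NumericMatrix gx(g.nrow(), g.ncol());
  const double* gp = g.begin(); const double* yp = y.begin(); double* op = gx.begin();
  const size_t n = (size_t)g.nrow() * g.ncol();
  for (size_t i = 0; i < n; ++i) op[i] = yp[i] > 0 ? gp[i] : 0.0;
  return gx;
}

// y(r, c) = x(r, c) * v[c]
// [[Rcpp::export]]
NumericMatrix cpp_col_scale(const NumericMatrix& x, const NumericVector& v) {
  const int C = x.ncol(), n = x.nrow();
  NumericMatrix y(n, C);
  for (int c = 0; c < C; ++c) {
    const double f = v[c];
    const double* xc = &x(0, c); double* yc = &y(0, c);
    for (int r = 0; r < n; ++r) yc[r] = f * xc[r];
  }
  return y;
}

// y(r, c) = x(r, c) * a[c] + b[c]
// [[Rcpp::export]]
NumericMatrix cpp_col_affine(const NumericMatrix& x, const NumericVector& a,
                             const NumericVector& b) {
  const int C = x.ncol(), n = x.nrow();
  NumericMatrix y(n, C);
  for (int c = 0; c < C; ++c) {
    const double f = a[c], o = b[c];
    const double* xc = &x(0, c); double* yc = &y(0, c);
    for (int r = 0; r < n; ++r) yc[r] = f * xc[r] + o;
  }
  return y;
}

// colSums(a * b) in one pass
// [[Rcpp::export]]
NumericVector cpp_colsums_prod(const NumericMatrix& a, const NumericMatrix& b) {
  const int C = a.ncol(), n = a.nrow();
  NumericVector out(C);
  for (int c = 0; c < C; ++c) {
    const double* ac = &a(0, c); const double* bc = &b(0, c);
    double s = 0.0;
    for (int r = 0; r < n; ++r) s += ac[r] * bc[r];
    out[c] = s;
  }
  return out;
}

// batch-norm training forward: xhat = (x - mu) * invstd; y = xhat * g + b
// [[Rcpp::export]]
List cpp_bn_fwd(const NumericMatrix& x, const NumericVector& mu,
                const NumericVector& invstd, const NumericVector& gamma,
                const NumericVector& beta) {
  const int C = x.ncol(), n = x.nrow();
  NumericMatrix xhat(n, C), y(n, C);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], s = invstd[c], g = gamma[c], b = beta[c];
    const double* xc = &x(0, c);
    double* hc = &xhat(0, c); double* yc = &y(0, c);
    for (int r = 0; r < n; ++r) {
      const double h = (xc[r] - m) * s;
      hc[r] = h;
      yc[r] = g * h + b;
    }
  }
  return List::create(_["xhat"] = xhat, _["y"] = y);
}

// batch-norm backward: gx = coef[c] * (n*g - sg[c] - xhat*sgx[c]);
// also returns sg = colSums(g), sgx = colSums(g * xhat)
// [[Rcpp::export]]
List cpp_bn_bwd(const NumericMatrix& g, const NumericMatrix& xhat,
                const NumericVector& gamma, const NumericVector& invstd) {
  const int C = g.ncol(), n = g.nrow();
  NumericVector sg(C), sgx(C);
  NumericMatrix gx(n, C);
  for (int c = 0; c < C; ++c) {
    const double* gc = &g(0, c); const double* hc = &xhat(0, c);
    double a = 0.0, b = 0.0;
    for (int r = 0; r < n; ++r) { a += gc[r]; b += gc[r] * hc[r]; }
    sg[c] = a; sgx[c] = b;
    const double coef = gamma[c] * invstd[c] / n;
    double* oc = &gx(0, c);
    for (int r = 0; r < n; ++r) oc[r] = coef * (n * gc[r] - a - hc[r] * b);
  }
  return List::create(_["gx"] = gx, _["sg"] = sg, _["sgx"] = sgx);
}

// softmax backward: gx = s * (g - rowSums(g * s))
// [[Rcpp::export]]
NumericMatrix cpp_softmax_bwd(const NumericMatrix& s, const NumericMatrix& g) {
  const int C = s.ncol(), n = s.nrow();
  std::vector<double> rs(n, 0.0);
  for (int c = 0; c < C; ++c) {
    const double* sc = &s(0, c); const double* gc = &g(0, c);
    for (int r = 0; r < n; ++r) rs[r] += sc[r] * gc[r];
  }
  NumericMatrix gx(n, C);
  for (int c = 0; c < C; ++c) {
    const double* sc = &s(0, c); const double* gc = &g(0, c);
    double* oc = &gx(0, c);
    for (int r = 0; r < n; ++r) oc[r] = sc[r] * (gc[r] - rs[r]);
  }
  return gx;
}

// gather-style depthwise backward: gx as correlation of gy with the flipped
// kernel, gw accumulated in the same sweep over output positions.
// [[Rcpp::export]]
List cpp_dwconv_bwd2(const NumericMatrix& x, const NumericMatrix& w,
                     const NumericMatrix& gy, int H, int W, int N, int k) {
  const int C = x.ncol();
  const int HW = H * W;
  const int p = (k - 1) / 2;
  NumericMatrix gx(x.nrow(), C);
  NumericMatrix gw(k * k, C);
  for (int c = 0; c < C; ++c) {
    const double* __restrict xc = &x(0, c);
    const double* __restrict gyc = &gy(0, c);
    const double* __restrict wc = &w(0, c);
    double* __restrict gxc = &gx(0, c);
    double* __restrict gwc = &gw(0, c);
    for (int n = 0; n < N; ++n) {
      const double* __restrict xn = xc + (size_t)n * HW;
      const double* __restrict gn = gyc + (size_t)n * HW;
      double* __restrict gxn = gxc + (size_t)n * HW;
      // gx(i, j) = sum_k w(ki, kj) * gy(i - ki + p, j - kj + p)
      for (int j = 0; j < W; ++j) {
        double* __restrict gxcol = gxn + (size_t)H * j;
        for (int kj = 0; kj < k; ++kj) {
          const int jg = j - kj + p;
          if (jg < 0 || jg >= W) continue;
          const double* __restrict gcol = gn + (size_t)H * jg;
          for (int ki = 0; ki < k; ++ki) {
            const double wv = wc[ki + k * kj];
            const int off = p - ki;
            const int h0 = off < 0 ? -off : 0;
            const int h1 = off > 0 ? H - off : H;
            const double* __restrict gs = gcol + off;
            for (int h = h0; h < h1; ++h) gxcol[h] += wv * gs[h];
          }
        }
        // gw(ki, kj) += sum_i x(i + ki - p, j + kj - p) * gy(i, j)
        const double* __restrict gycol = gn + (size_t)H * j;
        for (int kj = 0; kj < k; ++kj) {
          const int jc2 = j + kj - p;
          if (jc2 < 0 || jc2 >= W) continue;
          const double* __restrict xcol = xn + (size_t)H * jc2;
          for (int ki = 0; ki < k; ++ki) {
            const int off = ki - p;
            const int h0 = off < 0 ? -off : 0;
            const int h1 = off > 0 ? H - off : H;
            const double* __restrict xs = xcol + off;
            double acc = 0.0;
            for (int h = h0; h < h1; ++h) acc += xs[h] * gycol[h];
            gwc[ki + k * kj] += acc;
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// y(r, c) = x(r, c) + b[c]
// [[Rcpp::export]]
NumericMatrix cpp_col_add(const NumericMatrix& x, const NumericVector& b) {
  const int C = x.ncol(), n = x.nrow();
  NumericMatrix y(n, C);
  for (int c = 0; c < C; ++c) {
    const double o = b[c];
    const double* xc = &x(0, c); double* yc = &y(0, c);
    for (int r = 0; r < n; ++r) yc[r] = xc[r] + o;
  }
  return y;
}


// ---- fused batch-norm + ReLU ----------------------------------------------

// [[Rcpp::export]]
List cpp_bnrelu_fwd(const NumericMatrix& x, const NumericVector& mu,
                    const NumericVector& invstd, const NumericVector& gamma,
                    const NumericVector& beta) {
  const int C = x.ncol(), n = x.nrow();
  NumericMatrix xhat(n, C), y(n, C);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], s = invstd[c], g = gamma[c], b = beta[c];
    const double* __restrict xc = &x(0, c);
    double* __restrict hc = &xhat(0, c);
    double* __restrict yc = &y(0, c);
    for (int r = 0; r < n; ++r) {
      const double h = (xc[r] - m) * s;
      hc[r] = h;
      const double v = g * h + b;
      yc[r] = v > 0 ? v : 0.0;
    }
  }
  return List::create(_["xhat"] = xhat, _["y"] = y);
}

// backward through ReLU (mask recomputed from xhat) then batch norm
// [[Rcpp::export]]
List cpp_bnrelu_bwd(const NumericMatrix& g0, const NumericMatrix& xhat,
                    const NumericVector& gamma, const NumericVector& beta,
                    const NumericVector& invstd) {
  const int C = g0.ncol(), n = g0.nrow();
  NumericVector sg(C), sgx(C);
  NumericMatrix gx(n, C);
  for (int c = 0; c < C; ++c) {
    const double* __restrict gc = &g0(0, c);
    const double* __restrict hc = &xhat(0, c);
    const double gam = gamma[c], bet = beta[c];
    double* __restrict oc = &gx(0, c);
    double a = 0.0, b = 0.0;
    for (int r = 0; r < n; ++r) {
      const double g = (gam * hc[r] + bet) > 0 ? gc[r] : 0.0;
      oc[r] = g;  // stash masked gradient
      a += g;
      b += g * hc[r];
    }
    sg[c] = a; sgx[c] = b;
    const double coef = gamma[c] * invstd[c] / n;
    for (int r = 0; r < n; ++r) oc[r] = coef * (n * oc[r] - a - hc[r] * b);
  }
  return List::create(_["gx"] = gx, _["sg"] = sg, _["sgx"] = sgx);
}

// eval-mode affine + optional ReLU
// [[Rcpp::export]]
NumericMatrix cpp_col_affine_relu(const NumericMatrix& x, const NumericVector& a,
                                  const NumericVector& b) {
  const int C = x.ncol(), n = x.nrow();
  NumericMatrix y(n, C);
  for (int c = 0; c < C; ++c) {
    const double f = a[c], o = b[c];
    const double* __restrict xc = &x(0, c);
    double* __restrict yc = &y(0, c);
    for (int r = 0; r < n; ++r) {
      const double v = f * xc[r] + o;
      yc[r] = v > 0 ? v : 0.0;
    }
  }
  return y;
}

// ---- allocator tuning ------------------------------------------------------
// Large activation matrices (tens of MB) are allocated and freed every
// layer; with glibc's defaults each one is a fresh mmap/munmap pair and the
// kernel page-fault cost dominates. Raising the thresholds keeps the blocks
// on the heap for reuse.
#ifdef __GLIBC__
#include <malloc.h>
#endif

// [[Rcpp::export]]
void cpp_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 1024 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
#endif
}
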