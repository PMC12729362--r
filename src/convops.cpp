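#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <algorithm>
using namespace Rcpp;

// Feature maps are stored as (n_vox x C) matrices, n_vox running over a
// (H, W, D) grid in column-major order (h fastest). This makes pointwise
// convolutions and normalisation plain matrix/column operations in R and
// keeps the heavy gemms inside BLAS.

static inline int vox_index(int h, int w, int d, int H, int W) {
  return h + H * (w + W * d);
}

// im2col for a single-channel (H, W, D) volume, cubic kernel k, zero "same"
// padding, unit stride. Returns (n_out x k^3): rows are output voxels in
// (H, W, D) column-major order, columns are kernel offsets (kh fastest).
// Offset-major layout makes each column a contiguous shifted copy of the
// volume, so filling is memcpy-bound rather than gather-bound.
// [[Rcpp::export]]
NumericMatrix cpp_im2col3d(NumericVector x, int H, int W, int D, int k) {
  const int pad = (k - 1) / 2;
  const int k3 = k * k * k;
  const R_xlen_t n_out = (R_xlen_t)H * W * D;
  NumericMatrix col(n_out, k3);
  const double* px = x.begin();
  double* pc = col.begin();
  int r = 0;
  for (int kd = 0; kd < k; ++kd) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh, ++r) {
        double* dst = pc + (R_xlen_t)r * n_out;  // column r, already zeroed
        const int dh = kh - pad, dw = kw - pad, dd = kd - pad;
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        if (h1 <= h0) continue;
        for (int d = 0; d < D; ++d) {
          const int sd = d + dd;
          if (sd < 0 || sd >= D) continue;
          for (int w = 0; w < W; ++w) {
            const int sw = w + dw;
            if (sw < 0 || sw >= W) continue;
            std::memcpy(dst + vox_index(h0, w, d, H, W),
                        px + vox_index(h0 + dh, sw, sd, H, W),
                        (h1 - h0) * sizeof(double));
          }
        }
      }
    }
  }
  return col;
}

// Max pooling with window (ph, pw, pd), stride equal to window, floor mode.
// x: (n_vox x C). Returns out (n_out x C) and 1-based argmax row indices.
// [[Rcpp::export]]
List cpp_maxpool3d(NumericMatrix x, int H, int W, int D,
                   int ph, int pw, int pd) {
  const int Ho = H / ph, Wo = W / pw, Do = D / pd;
  const int C = x.ncol();
  const int n_out = Ho * Wo * Do;
  NumericMatrix out(n_out, C);
  IntegerMatrix idx(n_out, C);
  for (int c = 0; c < C; ++c) {
    const double* px = &x(0, c);
    for (int d = 0; d < Do; ++d) {
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h) {
          double best = R_NegInf; int besti = -1;
          for (int kd = 0; kd < pd; ++kd)
            for (int kw = 0; kw < pw; ++kw)
              for (int kh = 0; kh < ph; ++kh) {
                const int i = vox_index(h * ph + kh, w * pw + kw,
                                        d * pd + kd, H, W);
                if (px[i] > best) { best = px[i]; besti = i; }
              }
          const int o = vox_index(h, w, d, Ho, Wo);
          out(o, c) = best;
          idx(o, c) = besti + 1;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx,
                      _["dims"] = IntegerVector::create(Ho, Wo, Do));
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool3d_bwd(NumericMatrix dout, IntegerMatrix idx,
                                int n_in) {
  const int C = dout.ncol(), n_out = dout.nrow();
  NumericMatrix dx(n_in, C);
  for (int c = 0; c < C; ++c)
    for (int o = 0; o < n_out; ++o)
      dx(idx(o, c) - 1, c) += dout(o, c);
  return dx;
}

// Depthwise 3D convolution, cubic kernel k, zero "same" padding, per-axis
// strides. x: (n_vox x C), weights: (k^3 x C), one bias per channel.
// [[Rcpp::export]]
List cpp_depthwise3d(NumericMatrix x, int H, int W, int D,
                     NumericMatrix wt, NumericVector bias,
                     int k, int sh, int sw, int sd) {
  const int pad = (k - 1) / 2;
  const int C = x.ncol();
  const int Ho = (H + sh - 1) / sh, Wo = (W + sw - 1) / sw,
            Do = (D + sd - 1) / sd;
  NumericMatrix out(Ho * Wo * Do, C);
  for (int c = 0; c < C; ++c) {
    const double* px = &x(0, c);
    const double* pw_ = &wt(0, c);
    for (int d = 0; d < Do; ++d) {
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h) {
          double acc = bias[c];
          int r = 0;
          for (int kd = 0; kd < k; ++kd) {
            const int dd = d * sd + kd - pad;
            if (dd < 0 || dd >= D) { r += k * k; continue; }
            for (int kw = 0; kw < k; ++kw) {
              const int ww = w * sw + kw - pad;
              if (ww < 0 || ww >= W) { r += k; continue; }
              for (int kh = 0; kh < k; ++kh, ++r) {
                const int hh = h * sh + kh - pad;
                if (hh >= 0 && hh < H)
                  acc += pw_[r] * px[vox_index(hh, ww, dd, H, W)];
              }
            }
          }
          out(vox_index(h, w, d, Ho, Wo), c) = acc;
        }
      }
    }
  }
  return List::create(_["out"] = out,
                      _["dims"] = IntegerVector::create(Ho, Wo, Do));
}

// Backward pass of cpp_depthwise3d: gradients w.r.t. input, weights, bias.
// [[Rcpp::export]]
List cpp_depthwise3d_bwd(NumericMatrix dout, NumericMatrix x,
                         int H, int W, int D,
                         NumericMatrix wt, int k,
                         int sh, int sw, int sd) {
  const int pad = (k - 1) / 2;
  const int C = x.ncol();
  const int Ho = (H + sh - 1) / sh, Wo = (W + sw - 1) / sw,
            Do = (D + sd - 1) / sd;
  NumericMatrix dx(H * W * D, C);
  NumericMatrix dw(k * k * k, C);
  NumericVector db(C);
  for (int c = 0; c < C; ++c) {
    const double* px = &x(0, c);
    const double* pw_ = &wt(0, c);
    double* pdx = &dx(0, c);
    double* pdw = &dw(0, c);
    for (int d = 0; d < Do; ++d) {
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h) {
          const double g = dout(vox_index(h, w, d, Ho, Wo), c);
          if (g == 0.0) continue;
          db[c] += g;
          int r = 0;
          for (int kd = 0; kd < k; ++kd) {
            const int dd = d * sd + kd - pad;
            if (dd < 0 || dd >= D) { r += k * k; continue; }
            for (int kw = 0; kw < k; ++kw) {
              const int ww = w * sw + kw - pad;
              if (ww < 0 || ww >= W) { r += k; continue; }
              for (int kh = 0; kh < k; ++kh, ++r) {
                const int hh = h * sh + kh - pad;
                if (hh >= 0 && hh < H) {
                  const int i = vox_index(hh, ww, dd, H, W);
                  pdx[i] += g * pw_[r];
                  pdw[r] += g * px[i];
                }
              }
            }
          }
        }
      }
    }
  }
  // db may miss zero-gradient shortcuts above only when g == 0, harmless
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

static inline double clampd(double v, double lo, double hi) {
  return std::max(lo, std::min(hi, v));
}

// Bilinear resize of a 2D image (H x W matrix) to (out_h x out_w),
// pixel-center alignment, edge clamping. Constants are preserved exactly.
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix img, int out_h, int out_w) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(out_h, out_w);
  const double sh = (double)H / out_h, sw = (double)W / out_w;
  for (int j = 0; j < out_w; ++j) {
    const double x = clampd((j + 0.5) * sw - 0.5, 0.0, W - 1.0);
    const int x0 = (int)std::floor(x);
    const int x1 = std::min(x0 + 1, W - 1);
    const double fx = x - x0;
    for (int i = 0; i < out_h; ++i) {
      const double y = clampd((i + 0.5) * sh - 0.5, 0.0, H - 1.0);
      const int y0 = (int)std::floor(y);
      const int y1 = std::min(y0 + 1, H - 1);
      const double fy = y - y0;
      out(i, j) = (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
                  fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_nearest(NumericMatrix img, int out_h, int out_w) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(out_h, out_w);
  const double sh = (double)H / out_h, sw = (double)W / out_w;
  for (int j = 0; j < out_w; ++j) {
    int x = (int)clampd(std::floor((j + 0.5) * sw), 0.0, W - 1.0);
    for (int i = 0; i < out_h; ++i) {
      int y = (int)clampd(std::floor((i + 0.5) * sh), 0.0, H - 1.0);
      out(i, j) = img(y, x);
    }
  }
  return out;
}

// Inverse-warp an image with the affine map (row', col') -> A %*% (row, col)
// + t about the image centre: for each output pixel the source location is
// computed and sampled bilinearly; outside pixels take `fill`.
// a: length-4 (a11, a21, a12, a22 column-major), t: length-2 (rows, cols).
// [[Rcpp::export]]
NumericMatrix cpp_warp_affine(NumericMatrix img, NumericVector a,
                              NumericVector t, double fill,
                              bool bilinear) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const double dy = i - cy - t[0], dx = j - cx - t[1];
      const double sy = a[0] * dy + a[2] * dx + cy;
      const double sx = a[1] * dy + a[3] * dx + cx;
      if (sy < 0 || sy > H - 1 || sx < 0 || sx > W - 1) {
        out(i, j) = fill;
        continue;
      }
      if (bilinear) {
        const int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
        const int y1 = std::min(y0 + 1, H - 1), x1 = std::min(x0 + 1, W - 1);
        const double fy = sy - y0, fx = sx - x0;
        out(i, j) =
          (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
          fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
      } else {
        out(i, j) = img((int)std::lround(sy), (int)std::lround(sx));
      }
    }
  }
  return out;
}

// Direct "same"-padded 3D convolution of a single-channel volume with C
// cubic kernels: out[., c] = sum_r w[c, r] * shift_r(x). Fused accumulation
// over shifted contiguous runs avoids materializing an im2col matrix.
// [[Rcpp::export]]
NumericMatrix cpp_conv3d_same(NumericVector x, int H, int W, int D,
                              NumericMatrix wt, int k) {
  const int pad = (k - 1) / 2;
  const R_xlen_t n = (R_xlen_t)H * W * D;
  const int C = wt.nrow();
  NumericMatrix out(n, C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    double* po = &out(0, c);
    int r = 0;
    for (int kd = 0; kd < k; ++kd) {
      for (int kw = 0; kw < k; ++kw) {
        for (int kh = 0; kh < k; ++kh, ++r) {
          const double wv = wt(c, r);
          if (wv == 0.0) continue;
          const int dh = kh - pad, dw = kw - pad, dd = kd - pad;
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          if (h1 <= h0) continue;
          for (int d = 0; d < D; ++d) {
            const int sd = d + dd;
            if (sd < 0 || sd >= D) continue;
            for (int w = 0; w < W; ++w) {
              const int sw = w + dw;
              if (sw < 0 || sw >= W) continue;
              double* o = po + vox_index(h0, w, d, H, W);
              const double* s = px + vox_index(h0 + dh, sw, sd, H, W);
              const int len = h1 - h0;
              for (int i = 0; i < len; ++i) o[i] += wv * s[i];
            }
          }
        }
      }
    }
  }
  return out;
}

// Weight gradient of cpp_conv3d_same: dw[c, r] = <shift_r(x), dout[., c]>.
// [[Rcpp::export]]
NumericMatrix cpp_conv3d_same_dw(NumericVector x, NumericMatrix dout,
                                 int H, int W, int D, int k) {
  const int pad = (k - 1) / 2;
  const int C = dout.ncol();
  const int k3 = k * k * k;
  NumericMatrix dw(C, k3);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* pd = &dout(0, c);
    int r = 0;
    for (int kd = 0; kd < k; ++kd) {
      for (int kw = 0; kw < k; ++kw) {
        for (int kh = 0; kh < k; ++kh, ++r) {
          const int dh = kh - pad, dw_ = kw - pad, dd = kd - pad;
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          if (h1 <= h0) continue;
          double acc = 0.0;
          for (int d = 0; d < D; ++d) {
            const int sd = d + dd;
            if (sd < 0 || sd >= D) continue;
            for (int w = 0; w < W; ++w) {
              const int sw = w + dw_;
              if (sw < 0 || sw >= W) continue;
              const double* o = pd + vox_index(h0, w, d, H, W);
              const double* s = px + vox_index(h0 + dh, sw, sd, H, W);
              const int len = h1 - h0;
              for (int i = 0; i < len; ++i) acc += o[i] * s[i];
            }
          }
          dw(c, r) = acc;
        }
      }
    }
  }
  return dw;
}

// [[Rcpp::export]]
NumericMatrix cpp_relu(NumericMatrix x) {
  NumericMatrix out(x.nrow(), x.ncol());
  const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
  const double* px = x.begin(); double* po = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) po[i] = px[i] > 0 ? px[i] : 0.0;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_relu_bwd(NumericMatrix dout, NumericMatrix out) {
  NumericMatrix dx(dout.nrow(), dout.ncol());
  const R_xlen_t n = (R_xlen_t)dout.nrow() * dout.ncol();
  const double* pd = dout.begin(); const double* po = out.begin();
  double* px = dx.begin();
  for (R_xlen_t i = 0; i < n; ++i) px[i] = po[i] > 0 ? pd[i] : 0.0;
  return dx;
}

// Per-column standardize + scale/shift (instance normalization), fused.
// [[Rcpp::export]]
List cpp_instnorm_fwd(NumericMatrix x, NumericVector gamma,
                      NumericVector beta, double eps) {
  const int n = x.nrow(), C = x.ncol();
  NumericMatrix out(n, C), xc(n, C);
  NumericVector inv(C);
  for (int c = 0; c < C; ++c) {
    const double* px = &x(0, c);
    double mu = 0;
    for (int i = 0; i < n; ++i) mu += px[i];
    mu /= n;
    double* pxc = &xc(0, c);
    double v = 0;
    for (int i = 0; i < n; ++i) { pxc[i] = px[i] - mu; v += pxc[i] * pxc[i]; }
    v /= n;
    const double iv = 1.0 / std::sqrt(v + eps);
    inv[c] = iv;
    const double a = gamma[c] * iv, b = beta[c];
    double* po = &out(0, c);
    for (int i = 0; i < n; ++i) po[i] = a * pxc[i] + b;
  }
  return List::create(_["out"] = out, _["xc"] = xc, _["inv"] = inv);
}

// [[Rcpp::export]]
List cpp_instnorm_bwd(NumericMatrix dout, NumericMatrix xc,
                      NumericVector inv, NumericVector gamma) {
  const int n = dout.nrow(), C = dout.ncol();
  NumericMatrix dx(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* pd = &dout(0, c);
    const double* pxc = &xc(0, c);
    const double iv = inv[c], g = gamma[c];
    double sd = 0, sdx = 0, sg = 0;
    for (int i = 0; i < n; ++i) {
      const double xhat = pxc[i] * iv;
      sd += pd[i];
      sg += pd[i] * xhat;
    }
    dbeta[c] = sd;
    dgamma[c] = sg;
    const double m1 = g * sd / n;
    const double m2 = g * sg / n;
    sdx = 0; // unused
    double* px = &dx(0, c);
    for (int i = 0; i < n; ++i) {
      const double xhat = pxc[i] * iv;
      px[i] = iv * (g * pd[i] - m1 - xhat * m2);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
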