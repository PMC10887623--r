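#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear lookup on an image stored column-major (H x W), physical frame:
// pixel (i, j) (0-based) sits at x = (j - (W-1)/2) * px, y = (i - (H-1)/2) * px.
static inline double sample_image(const double* img, int H, int W, double px,
                                  double x, double y) {
  double cj = x / px + (W - 1) * 0.5;
  double ci = y / px + (H - 1) * 0.5;
  int j0 = (int)std::floor(cj), i0 = (int)std::floor(ci);
  double fj = cj - j0, fi = ci - i0;
  double v = 0.0;
  for (int di = 0; di <= 1; ++di) {
    int ii = i0 + di;
    if (ii < 0 || ii >= H) continue;
    double wi = di ? fi : 1.0 - fi;
    for (int dj = 0; dj <= 1; ++dj) {
      int jj = j0 + dj;
      if (jj < 0 || jj >= W) continue;
      double wj = dj ? fj : 1.0 - fj;
      v += wi * wj * img[ii + (size_t)jj * H];
    }
  }
  return v;
}

static inline void splat_image(double* img, int H, int W, double px,
                               double x, double y, double val) {
  double cj = x / px + (W - 1) * 0.5;
  double ci = y / px + (H - 1) * 0.5;
  int j0 = (int)std::floor(cj), i0 = (int)std::floor(ci);
  double fj = cj - j0, fi = ci - i0;
  for (int di = 0; di <= 1; ++di) {
    int ii = i0 + di;
    if (ii < 0 || ii >= H) continue;
    double wi = di ? fi : 1.0 - fi;
    for (int dj = 0; dj <= 1; ++dj) {
      int jj = j0 + dj;
      if (jj < 0 || jj >= W) continue;
      double wj = dj ? fj : 1.0 - fj;
      img[ii + (size_t)jj * H] += wi * wj * val;
    }
  }
}

// Fan-beam forward projection by ray marching. betas: source angles (rad);
// det_s: physical detector-channel offsets on the detector line (at distance
// dsd from the source). Returns n_views x n_det matrix of line integrals.
// [[Rcpp::export]]
NumericMatrix fan_project_cpp(NumericMatrix image, double pixel_size,
                              NumericVector betas, NumericVector det_s,
                              double dso, double dsd, double step) {
  int H = image.nrow(), W = image.ncol();
  int nv = betas.size(), nd = det_s.size();
  NumericMatrix out(nv, nd);
  double R = 0.5 * pixel_size * std::sqrt((double)H * H + (double)W * W) + pixel_size;
  const double* img = image.begin();
  for (int v = 0; v < nv; ++v) {
    double cb = std::cos(betas[v]), sb = std::sin(betas[v]);
    double sx = dso * cb, sy = dso * sb;
    for (int d = 0; d < nd; ++d) {
      // detector element position: behind iso along -(cb,sb), offset along (-sb,cb)
      double ex = sx - dsd * cb - det_s[d] * sb;
      double ey = sy - dsd * sb + det_s[d] * cb;
      double ux = ex - sx, uy = ey - sy;
      double len = std::sqrt(ux * ux + uy * uy);
      ux /= len; uy /= len;
      // march only across the image-support disk around the origin
      double t0 = dso - R, t1 = dso + R;
      int n = (int)std::ceil((t1 - t0) / step);
      double acc = 0.0;
      for (int k = 0; k < n; ++k) {
        double t = t0 + (k + 0.5) * step;
        acc += sample_image(img, H, W, pixel_size, sx + t * ux, sy + t * uy);
      }
      out(v, d) = acc * step;
    }
  }
  return out;
}

// Exact adjoint of fan_project_cpp (same sampling pattern, gather -> scatter).
// [[Rcpp::export]]
NumericMatrix fan_backproject_adj_cpp(NumericMatrix sino, int H, int W,
                                      double pixel_size, NumericVector betas,
                                      NumericVector det_s, double dso,
                                      double dsd, double step) {
  int nv = betas.size(), nd = det_s.size();
  NumericMatrix out(H, W);
  double R = 0.5 * pixel_size * std::sqrt((double)H * H + (double)W * W) + pixel_size;
  double* img = out.begin();
  for (int v = 0; v < nv; ++v) {
    double cb = std::cos(betas[v]), sb = std::sin(betas[v]);
    double sx = dso * cb, sy = dso * sb;
    for (int d = 0; d < nd; ++d) {
      double val = sino(v, d) * step;
      if (val == 0.0) continue;
      double ex = sx - dsd * cb - det_s[d] * sb;
      double ey = sy - dsd * sb + det_s[d] * cb;
      double ux = ex - sx, uy = ey - sy;
      double len = std::sqrt(ux * ux + uy * uy);
      ux /= len; uy /= len;
      double t0 = dso - R, t1 = dso + R;
      int n = (int)std::ceil((t1 - t0) / step);
      for (int k = 0; k < n; ++k) {
        double t = t0 + (k + 0.5) * step;
        splat_image(img, H, W, pixel_size, sx + t * ux, sy + t * uy, val);
      }
    }
  }
  return out;
}

// Weighted fan-beam backprojection of a ramp-filtered sinogram given on the
// virtual detector through the isocenter (coordinates s_iso, uniform spacing).
// out value(x,y) = (dbeta/2) * sum_v interp(filt[v, ], s(x,y)) / U^2.
// [[Rcpp::export]]
NumericMatrix fan_fbp_backproject_cpp(NumericMatrix filt, NumericVector betas,
                                      NumericVector s_iso, double dso,
                                      int out_size, double pixel_size) {
  int nv = betas.size(), nd = s_iso.size();
  double s0 = s_iso[0], ds = (nd > 1) ? (s_iso[1] - s_iso[0]) : 1.0;
  NumericMatrix out(out_size, out_size);
  double dbeta = 2.0 * M_PI / nv;
  std::vector<double> cbv(nv), sbv(nv);
  for (int v = 0; v < nv; ++v) { cbv[v] = std::cos(betas[v]); sbv[v] = std::sin(betas[v]); }
  for (int j = 0; j < out_size; ++j) {
    double x = (j - (out_size - 1) * 0.5) * pixel_size;
    for (int i = 0; i < out_size; ++i) {
      double y = (i - (out_size - 1) * 0.5) * pixel_size;
      double acc = 0.0;
      for (int v = 0; v < nv; ++v) {
        double d = dso - (x * cbv[v] + y * sbv[v]);
        if (d <= 1e-9) continue;
        double e = -x * sbv[v] + y * cbv[v];
        double s = e * dso / d;
        double c = (s - s0) / ds;
        int c0 = (int)std::floor(c);
        if (c0 < 0 || c0 >= nd - 1) continue;
        double f = c - c0;
        double p = (1.0 - f) * filt(v, c0) + f * filt(v, c0 + 1);
        double U = d / dso;
        acc += p / (U * U);
      }
      out(i, j) = acc * dbeta * 0.5;
    }
  }
  return out;
}

// im2col for an (H x W x C) column-major array already padded.
// Row index of cols: a = ((c*kh) + ki)*kw + kj (0-based); column: ho + wo*Ho.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector xpad, int H, int W, int C,
                         int kh, int kw, int stride) {
  int Ho = (H - kh) / stride + 1;
  int Wo = (W - kw) / stride + 1;
  NumericMatrix cols(C * kh * kw, Ho * Wo);
  const double* x = xpad.begin();
  double* cl = cols.begin();
  int nrow = C * kh * kw;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      size_t ncol = (size_t)ho + (size_t)wo * Ho;
      double* dst = cl + ncol * nrow;
      int i0 = ho * stride, j0 = wo * stride;
      for (int c = 0; c < C; ++c) {
        const double* plane = x + (size_t)c * H * W;
        for (int ki = 0; ki < kh; ++ki) {
          const double* src = plane + (i0 + ki) + (size_t)j0 * H;
          for (int kj = 0; kj < kw; ++kj) {
            dst[((size_t)c * kh + ki) * kw + kj] = src[(size_t)kj * H];
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col_cpp: scatter-add columns back into an (H x W x C) array.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int kh, int kw, int stride) {
  int Ho = (H - kh) / stride + 1;
  int Wo = (W - kw) / stride + 1;
  NumericVector out((size_t)H * W * C);
  double* x = out.begin();
  const double* cl = cols.begin();
  int nrow = C * kh * kw;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      size_t ncol = (size_t)ho + (size_t)wo * Ho;
      const double* src = cl + ncol * nrow;
      int i0 = ho * stride, j0 = wo * stride;
      for (int c = 0; c < C; ++c) {
        double* plane = x + (size_t)c * H * W;
        for (int ki = 0; ki < kh; ++ki) {
          double* dst = plane + (i0 + ki) + (size_t)j0 * H;
          for (int kj = 0; kj < kw; ++kj) {
            dst[(size_t)kj * H] += src[((size_t)c * kh + ki) * kw + kj];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}
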