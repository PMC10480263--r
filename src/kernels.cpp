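#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Feature maps are R arrays dim c(H, W, C), column-major.
// Weights are arrays dim c(kh, kw, Cin, Cout).

static inline int dim3(const NumericVector& x, int k) {
  IntegerVector d = x.attr("dim");
  return d[k];
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                           int stride, int pad) {
  const int H = dim3(x, 0), W = dim3(x, 1), Ci = dim3(x, 2);
  const int kh = dim3(w, 0), kw = dim3(w, 1), Co = dim3(w, 3);
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector y(Ho * Wo * Co);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  for (int co = 0; co < Co; ++co) {
    const double bc = b[co];
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        double acc = bc;
        for (int ci = 0; ci < Ci; ++ci) {
          for (int kj = 0; kj < kw; ++kj) {
            const int jj = jo * stride + kj - pad;
            if (jj < 0 || jj >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int ii = io * stride + ki - pad;
              if (ii < 0 || ii >= H) continue;
              acc += xp[ii + H * (jj + W * ci)] *
                     wp[ki + kh * (kj + kw * (ci + Ci * co))];
            }
          }
        }
        yp[io + Ho * (jo + Wo * co)] = acc;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                  int stride, int pad) {
  const int H = dim3(x, 0), W = dim3(x, 1), Ci = dim3(x, 2);
  const int kh = dim3(w, 0), kw = dim3(w, 1), Co = dim3(w, 3);
  const int Ho = dim3(dy, 0), Wo = dim3(dy, 1);
  NumericVector dx(H * W * Ci), dw(kh * kw * Ci * Co), db(Co);
  dx.attr("dim") = IntegerVector::create(H, W, Ci);
  dw.attr("dim") = IntegerVector::create(kh, kw, Ci, Co);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  double* dwp = dw.begin();
  for (int co = 0; co < Co; ++co) {
    double bacc = 0.0;
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const double g = dyp[io + Ho * (jo + Wo * co)];
        if (g == 0.0) continue;
        bacc += g;
        for (int ci = 0; ci < Ci; ++ci) {
          for (int kj = 0; kj < kw; ++kj) {
            const int jj = jo * stride + kj - pad;
            if (jj < 0 || jj >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int ii = io * stride + ki - pad;
              if (ii < 0 || ii >= H) continue;
              const int xi = ii + H * (jj + W * ci);
              const int wi = ki + kh * (kj + kw * (ci + Ci * co));
              dxp[xi] += g * wp[wi];
              dwp[wi] += g * xp[xi];
            }
          }
        }
      }
    }
    // bias gradient must include zero-gradient positions too; recompute exactly
    db[co] = 0.0;
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io)
        db[co] += dyp[io + Ho * (jo + Wo * co)];
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector cpp_tconv_fwd(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  const int H = dim3(x, 0), W = dim3(x, 1), Ci = dim3(x, 2);
  const int kh = dim3(w, 0), kw = dim3(w, 1), Co = dim3(w, 3);
  const int Ho = (H - 1) * stride + kh - 2 * pad;
  const int Wo = (W - 1) * stride + kw - 2 * pad;
  NumericVector y(Ho * Wo * Co);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  for (int co = 0; co < Co; ++co) {
    for (int k = 0; k < Ho * Wo; ++k) yp[k + Ho * Wo * co] = b[co];
    for (int ci = 0; ci < Ci; ++ci) {
      for (int jj = 0; jj < W; ++jj) {
        for (int ii = 0; ii < H; ++ii) {
          const double xv = xp[ii + H * (jj + W * ci)];
          if (xv == 0.0) continue;
          for (int kj = 0; kj < kw; ++kj) {
            const int oj = jj * stride + kj - pad;
            if (oj < 0 || oj >= Wo) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int oi = ii * stride + ki - pad;
              if (oi < 0 || oi >= Ho) continue;
              yp[oi + Ho * (oj + Wo * co)] +=
                xv * wp[ki + kh * (kj + kw * (ci + Ci * co))];
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_tconv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, int pad) {
  const int H = dim3(x, 0), W = dim3(x, 1), Ci = dim3(x, 2);
  const int kh = dim3(w, 0), kw = dim3(w, 1), Co = dim3(w, 3);
  const int Ho = dim3(dy, 0), Wo = dim3(dy, 1);
  NumericVector dx(H * W * Ci), dw(kh * kw * Ci * Co), db(Co);
  dx.attr("dim") = IntegerVector::create(H, W, Ci);
  dw.attr("dim") = IntegerVector::create(kh, kw, Ci, Co);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  double* dwp = dw.begin();
  for (int co = 0; co < Co; ++co) {
    double bacc = 0.0;
    for (int k = 0; k < Ho * Wo; ++k) bacc += dyp[k + Ho * Wo * co];
    db[co] = bacc;
    for (int ci = 0; ci < Ci; ++ci) {
      for (int jj = 0; jj < W; ++jj) {
        for (int ii = 0; ii < H; ++ii) {
          const int xi = ii + H * (jj + W * ci);
          const double xv = xp[xi];
          double dacc = 0.0;
          for (int kj = 0; kj < kw; ++kj) {
            const int oj = jj * stride + kj - pad;
            if (oj < 0 || oj >= Wo) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int oi = ii * stride + ki - pad;
              if (oi < 0 || oi >= Ho) continue;
              const double g = dyp[oi + Ho * (oj + Wo * co)];
              const int wi = ki + kh * (kj + kw * (ci + Ci * co));
              dacc += g * wp[wi];
              dwp[wi] += g * xv;
            }
          }
          dxp[xi] += dacc;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

static inline double bilin(const double* img, int H, int W, double r, double c,
                           bool zero_outside) {
  if (zero_outside) {
    if (r < -1.0 || r > (double)H || c < -1.0 || c > (double)W) return 0.0;
  }
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  double fr = r - r0, fc = c - c0;
  int r1 = r0 + 1, c1 = c0 + 1;
  double v00, v01, v10, v11;
  if (zero_outside) {
    v00 = (r0 >= 0 && r0 < H && c0 >= 0 && c0 < W) ? img[r0 + H * c0] : 0.0;
    v10 = (r1 >= 0 && r1 < H && c0 >= 0 && c0 < W) ? img[r1 + H * c0] : 0.0;
    v01 = (r0 >= 0 && r0 < H && c1 >= 0 && c1 < W) ? img[r0 + H * c1] : 0.0;
    v11 = (r1 >= 0 && r1 < H && c1 >= 0 && c1 < W) ? img[r1 + H * c1] : 0.0;
  } else {
    int rr0 = std::min(std::max(r0, 0), H - 1);
    int rr1 = std::min(std::max(r1, 0), H - 1);
    int cc0 = std::min(std::max(c0, 0), W - 1);
    int cc1 = std::min(std::max(c1, 0), W - 1);
    v00 = img[rr0 + H * cc0];
    v10 = img[rr1 + H * cc0];
    v01 = img[rr0 + H * cc1];
    v11 = img[rr1 + H * cc1];
  }
  return (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11);
}

// Sample img (H x W matrix) at fractional 0-based (rows, cols).
// mode "clamp": edge-clamped; mode "zero": zero outside.
// [[Rcpp::export]]
NumericVector cpp_bilinear_sample(NumericMatrix img, NumericVector rows,
                                  NumericVector cols, std::string mode) {
  const int H = img.nrow(), W = img.ncol();
  const bool zero_outside = (mode == "zero");
  const int n = rows.size();
  NumericVector out(n);
  const double* ip = img.begin();
  for (int k = 0; k < n; ++k)
    out[k] = bilin(ip, H, W, rows[k], cols[k], zero_outside);
  return out;
}

// Parallel-beam radon transform. Angles in degrees; bins centred on the
// image centre ((H-1)/2, (W-1)/2); integration step 1 px, bilinear, zero
// outside the image. Returns n_angles x n_bins.
// [[Rcpp::export]]
NumericMatrix cpp_radon(NumericMatrix img, NumericVector angles_deg, int n_bins) {
  const int H = img.nrow(), W = img.ncol(), A = angles_deg.size();
  const double rc = (H - 1) / 2.0, cc = (W - 1) / 2.0;
  const double half = (n_bins - 1) / 2.0;
  NumericMatrix sino(A, n_bins);
  const double* ip = img.begin();
  for (int a = 0; a < A; ++a) {
    const double th = angles_deg[a] * M_PI / 180.0;
    const double ct = std::cos(th), st = std::sin(th);
    for (int ib = 0; ib < n_bins; ++ib) {
      const double t = ib - half;
      double acc = 0.0;
      for (int is = 0; is < n_bins; ++is) {
        const double s = is - half;
        const double x = t * ct - s * st;  // col offset
        const double y = t * st + s * ct;  // row offset
        acc += bilin(ip, H, W, y + rc, x + cc, true);
      }
      sino(a, ib) = acc;
    }
  }
  return sino;
}

// Backprojection of an (already ramp-filtered) sinogram onto an
// out_h x out_w grid, scaled by pi / (2 * n_angles).
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix fsino, NumericVector angles_deg,
                              int out_h, int out_w) {
  const int A = fsino.nrow(), n_bins = fsino.ncol();
  const double rc = (out_h - 1) / 2.0, cc = (out_w - 1) / 2.0;
  const double half = (n_bins - 1) / 2.0;
  NumericMatrix out(out_h, out_w);
  for (int a = 0; a < A; ++a) {
    const double th = angles_deg[a] * M_PI / 180.0;
    const double ct = std::cos(th), st = std::sin(th);
    for (int j = 0; j < out_w; ++j) {
      const double x = j - cc;
      for (int i = 0; i < out_h; ++i) {
        const double y = i - rc;
        const double t = x * ct + y * st + half;
        const int t0 = (int)std::floor(t);
        if (t0 < 0 || t0 >= n_bins - 1) continue;
        const double f = t - t0;
        out(i, j) += (1 - f) * fsino(a, t0) + f * fsino(a, t0 + 1);
      }
    }
  }
  const double scale = M_PI / (2.0 * A);
  for (int k = 0; k < out_h * out_w; ++k) out[k] *= scale;
  return out;
}

// 2-D valid cross-correlation (kernel not flipped), for windowed statistics.
// [[Rcpp::export]]
NumericMatrix cpp_conv2_valid(NumericMatrix img, NumericMatrix ker) {
  const int H = img.nrow(), W = img.ncol();
  const int kh = ker.nrow(), kw = ker.ncol();
  const int Ho = H - kh + 1, Wo = W - kw + 1;
  NumericMatrix out(Ho, Wo);
  for (int jo = 0; jo < Wo; ++jo)
    for (int io = 0; io < Ho; ++io) {
      double acc = 0.0;
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          acc += img(io + ki, jo + kj) * ker(ki, kj);
      out(io, jo) = acc;
    }
  return out;
}
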