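// Numerical kernels: 2D convolution (im2col + GEMM) with gradients, batched
// matrix products for windowed self-attention, separable Gaussian smoothing,
// trilinear volume sampling, and surface-distance sets for Hausdorff metrics.
// All kernels are single-threaded and deterministic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int H, int k, int stride, int pad) {
  return (H + 2 * pad - k) / stride + 1;
}

// Fill the im2col matrix M (HoWo x kh*kw*C) for one sample.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad, arma::mat& M) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int q = i + kh * (j + kw * c);
        for (int ow = 0; ow < Wo; ++ow) {
          const int w = ow * stride - pad + j;
          for (int oh = 0; oh < Ho; ++oh) {
            const int h = oh * stride - pad + i;
            double v = 0.0;
            if (h >= 0 && h < H && w >= 0 && w < W)
              v = x[h + (size_t)H * (w + (size_t)W * c)];
            M(oh + (size_t)Ho * ow, q) = v;
          }
        }
      }
    }
  }
}

// Scatter-add of the column matrix back onto the input grid (adjoint of im2col).
static void col2im_add(const arma::mat& M, int H, int W, int C,
                       int kh, int kw, int stride, int pad, double* gx) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int q = i + kh * (j + kw * c);
        for (int ow = 0; ow < Wo; ++ow) {
          const int w = ow * stride - pad + j;
          if (w < 0 || w >= W) continue;
          for (int oh = 0; oh < Ho; ++oh) {
            const int h = oh * stride - pad + i;
            if (h < 0 || h >= H) continue;
            gx[h + (size_t)H * (w + (size_t)W * c)] += M(oh + (size_t)Ho * ow, q);
          }
        }
      }
    }
  }
}

// Vectorized same-padding stride-1 convolution: shift-and-add with
// submatrix axpy operations (fast path for 3x3 layers).
static void conv_same_fw(const double* x, const double* w, const double* b,
                         int H, int W, int C, int N, int k, int Co,
                         double* y) {
  const int p = (k - 1) / 2;
  const size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Co; ++co) {
      arma::mat Y(y + plane * (co + (size_t)Co * n), H, W, false, true);
      Y.fill(b[co]);
      for (int c = 0; c < C; ++c) {
        const arma::mat X(const_cast<double*>(x) + plane * (c + (size_t)C * n),
                          H, W, false, true);
        for (int j = 0; j < k; ++j) {
          const int dj = j - p;
          const int c0 = std::max(0, -dj), c1 = std::min(W - 1, W - 1 - dj);
          if (c0 > c1) continue;
          for (int i = 0; i < k; ++i) {
            const int di = i - p;
            const int r0 = std::max(0, -di), r1 = std::min(H - 1, H - 1 - di);
            if (r0 > r1) continue;
            const double wv = w[i + k * (j + k * (c + (size_t)C * co))];
            Y.submat(r0, c0, r1, c1) +=
              wv * X.submat(r0 + di, c0 + dj, r1 + di, c1 + dj);
          }
        }
      }
    }
  }
}

static void conv_same_bw(const double* x, const double* w, const double* gy,
                         int H, int W, int C, int N, int k, int Co,
                         double* gx, double* gw, double* gb) {
  const int p = (k - 1) / 2;
  const size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Co; ++co) {
      const arma::mat GY(const_cast<double*>(gy) + plane * (co + (size_t)Co * n),
                         H, W, false, true);
      gb[co] += arma::accu(GY);
      for (int c = 0; c < C; ++c) {
        const arma::mat X(const_cast<double*>(x) + plane * (c + (size_t)C * n),
                          H, W, false, true);
        arma::mat GX(gx + plane * (c + (size_t)C * n), H, W, false, true);
        for (int j = 0; j < k; ++j) {
          const int dj = j - p;
          const int c0 = std::max(0, -dj), c1 = std::min(W - 1, W - 1 - dj);
          if (c0 > c1) continue;
          for (int i = 0; i < k; ++i) {
            const int di = i - p;
            const int r0 = std::max(0, -di), r1 = std::min(H - 1, H - 1 - di);
            if (r0 > r1) continue;
            const size_t wi = i + k * (j + k * (c + (size_t)C * co));
            const double wv = w[wi];
            gw[wi] += arma::accu(
              X.submat(r0 + di, c0 + dj, r1 + di, c1 + dj) %
              GY.submat(r0, c0, r1, c1));
            GX.submat(r0 + di, c0 + dj, r1 + di, c1 + dj) +=
              wv * GY.submat(r0, c0, r1, c1);
          }
        }
      }
    }
  }
}

// x: (H, W, Cin, N); w: (kh, kw, Cin, Cout); b: length Cout.
// [[Rcpp::export(name = ".cpp_conv2d_fw")]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  if (wd[2] != C) stop("channel mismatch in conv2d");
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("conv2d output would be empty");
  NumericVector y(Ho * (size_t)Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  if (stride == 1 && kh == kw && pad == (kh - 1) / 2) {
    conv_same_fw(x.begin(), w.begin(), b.begin(), H, W, C, N, kh, Co,
                 y.begin());
    return y;
  }
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * C, Co, false, true);
  arma::mat M((size_t)Ho * Wo, (size_t)kh * kw * C);
  arma::rowvec bv(const_cast<double*>(b.begin()), Co, false, true);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, M);
    arma::mat Yn(y.begin() + (size_t)Ho * Wo * Co * n, (size_t)Ho * Wo, Co, false, true);
    Yn = M * Wm;
    Yn.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bw")]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  NumericVector gx(x.size()); gx.attr("dim") = xd;
  NumericVector gw(w.size()); gw.attr("dim") = wd;
  NumericVector gb(Co);
  if (stride == 1 && kh == kw && pad == (kh - 1) / 2) {
    conv_same_bw(x.begin(), w.begin(), gy.begin(), H, W, C, N, kh, Co,
                 gx.begin(), gw.begin(), gb.begin());
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * C, Co, false, true);
  arma::mat Gw(gw.begin(), (size_t)kh * kw * C, Co, false, true);
  arma::rowvec Gb(gb.begin(), Co, false, true);
  arma::mat M((size_t)Ho * Wo, (size_t)kh * kw * C);
  for (int n = 0; n < N; ++n) {
    arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)Ho * Wo * Co * n,
                 (size_t)Ho * Wo, Co, false, true);
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, M);
    Gw += M.t() * Gy;
    Gb += arma::sum(Gy, 0);
    arma::mat Gcol = Gy * Wm.t();
    col2im_add(Gcol, H, W, C, kh, kw, stride, pad,
               gx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Batched matrix multiply: A (ma, ka, B), Bm (kb, nb, B); optional transposes.
// [[Rcpp::export(name = ".cpp_bmm")]]
NumericVector cpp_bmm(NumericVector A, NumericVector Bm, bool tA, bool tB) {
  IntegerVector ad = A.attr("dim"), bd = Bm.attr("dim");
  const int a1 = ad[0], a2 = ad[1], nB = ad[2];
  const int b1 = bd[0], b2 = bd[1];
  if (bd[2] != nB) stop("batch mismatch in bmm");
  const int m = tA ? a2 : a1, kA = tA ? a1 : a2;
  const int kB = tB ? b2 : b1, n = tB ? b1 : b2;
  if (kA != kB) stop("inner dimension mismatch in bmm");
  NumericVector Cv((size_t)m * n * nB);
  Cv.attr("dim") = IntegerVector::create(m, n, nB);
  for (int s = 0; s < nB; ++s) {
    arma::mat As(const_cast<double*>(A.begin()) + (size_t)a1 * a2 * s, a1, a2, false, true);
    arma::mat Bs(const_cast<double*>(Bm.begin()) + (size_t)b1 * b2 * s, b1, b2, false, true);
    arma::mat Cs(Cv.begin() + (size_t)m * n * s, m, n, false, true);
    if (!tA && !tB) Cs = As * Bs;
    else if (tA && !tB) Cs = As.t() * Bs;
    else if (!tA && tB) Cs = As * Bs.t();
    else Cs = As.t() * Bs.t();
  }
  return Cv;
}

// Separable Gaussian smoothing of a 3D array; sigma in voxels per axis.
// Edge-renormalized (kernel mass restricted to the support inside the grid).
static void blur_axis(std::vector<double>& v, int d0, int d1, int d2,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  for (int i = -r; i <= r; ++i) k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
  const int dims[3] = {d0, d1, d2};
  const int n = dims[axis];
  const size_t strides[3] = {1, (size_t)d0, (size_t)d0 * d1};
  const size_t st = strides[axis];
  std::vector<double> line(n);
  for (int a = 0; a < (axis == 0 ? d1 : d0); ++a) {
    for (int b = 0; b < (axis == 2 ? d1 : d2); ++b) {
      size_t base;
      if (axis == 0)      base = (size_t)d0 * a + (size_t)d0 * d1 * b;
      else if (axis == 1) base = (size_t)a + (size_t)d0 * d1 * b;
      else                base = (size_t)a + (size_t)d0 * b;
      for (int i = 0; i < n; ++i) line[i] = v[base + st * i];
      for (int i = 0; i < n; ++i) {
        double s = 0, wsum = 0;
        const int lo = std::max(0, i - r), hi = std::min(n - 1, i + r);
        for (int j = lo; j <= hi; ++j) { s += k[j - i + r] * line[j]; wsum += k[j - i + r]; }
        v[base + st * i] = s / wsum;
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_gauss_blur3d")]]
NumericVector cpp_gauss_blur3d(NumericVector x, NumericVector sigma_vox) {
  IntegerVector xd = x.attr("dim");
  std::vector<double> v(x.begin(), x.end());
  blur_axis(v, xd[0], xd[1], xd[2], 0, sigma_vox[0]);
  blur_axis(v, xd[0], xd[1], xd[2], 1, sigma_vox[1]);
  blur_axis(v, xd[0], xd[1], xd[2], 2, sigma_vox[2]);
  NumericVector y(v.begin(), v.end());
  y.attr("dim") = xd;
  return y;
}

// Trilinear sampling of volume vol (H,W,D) at continuous 0-based voxel
// coordinates (n x 3); out-of-support points take `fill`.
// [[Rcpp::export(name = ".cpp_sample_trilinear")]]
NumericVector cpp_sample_trilinear(NumericVector vol, NumericMatrix pts,
                                   double fill, bool nearest) {
  IntegerVector vd = vol.attr("dim");
  const int H = vd[0], W = vd[1], D = vd[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double* v = vol.begin();
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    if (nearest) {
      const int xi = (int)std::lround(x), yi = (int)std::lround(y), zi = (int)std::lround(z);
      if (xi < 0 || xi >= H || yi < 0 || yi >= W || zi < 0 || zi >= D) out[i] = fill;
      else out[i] = v[xi + (size_t)H * (yi + (size_t)W * zi)];
      continue;
    }
    if (x < 0 || x > H - 1 || y < 0 || y > W - 1 || z < 0 || z > D - 1) { out[i] = fill; continue; }
    const int x0 = std::min((int)std::floor(x), H - 2 >= 0 ? H - 2 : 0);
    const int y0 = std::min((int)std::floor(y), W - 2 >= 0 ? W - 2 : 0);
    const int z0 = std::min((int)std::floor(z), D - 2 >= 0 ? D - 2 : 0);
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    double acc = 0;
    for (int dz = 0; dz <= 1; ++dz)
      for (int dy = 0; dy <= 1; ++dy)
        for (int dx = 0; dx <= 1; ++dx) {
          const int xi = std::min(x0 + dx, H - 1), yi = std::min(y0 + dy, W - 1),
                    zi = std::min(z0 + dz, D - 1);
          const double wgt = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
          acc += wgt * v[xi + (size_t)H * (yi + (size_t)W * zi)];
        }
    out[i] = acc;
  }
  return out;
}

// For each point in A (nA x 3, mm), the distance to the nearest point in B.
// [[Rcpp::export(name = ".cpp_min_dists")]]
NumericVector cpp_min_dists(NumericMatrix A, NumericMatrix B) {
  const int nA = A.nrow(), nB = B.nrow();
  NumericVector out(nA);
  for (int i = 0; i < nA; ++i) {
    double best = R_PosInf;
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < nB; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
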