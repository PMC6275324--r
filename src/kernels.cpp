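// Low-level numerical kernels for the 3D networks and the synthetic
// simulator. Feature maps are stored as dense matrices with one row per
// voxel (batch samples stacked along rows, x fastest / column-major
// spatial order) and one column per channel. Convolutions are lowered to
// GEMM through im2col/col2im so BLAS carries the arithmetic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int vox_index(int x, int y, int z, const int *d) {
  return x + d[0] * (y + d[1] * z);
}

// valid output range [lo, hi] for one axis so that 0 <= o*s - p + kk < n
static inline void axis_range(int n_in, int n_out, int s, int p, int kk,
                              int *lo, int *hi) {
  int l = (p - kk + s - 1) / s;       // ceil((p - kk) / s)
  if (p - kk <= 0) l = 0;
  int h = (n_in - 1 + p - kk) / s;    // floor
  if (h > n_out - 1) h = n_out - 1;
  *lo = l;
  *hi = h;
}

// Gather the im2col matrix for one sample.
// x: (vox x Cin) block for this sample; col: (ovox x K*Cin), K = k1*k2*k3.
// Column layout: kidx + K*ci with kidx = kx + k1*(ky + k2*kz).
static void im2col_sample(const double *x, const int *ind, int cin,
                          const int *outd, const int *k, const int *s,
                          const int *p, double *col) {
  const int K = k[0] * k[1] * k[2];
  const int ovox = outd[0] * outd[1] * outd[2];
  const int vox = ind[0] * ind[1] * ind[2];
  for (int ci = 0; ci < cin; ++ci) {
    const double *xc = x + (size_t)ci * vox;
    for (int kz = 0; kz < k[2]; ++kz)
      for (int ky = 0; ky < k[1]; ++ky)
        for (int kx = 0; kx < k[0]; ++kx) {
          const int kidx = kx + k[0] * (ky + k[1] * kz);
          double *cc = col + (size_t)(kidx + K * ci) * ovox;
          int xlo, xhi, ylo, yhi, zlo, zhi;
          axis_range(ind[0], outd[0], s[0], p[0], kx, &xlo, &xhi);
          axis_range(ind[1], outd[1], s[1], p[1], ky, &ylo, &yhi);
          axis_range(ind[2], outd[2], s[2], p[2], kz, &zlo, &zhi);
          for (int oz = 0; oz < outd[2]; ++oz) {
            const int iz = oz * s[2] - p[2] + kz;
            const bool zok = oz >= zlo && oz <= zhi;
            for (int oy = 0; oy < outd[1]; ++oy) {
              double *crow = cc + (size_t)outd[0] * (oy + outd[1] * oz);
              if (!zok || oy < ylo || oy > yhi) {
                std::fill(crow, crow + outd[0], 0.0);
                continue;
              }
              const int iy = oy * s[1] - p[1] + ky;
              const double *xrow = xc + (size_t)ind[0] * (iy + ind[1] * iz);
              if (xlo > 0) std::fill(crow, crow + xlo, 0.0);
              if (xhi < outd[0] - 1)
                std::fill(crow + xhi + 1, crow + outd[0], 0.0);
              if (s[0] == 1) {
                std::copy(xrow + xlo - p[0] + kx, xrow + xhi + 1 - p[0] + kx,
                          crow + xlo);
              } else {
                for (int ox = xlo; ox <= xhi; ++ox)
                  crow[ox] = xrow[ox * s[0] - p[0] + kx];
              }
            }
          }
        }
  }
}

// Scatter-add transpose of im2col_sample.
static void col2im_sample(const double *col, const int *ind, int cin,
                          const int *outd, const int *k, const int *s,
                          const int *p, double *x) {
  const int K = k[0] * k[1] * k[2];
  const int ovox = outd[0] * outd[1] * outd[2];
  const int vox = ind[0] * ind[1] * ind[2];
  for (int ci = 0; ci < cin; ++ci) {
    double *xc = x + (size_t)ci * vox;
    for (int kz = 0; kz < k[2]; ++kz)
      for (int ky = 0; ky < k[1]; ++ky)
        for (int kx = 0; kx < k[0]; ++kx) {
          const int kidx = kx + k[0] * (ky + k[1] * kz);
          const double *cc = col + (size_t)(kidx + K * ci) * ovox;
          int xlo, xhi, ylo, yhi, zlo, zhi;
          axis_range(ind[0], outd[0], s[0], p[0], kx, &xlo, &xhi);
          axis_range(ind[1], outd[1], s[1], p[1], ky, &ylo, &yhi);
          axis_range(ind[2], outd[2], s[2], p[2], kz, &zlo, &zhi);
          for (int oz = zlo; oz <= zhi; ++oz) {
            const int iz = oz * s[2] - p[2] + kz;
            for (int oy = ylo; oy <= yhi; ++oy) {
              const int iy = oy * s[1] - p[1] + ky;
              const double *crow = cc + (size_t)outd[0] * (oy + outd[1] * oz);
              double *xrow = xc + (size_t)ind[0] * (iy + ind[1] * iz);
              if (s[0] == 1) {
                double *xr = xrow - p[0] + kx;
                for (int ox = xlo; ox <= xhi; ++ox) xr[ox] += crow[ox];
              } else {
                for (int ox = xlo; ox <= xhi; ++ox)
                  xrow[ox * s[0] - p[0] + kx] += crow[ox];
              }
            }
          }
        }
  }
}

// ---- specialized direct kernels for 3x3x3, stride 1, pad 1 ---------------
// Single-precision accumulation: activations/weights are converted once per
// call; the contiguous inner loops vectorize and no im2col buffer is built.

static void to_float(const double *src, size_t n, float *dst) {
  for (size_t i = 0; i < n; ++i) dst[i] = (float)src[i];
}

// The toolchain's baseline -march predates SIMD widths every current CPU
// has; multiversioning compiles the two hot loops for wider vector units
// and dispatches at load time, independent of the global flags.
#if defined(__GNUC__) && defined(__x86_64__) && !defined(__clang__)
#define HOT_CLONES __attribute__((target_clones("arch=x86-64-v4", "arch=x86-64-v3", "default")))
#else
#define HOT_CLONES
#endif

// y[vox x cout] += conv3(x[vox x cin], w[27*cin x cout]) with w column-major
// as in the im2col layout (kidx + 27*ci).
HOT_CLONES
static void direct3_fw(const float *x, const int *d, int cin, int cout,
                       const float *w, float *y) {
  const int d1 = d[0], d2 = d[1], d3 = d[2];
  const int vox = d1 * d2 * d3;
  std::vector<float> acc((size_t)d1 * cout);
  for (int oz = 0; oz < d3; ++oz) {
    for (int oy = 0; oy < d2; ++oy) {
      std::fill(acc.begin(), acc.end(), 0.0f);
      for (int kz = 0; kz < 3; ++kz) {
        const int iz = oz - 1 + kz;
        if (iz < 0 || iz >= d3) continue;
        for (int ky = 0; ky < 3; ++ky) {
          const int iy = oy - 1 + ky;
          if (iy < 0 || iy >= d2) continue;
          const float *xpl = x + (size_t)d1 * (iy + (size_t)d2 * iz);
          for (int ci = 0; ci < cin; ++ci) {
            const float *xrow = xpl + (size_t)ci * vox;
            for (int kx = 0; kx < 3; ++kx) {
              const int kidx = kx + 3 * (ky + 3 * kz);
              const int off = kx - 1;
              const int lo = off < 0 ? 1 : 0;
              const int hi = off > 0 ? d1 - 1 : d1;
              const float *__restrict xs = xrow + off;
              for (int co = 0; co < cout; ++co) {
                const float wv = w[(size_t)(kidx + 27 * ci) +
                                   (size_t)(27 * cin) * co];
                float *__restrict arow = acc.data() + (size_t)co * d1;
                for (int ox = lo; ox < hi; ++ox) arow[ox] += wv * xs[ox];
              }
            }
          }
        }
      }
      for (int co = 0; co < cout; ++co) {
        float *dst = y + (size_t)co * vox + (size_t)d1 * (oy + (size_t)d2 * oz);
        const float *arow = acc.data() + (size_t)co * d1;
        for (int ox = 0; ox < d1; ++ox) dst[ox] = arow[ox];
      }
    }
  }
}

// gW[27*cin x cout] += correlation of x with gy
HOT_CLONES
static void direct3_gw(const float *x, const float *gy, const int *d, int cin,
                       int cout, double *gW_) {
  const int d1 = d[0], d2 = d[1], d3 = d[2];
  const int vox = d1 * d2 * d3;
  for (int kz = 0; kz < 3; ++kz)
    for (int ky = 0; ky < 3; ++ky) {
      for (int oz = 0; oz < d3; ++oz) {
        const int iz = oz - 1 + kz;
        if (iz < 0 || iz >= d3) continue;
        for (int oy = 0; oy < d2; ++oy) {
          const int iy = oy - 1 + ky;
          if (iy < 0 || iy >= d2) continue;
          const float *xpl = x + (size_t)d1 * (iy + (size_t)d2 * iz);
          const float *gpl = gy + (size_t)d1 * (oy + (size_t)d2 * oz);
          for (int ci = 0; ci < cin; ++ci) {
            const float *xrow = xpl + (size_t)ci * vox;
            for (int co = 0; co < cout; ++co) {
              const float *grow = gpl + (size_t)co * vox;
              for (int kx = 0; kx < 3; ++kx) {
                const int off = kx - 1;
                const int lo = off < 0 ? 1 : 0;
                const int hi = off > 0 ? d1 - 1 : d1;
                const float *__restrict xs = xrow + off;
                const float *__restrict gr = grow;
                float s = 0.0f;
#pragma omp simd reduction(+ : s)
                for (int ox = lo; ox < hi; ++ox) s += xs[ox] * gr[ox];
                gW_[(size_t)(kx + 3 * (ky + 3 * kz) + 27 * ci) +
                    (size_t)(27 * cin) * co] += s;
              }
            }
          }
        }
      }
    }
}

static bool is_direct3(const IntegerVector &k, const IntegerVector &s,
                       const IntegerVector &p) {
  return k[0] == 3 && k[1] == 3 && k[2] == 3 && s[0] == 1 && s[1] == 1 &&
         s[2] == 1 && p[0] == 1 && p[1] == 1 && p[2] == 1;
}

static void check_geom(const NumericMatrix &x, const IntegerVector &ind,
                       int nbatch) {
  const long vox = (long)ind[0] * ind[1] * ind[2];
  if ((long)x.nrow() != vox * nbatch)
    stop("feature map has %d rows but geometry implies %ld", x.nrow(),
         vox * nbatch);
}

// Direct 3D convolution. W: (K*Cin x Cout), bias length Cout.
// [[Rcpp::export(name = ".conv3d_fw")]]
NumericMatrix conv3d_fw(const NumericMatrix &x, const IntegerVector &ind,
                        int nbatch, const NumericMatrix &W,
                        const NumericVector &bias, const IntegerVector &k,
                        const IntegerVector &s, const IntegerVector &p,
                        const IntegerVector &outd) {
  check_geom(x, ind, nbatch);
  const int cin = x.ncol(), cout = W.ncol();
  const int K = k[0] * k[1] * k[2];
  if (W.nrow() != K * cin) stop("weight rows mismatch im2col width");
  const int vox = ind[0] * ind[1] * ind[2];
  const int ovox = outd[0] * outd[1] * outd[2];
  NumericMatrix y((size_t)ovox * nbatch, cout);
  if (is_direct3(k, s, p)) {
    std::vector<float> wf((size_t)W.nrow() * cout), xf((size_t)vox * cin),
        yf((size_t)vox * cout);
    to_float(W.begin(), wf.size(), wf.data());
    for (int n = 0; n < nbatch; ++n) {
      for (int c = 0; c < cin; ++c)
        to_float(x.begin() + (size_t)c * x.nrow() + (size_t)n * vox, vox,
                 xf.data() + (size_t)c * vox);
      direct3_fw(xf.data(), ind.begin(), cin, cout, wf.data(), yf.data());
      for (int c = 0; c < cout; ++c) {
        double *dst = y.begin() + (size_t)c * y.nrow() + (size_t)n * vox;
        const float *src = yf.data() + (size_t)c * vox;
        const double bb = bias[c];
        for (int i = 0; i < vox; ++i) dst[i] = (double)src[i] + bb;
      }
    }
    return y;
  }
  arma::mat col(ovox, (size_t)K * cin);
  const arma::mat Wm(const_cast<double *>(W.begin()), W.nrow(), cout, false);
  for (int n = 0; n < nbatch; ++n) {
    // each sample's channel data is strided across the stacked rows, so
    // copy the sample block out first
    arma::mat xs(vox, cin);
    for (int c = 0; c < cin; ++c)
      std::copy(x.begin() + (size_t)c * x.nrow() + (size_t)n * vox,
                x.begin() + (size_t)c * x.nrow() + (size_t)(n + 1) * vox,
                xs.colptr(c));
    im2col_sample(xs.memptr(), ind.begin(), cin, outd.begin(), k.begin(),
                  s.begin(), p.begin(), col.memptr());
    arma::mat ys = col * Wm;
    for (int c = 0; c < cout; ++c) {
      double *dst = y.begin() + (size_t)c * y.nrow() + (size_t)n * ovox;
      const double *src = ys.colptr(c);
      const double b = bias[c];
      for (int i = 0; i < ovox; ++i) dst[i] = src[i] + b;
    }
  }
  return y;
}

// Backward pass of conv3d_fw: returns list(gx, gW, gb).
// [[Rcpp::export(name = ".conv3d_bw")]]
List conv3d_bw(const NumericMatrix &x, const NumericMatrix &gy,
               const IntegerVector &ind, int nbatch, const NumericMatrix &W,
               const IntegerVector &k, const IntegerVector &s,
               const IntegerVector &p, const IntegerVector &outd,
               bool need_gx, bool need_gw) {
  const int cin = x.ncol(), cout = W.ncol();
  const int K = k[0] * k[1] * k[2];
  const int vox = ind[0] * ind[1] * ind[2];
  const int ovox = outd[0] * outd[1] * outd[2];
  NumericMatrix gx(need_gx ? (size_t)vox * nbatch : 1, need_gx ? cin : 1);
  arma::mat gW(W.nrow(), cout, arma::fill::zeros);
  arma::vec gb(cout, arma::fill::zeros);
  if (is_direct3(k, s, p)) {
    std::vector<float> xf((size_t)vox * cin), gyf((size_t)vox * cout),
        gxf((size_t)vox * cin);
    std::vector<float> wflip;
    if (need_gx) {
      // flipped + transposed weights: gx is the correlation of gy with the
      // kernel reversed along all three axes and channel roles swapped
      wflip.resize((size_t)27 * cout * cin);
      for (int ci = 0; ci < cin; ++ci)
        for (int co = 0; co < cout; ++co)
          for (int kidx = 0; kidx < 27; ++kidx)
            wflip[(size_t)(26 - kidx + 27 * co) + (size_t)(27 * cout) * ci] =
                (float)W[(size_t)(kidx + 27 * ci) + (size_t)(27 * cin) * co];
    }
    for (int n = 0; n < nbatch; ++n) {
      for (int c = 0; c < cout; ++c) {
        const double *src = gy.begin() + (size_t)c * gy.nrow() + (size_t)n * vox;
        float *dst = gyf.data() + (size_t)c * vox;
        double s_ = 0.0;
        for (int i = 0; i < vox; ++i) { dst[i] = (float)src[i]; s_ += src[i]; }
        gb[c] += s_;
      }
      if (need_gw) {
        for (int c = 0; c < cin; ++c)
          to_float(x.begin() + (size_t)c * x.nrow() + (size_t)n * vox, vox,
                   xf.data() + (size_t)c * vox);
        direct3_gw(xf.data(), gyf.data(), ind.begin(), cin, cout,
                   gW.memptr());
      }
      if (need_gx) {
        direct3_fw(gyf.data(), ind.begin(), cout, cin, wflip.data(),
                   gxf.data());
        for (int c = 0; c < cin; ++c) {
          double *dst = gx.begin() + (size_t)c * gx.nrow() + (size_t)n * vox;
          const float *src = gxf.data() + (size_t)c * vox;
          for (int i = 0; i < vox; ++i) dst[i] = (double)src[i];
        }
      }
    }
    return List::create(_["gx"] = gx, _["gW"] = wrap(gW), _["gb"] = wrap(gb));
  }
  arma::mat col(ovox, (size_t)K * cin);
  const arma::mat Wm(const_cast<double *>(W.begin()), W.nrow(), cout, false);
  for (int n = 0; n < nbatch; ++n) {
    arma::mat gys(ovox, cout);
    for (int c = 0; c < cout; ++c)
      std::copy(gy.begin() + (size_t)c * gy.nrow() + (size_t)n * ovox,
                gy.begin() + (size_t)c * gy.nrow() + (size_t)(n + 1) * ovox,
                gys.colptr(c));
    gb += arma::sum(gys, 0).t();
    if (need_gw) {
      arma::mat xs(vox, cin);
      for (int c = 0; c < cin; ++c)
        std::copy(x.begin() + (size_t)c * x.nrow() + (size_t)n * vox,
                  x.begin() + (size_t)c * x.nrow() + (size_t)(n + 1) * vox,
                  xs.colptr(c));
      im2col_sample(xs.memptr(), ind.begin(), cin, outd.begin(), k.begin(),
                    s.begin(), p.begin(), col.memptr());
      gW += col.t() * gys;
    }
    if (need_gx) {
      arma::mat WmT = Wm.t();
      arma::mat gcol = gys * WmT;
      arma::mat gxs(vox, cin, arma::fill::zeros);
      col2im_sample(gcol.memptr(), ind.begin(), cin, outd.begin(), k.begin(),
                    s.begin(), p.begin(), gxs.memptr());
      for (int c = 0; c < cin; ++c)
        std::copy(gxs.colptr(c), gxs.colptr(c) + vox,
                  gx.begin() + (size_t)c * gx.nrow() + (size_t)n * vox);
    }
  }
  return List::create(_["gx"] = gx, _["gW"] = wrap(gW), _["gb"] = wrap(gb));
}

// Transposed convolution: the adjoint of a (k, s, p) convolution mapping
// the OUTPUT geometry back to the input geometry. W: (K*Cout x Cin).
// [[Rcpp::export(name = ".tconv3d_fw")]]
NumericMatrix tconv3d_fw(const NumericMatrix &x, const IntegerVector &ind,
                         int nbatch, const NumericMatrix &W,
                         const NumericVector &bias, const IntegerVector &k,
                         const IntegerVector &s, const IntegerVector &p,
                         const IntegerVector &outd) {
  check_geom(x, ind, nbatch);
  const int cin = x.ncol(), cout = W.nrow() / (k[0] * k[1] * k[2]);
  if (W.ncol() != cin) stop("tconv weight cols must equal input channels");
  const int vox = ind[0] * ind[1] * ind[2];
  const int ovox = outd[0] * outd[1] * outd[2];
  NumericMatrix y((size_t)ovox * nbatch, cout);
  const arma::mat Wm(const_cast<double *>(W.begin()), W.nrow(), cin, false);
  for (int n = 0; n < nbatch; ++n) {
    arma::mat xs(vox, cin);
    for (int c = 0; c < cin; ++c)
      std::copy(x.begin() + (size_t)c * x.nrow() + (size_t)n * vox,
                x.begin() + (size_t)c * x.nrow() + (size_t)(n + 1) * vox,
                xs.colptr(c));
    arma::mat WmT = Wm.t();
    arma::mat gcol = xs * WmT;  // (vox x K*Cout) in conv im2col layout
    arma::mat ys(ovox, cout, arma::fill::zeros);
    // roles swapped: conv input geometry = outd (large), conv output = ind
    col2im_sample(gcol.memptr(), outd.begin(), cout, ind.begin(), k.begin(),
                  s.begin(), p.begin(), ys.memptr());
    for (int c = 0; c < cout; ++c) {
      double *dst = y.begin() + (size_t)c * y.nrow() + (size_t)n * ovox;
      const double *src = ys.colptr(c);
      const double b = bias[c];
      for (int i = 0; i < ovox; ++i) dst[i] = src[i] + b;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".tconv3d_bw")]]
List tconv3d_bw(const NumericMatrix &x, const NumericMatrix &gy,
                const IntegerVector &ind, int nbatch, const NumericMatrix &W,
                const IntegerVector &k, const IntegerVector &s,
                const IntegerVector &p, const IntegerVector &outd,
                bool need_gx, bool need_gw) {
  const int cin = x.ncol();
  const int K = k[0] * k[1] * k[2];
  const int cout = W.nrow() / K;
  const int vox = ind[0] * ind[1] * ind[2];
  const int ovox = outd[0] * outd[1] * outd[2];
  NumericMatrix gx(need_gx ? (size_t)vox * nbatch : 1, need_gx ? cin : 1);
  arma::mat gW(W.nrow(), cin, arma::fill::zeros);
  arma::vec gb(cout, arma::fill::zeros);
  arma::mat col(vox, (size_t)K * cout);
  const arma::mat Wm(const_cast<double *>(W.begin()), W.nrow(), cin, false);
  for (int n = 0; n < nbatch; ++n) {
    arma::mat gys(ovox, cout);
    for (int c = 0; c < cout; ++c)
      std::copy(gy.begin() + (size_t)c * gy.nrow() + (size_t)n * ovox,
                gy.begin() + (size_t)c * gy.nrow() + (size_t)(n + 1) * ovox,
                gys.colptr(c));
    gb += arma::sum(gys, 0).t();
    // im2col over the large (output) geometry of gy
    im2col_sample(gys.memptr(), outd.begin(), cout, ind.begin(), k.begin(),
                  s.begin(), p.begin(), col.memptr());
    if (need_gw) {
      arma::mat xs(vox, cin);
      for (int c = 0; c < cin; ++c)
        std::copy(x.begin() + (size_t)c * x.nrow() + (size_t)n * vox,
                  x.begin() + (size_t)c * x.nrow() + (size_t)(n + 1) * vox,
                  xs.colptr(c));
      gW += col.t() * xs;
    }
    if (need_gx) {
      arma::mat gxs = col * Wm;
      for (int c = 0; c < cin; ++c)
        std::copy(gxs.colptr(c), gxs.colptr(c) + vox,
                  gx.begin() + (size_t)c * gx.nrow() + (size_t)n * vox);
    }
  }
  return List::create(_["gx"] = gx, _["gW"] = wrap(gW), _["gb"] = wrap(gb));
}

// 2x2x2-style max pooling (window = stride, per-axis), recording argmax.
// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(const NumericMatrix &x, const IntegerVector &ind, int nbatch,
                const IntegerVector &w) {
  const int cin = x.ncol();
  const int vox = ind[0] * ind[1] * ind[2];
  int outd[3];
  for (int a = 0; a < 3; ++a) outd[a] = ind[a] / w[a];
  const int ovox = outd[0] * outd[1] * outd[2];
  NumericMatrix y((size_t)ovox * nbatch, cin);
  IntegerMatrix am((size_t)ovox * nbatch, cin);
  for (int n = 0; n < nbatch; ++n)
    for (int c = 0; c < cin; ++c) {
      const double *xc = x.begin() + (size_t)c * x.nrow() + (size_t)n * vox;
      double *yc = y.begin() + (size_t)c * y.nrow() + (size_t)n * ovox;
      int *ac = am.begin() + (size_t)c * am.nrow() + (size_t)n * ovox;
      for (int oz = 0; oz < outd[2]; ++oz)
        for (int oy = 0; oy < outd[1]; ++oy)
          for (int ox = 0; ox < outd[0]; ++ox) {
            double best = -1e300;
            int bi = -1;
            for (int dz = 0; dz < w[2]; ++dz)
              for (int dy = 0; dy < w[1]; ++dy)
                for (int dx = 0; dx < w[0]; ++dx) {
                  const int i = vox_index(ox * w[0] + dx, oy * w[1] + dy,
                                          oz * w[2] + dz, ind.begin());
                  if (xc[i] > best) { best = xc[i]; bi = i; }
                }
            const int o = ox + outd[0] * (oy + outd[1] * oz);
            yc[o] = best;
            ac[o] = bi;
          }
    }
  return List::create(_["y"] = y, _["argmax"] = am,
                      _["outd"] = IntegerVector::create(outd[0], outd[1], outd[2]));
}

// [[Rcpp::export(name = ".maxpool_bw")]]
NumericMatrix maxpool_bw(const NumericMatrix &gy, const IntegerMatrix &am,
                         const IntegerVector &ind, int nbatch) {
  const int cin = gy.ncol();
  const int vox = ind[0] * ind[1] * ind[2];
  const int ovox = gy.nrow() / nbatch;
  NumericMatrix gx((size_t)vox * nbatch, cin);
  for (int n = 0; n < nbatch; ++n)
    for (int c = 0; c < cin; ++c) {
      const double *gyc = gy.begin() + (size_t)c * gy.nrow() + (size_t)n * ovox;
      const int *ac = am.begin() + (size_t)c * am.nrow() + (size_t)n * ovox;
      double *gxc = gx.begin() + (size_t)c * gx.nrow() + (size_t)n * vox;
      for (int o = 0; o < ovox; ++o) gxc[ac[o]] += gyc[o];
    }
  return gx;
}

static inline void lin_coef(int o, int nin, int nout, int *i0, int *i1,
                            double *w1) {
  // half-pixel-centre resampling
  double pos = (o + 0.5) * ((double)nin / nout) - 0.5;
  if (pos < 0) pos = 0;
  if (pos > nin - 1) pos = nin - 1;
  *i0 = (int)std::floor(pos);
  *i1 = *i0 + 1 < nin ? *i0 + 1 : *i0;
  *w1 = pos - *i0;
}

// Trilinear resampling to an arbitrary target extent (used for the U-Net
// decoder upsampling). Adjoint obtained with transpose = true.
// [[Rcpp::export(name = ".resize3d")]]
NumericMatrix resize3d(const NumericMatrix &x, const IntegerVector &ind,
                       int nbatch, const IntegerVector &outd, bool transpose) {
  const int cin = x.ncol();
  const int vox = ind[0] * ind[1] * ind[2];
  const int ovox = outd[0] * outd[1] * outd[2];
  NumericMatrix y((size_t)(transpose ? vox : ovox) * nbatch, cin);
  std::vector<int> x0(outd[0]), x1(outd[0]), y0(outd[1]), y1(outd[1]),
      z0(outd[2]), z1(outd[2]);
  std::vector<double> wx(outd[0]), wy(outd[1]), wz(outd[2]);
  for (int o = 0; o < outd[0]; ++o) lin_coef(o, ind[0], outd[0], &x0[o], &x1[o], &wx[o]);
  for (int o = 0; o < outd[1]; ++o) lin_coef(o, ind[1], outd[1], &y0[o], &y1[o], &wy[o]);
  for (int o = 0; o < outd[2]; ++o) lin_coef(o, ind[2], outd[2], &z0[o], &z1[o], &wz[o]);
  for (int n = 0; n < nbatch; ++n)
    for (int c = 0; c < cin; ++c) {
      const double *xc = x.begin() + (size_t)c * x.nrow() +
                         (size_t)n * (transpose ? ovox : vox);
      double *yc = y.begin() + (size_t)c * y.nrow() +
                   (size_t)n * (transpose ? vox : ovox);
      for (int oz = 0; oz < outd[2]; ++oz)
        for (int oy = 0; oy < outd[1]; ++oy)
          for (int ox = 0; ox < outd[0]; ++ox) {
            const int o = ox + outd[0] * (oy + outd[1] * oz);
            const int c000 = vox_index(x0[ox], y0[oy], z0[oz], ind.begin());
            const int c100 = vox_index(x1[ox], y0[oy], z0[oz], ind.begin());
            const int c010 = vox_index(x0[ox], y1[oy], z0[oz], ind.begin());
            const int c110 = vox_index(x1[ox], y1[oy], z0[oz], ind.begin());
            const int c001 = vox_index(x0[ox], y0[oy], z1[oz], ind.begin());
            const int c101 = vox_index(x1[ox], y0[oy], z1[oz], ind.begin());
            const int c011 = vox_index(x0[ox], y1[oy], z1[oz], ind.begin());
            const int c111 = vox_index(x1[ox], y1[oy], z1[oz], ind.begin());
            const double ax = wx[ox], ay = wy[oy], az = wz[oz];
            const double w000 = (1 - ax) * (1 - ay) * (1 - az),
                         w100 = ax * (1 - ay) * (1 - az),
                         w010 = (1 - ax) * ay * (1 - az),
                         w110 = ax * ay * (1 - az),
                         w001 = (1 - ax) * (1 - ay) * az,
                         w101 = ax * (1 - ay) * az,
                         w011 = (1 - ax) * ay * az, w111 = ax * ay * az;
            if (!transpose) {
              yc[o] = w000 * xc[c000] + w100 * xc[c100] + w010 * xc[c010] +
                      w110 * xc[c110] + w001 * xc[c001] + w101 * xc[c101] +
                      w011 * xc[c011] + w111 * xc[c111];
            } else {
              const double g = xc[o];
              yc[c000] += w000 * g; yc[c100] += w100 * g;
              yc[c010] += w010 * g; yc[c110] += w110 * g;
              yc[c001] += w001 * g; yc[c101] += w101 * g;
              yc[c011] += w011 * g; yc[c111] += w111 * g;
            }
          }
    }
  return y;
}

// ---- exact squared Euclidean distance transform (separable 1D passes) ----

static void edt1d(const double *f, int n, double *d, int *v, double *z) {
  int k = 0;
  v[0] = 0;
  z[0] = -1e300;
  z[1] = 1e300;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e300;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared distance to the nearest nonzero voxel of mask (anisotropic
// voxel spacing supported); INF-filled where the mask is empty.
// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(const LogicalVector &mask, const IntegerVector &ind,
                       const NumericVector &spacing) {
  const int d1 = ind[0], d2 = ind[1], d3 = ind[2];
  const int vox = d1 * d2 * d3;
  const double BIG = 1e300;
  NumericVector D(vox);
  for (int i = 0; i < vox; ++i) D[i] = mask[i] ? 0.0 : BIG;
  const int nmax = std::max(d1, std::max(d2, d3));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // pass along x
  for (int iz = 0; iz < d3; ++iz)
    for (int iy = 0; iy < d2; ++iy) {
      double *row = D.begin() + (size_t)d1 * (iy + d2 * iz);
      edt1d(row, d1, dd.data(), v.data(), z.data());
      for (int i = 0; i < d1; ++i) row[i] = dd[i];
    }
  // pass along y
  for (int iz = 0; iz < d3; ++iz)
    for (int ix = 0; ix < d1; ++ix) {
      for (int iy = 0; iy < d2; ++iy) f[iy] = D[vox_index(ix, iy, iz, ind.begin())];
      edt1d(f.data(), d2, dd.data(), v.data(), z.data());
      for (int iy = 0; iy < d2; ++iy) D[vox_index(ix, iy, iz, ind.begin())] = dd[iy];
    }
  // pass along z with anisotropic spacing folded in afterwards: scale the
  // in-plane result into spacing units first
  const double sxy = spacing[0] * spacing[0];
  const double sz = spacing[2] * spacing[2];
  for (int i = 0; i < vox; ++i) if (D[i] < BIG) D[i] *= sxy / sz;
  for (int iy = 0; iy < d2; ++iy)
    for (int ix = 0; ix < d1; ++ix) {
      for (int iz = 0; iz < d3; ++iz) f[iz] = D[vox_index(ix, iy, iz, ind.begin())];
      edt1d(f.data(), d3, dd.data(), v.data(), z.data());
      for (int iz = 0; iz < d3; ++iz) D[vox_index(ix, iy, iz, ind.begin())] = dd[iz] * sz;
    }
  return D;
}

// Trilinear pull-back warp: out(v) = vol(v + disp(v)), zero outside.
// vols: (vox x C), disp: (vox x 3) in voxel units.
// [[Rcpp::export(name = ".warp3d")]]
NumericMatrix warp3d(const NumericMatrix &vols, const IntegerVector &ind,
                     const NumericMatrix &disp) {
  const int d1 = ind[0], d2 = ind[1], d3 = ind[2];
  const int vox = d1 * d2 * d3;
  const int C = vols.ncol();
  NumericMatrix out(vox, C);
  for (int iz = 0; iz < d3; ++iz)
    for (int iy = 0; iy < d2; ++iy)
      for (int ix = 0; ix < d1; ++ix) {
        const int i = vox_index(ix, iy, iz, ind.begin());
        const double px = ix + disp(i, 0), py = iy + disp(i, 1),
                     pz = iz + disp(i, 2);
        const int fx = (int)std::floor(px), fy = (int)std::floor(py),
                  fz = (int)std::floor(pz);
        const double ax = px - fx, ay = py - fy, az = pz - fz;
        for (int c = 0; c < C; ++c) {
          double acc = 0.0;
          for (int dz = 0; dz <= 1; ++dz)
            for (int dy = 0; dy <= 1; ++dy)
              for (int dx = 0; dx <= 1; ++dx) {
                const int qx = fx + dx, qy = fy + dy, qz = fz + dz;
                if (qx < 0 || qx >= d1 || qy < 0 || qy >= d2 || qz < 0 ||
                    qz >= d3)
                  continue;
                const double w = (dx ? ax : 1 - ax) * (dy ? ay : 1 - ay) *
                                 (dz ? az : 1 - az);
                acc += w * vols(vox_index(qx, qy, qz, ind.begin()), c);
              }
          out(i, c) = acc;
        }
      }
  return out;
}

// ---- fused elementwise / column-affine helpers ---------------------------
// These replace allocation-heavy R idioms (sweep, pmax, exp) on the large
// feature-map matrices.

// [[Rcpp::export(name = ".relu_fw")]]
NumericMatrix relu_fw(const NumericMatrix &x) {
  NumericMatrix y(x.nrow(), x.ncol());
  const double *src = x.begin(); double *dst = y.begin();
  const size_t n = (size_t)x.nrow() * x.ncol();
  for (size_t i = 0; i < n; ++i) dst[i] = src[i] > 0 ? src[i] : 0.0;
  return y;
}

// [[Rcpp::export(name = ".mask_pos")]]
NumericMatrix mask_pos(const NumericMatrix &g, const NumericMatrix &v) {
  NumericMatrix y(g.nrow(), g.ncol());
  const double *gs = g.begin(), *vs = v.begin(); double *dst = y.begin();
  const size_t n = (size_t)g.nrow() * g.ncol();
  for (size_t i = 0; i < n; ++i) dst[i] = vs[i] > 0 ? gs[i] : 0.0;
  return y;
}

// [[Rcpp::export(name = ".sigmoid_fw")]]
NumericMatrix sigmoid_fw(const NumericMatrix &x) {
  NumericMatrix y(x.nrow(), x.ncol());
  const double *src = x.begin(); double *dst = y.begin();
  const size_t n = (size_t)x.nrow() * x.ncol();
  for (size_t i = 0; i < n; ++i) dst[i] = 1.0 / (1.0 + std::exp(-src[i]));
  return y;
}

// [[Rcpp::export(name = ".sigmoid_bw")]]
NumericMatrix sigmoid_bw(const NumericMatrix &g, const NumericMatrix &y) {
  NumericMatrix o(g.nrow(), g.ncol());
  const double *gs = g.begin(), *ys = y.begin(); double *dst = o.begin();
  const size_t n = (size_t)g.nrow() * g.ncol();
  for (size_t i = 0; i < n; ++i) dst[i] = gs[i] * ys[i] * (1.0 - ys[i]);
  return o;
}

// per-column mean and (biased) variance in one pass
// [[Rcpp::export(name = ".col_meanvar")]]
List col_meanvar(const NumericMatrix &x) {
  const int n = x.nrow(), c = x.ncol();
  NumericVector mu(c), va(c);
  for (int j = 0; j < c; ++j) {
    const double *col = x.begin() + (size_t)j * n;
    double s = 0, s2 = 0;
    for (int i = 0; i < n; ++i) { s += col[i]; s2 += col[i] * col[i]; }
    mu[j] = s / n;
    va[j] = s2 / n - mu[j] * mu[j];
    if (va[j] < 0) va[j] = 0;
  }
  return List::create(_["mean"] = mu, _["var"] = va);
}

// y = x * a[col] + b[col]
// [[Rcpp::export(name = ".col_affine")]]
NumericMatrix col_affine(const NumericMatrix &x, const NumericVector &a,
                         const NumericVector &b) {
  const int n = x.nrow(), c = x.ncol();
  NumericMatrix y(n, c);
  for (int j = 0; j < c; ++j) {
    const double *src = x.begin() + (size_t)j * n;
    double *dst = y.begin() + (size_t)j * n;
    const double aj = a[j], bj = b[j];
    for (int i = 0; i < n; ++i) dst[i] = src[i] * aj + bj;
  }
  return y;
}

// per-column means of g and of g*xhat in one pass
// [[Rcpp::export(name = ".col_gstats")]]
List col_gstats(const NumericMatrix &g, const NumericMatrix &xhat) {
  const int n = g.nrow(), c = g.ncol();
  NumericVector gm(c), gxm(c);
  for (int j = 0; j < c; ++j) {
    const double *gs = g.begin() + (size_t)j * n;
    const double *xs = xhat.begin() + (size_t)j * n;
    double s = 0, sx = 0;
    for (int i = 0; i < n; ++i) { s += gs[i]; sx += gs[i] * xs[i]; }
    gm[j] = s / n; gxm[j] = sx / n;
  }
  return List::create(_["gmean"] = gm, _["gxmean"] = gxm);
}

// gx = (g - gm[col] - xhat * gxm[col]) * coef[col]
// [[Rcpp::export(name = ".bn_bwx")]]
NumericMatrix bn_bwx(const NumericMatrix &g, const NumericMatrix &xhat,
                     const NumericVector &gm, const NumericVector &gxm,
                     const NumericVector &coef) {
  const int n = g.nrow(), c = g.ncol();
  NumericMatrix y(n, c);
  for (int j = 0; j < c; ++j) {
    const double *gs = g.begin() + (size_t)j * n;
    const double *xs = xhat.begin() + (size_t)j * n;
    double *dst = y.begin() + (size_t)j * n;
    const double a = gm[j], b = gxm[j], cf = coef[j];
    for (int i = 0; i < n; ++i) dst[i] = (gs[i] - a - xs[i] * b) * cf;
  }
  return y;
}
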