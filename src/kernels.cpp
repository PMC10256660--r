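// Low-level numeric kernels for the ST-V-Net layers.
//
// Array convention (matches the R side): feature maps are dense double
// arrays with dim = c(X, Y, Z, C), column-major, 0-based voxel indices in
// all C++ code.  Convolutions use "same" zero padding; pooling and
// transpose convolutions use kernel 2, stride 2.  Convolutions are
// evaluated as im2col gathers followed by BLAS GEMM (via Armadillo),
// chunked over the slice axis to bound scratch memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Direct "same"-padded convolution, blocked over z-slabs so the working
// set stays in cache; the inner i-loop runs over contiguous memory in
// both the input and the output, which keeps the kernel compute-bound
// at the small channel counts the networks use.
#define CONV_SLAB 4

// valid output range [lo, hi) along one axis for kernel offset d with
// padding p and source extent n
static inline void valid_range(int d, int p, int n, int& lo, int& hi) {
  lo = std::max(0, p - d);
  hi = std::min(n, n + p - d);
}

// linear index of w[0, dj, dk, ci, co] in a (ks,ks,ks,Ci,Co) array
static inline size_t di_base(int ks, int dj, int dk, int ci, int co,
                             int Ci) {
  return ks * ((size_t)dj + ks * ((size_t)dk + ks *
                                  ((size_t)ci + (size_t)Ci * co)));
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xd,
                             NumericVector w, int ks, int Co,
                             NumericVector b) {
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  const int p = (ks - 1) / 2;
  const size_t plane = (size_t)X * Y, volm = plane * Z;
  NumericVector y(volm * Co);
  double* yp = y.begin();
  const double* xp = x.begin();
  const double* wp = w.begin();
  for (int co = 0; co < Co; ++co)
    std::fill(yp + co * volm, yp + (co + 1) * volm, b[co]);
  for (int z0 = 0; z0 < Z; z0 += CONV_SLAB) {
    const int z1 = std::min(Z, z0 + CONV_SLAB);
    for (int ci = 0; ci < Ci; ++ci) {
      const double* xc = xp + ci * volm;
      for (int dk = 0; dk < ks; ++dk) {
        int klo, khi;
        valid_range(dk, p, Z, klo, khi);
        klo = std::max(klo, z0); khi = std::min(khi, z1);
        if (klo >= khi) continue;
        for (int dj = 0; dj < ks; ++dj) {
          int jlo, jhi;
          valid_range(dj, p, Y, jlo, jhi);
          int ilo, ihi;
          for (int co = 0; co < Co; ++co) {
            double* yc = yp + co * volm;
            for (int di = 0; di < ks; ++di) {
              const double wv =
                wp[di + ks * ((size_t)dj + ks * (dk + ks *
                  ((size_t)ci + (size_t)Ci * co)))];
              if (wv == 0.0) continue;
              valid_range(di, p, X, ilo, ihi);
              const int ishift = di - p, jshift = dj - p, kshift = dk - p;
              for (int k = klo; k < khi; ++k) {
                const double* xsl = xc + (size_t)X * (jshift + (size_t)Y *
                                                      (k + kshift)) + ishift;
                double* ysl = yc + (size_t)X * ((size_t)Y * k);
                for (int j = jlo; j < jhi; ++j) {
                  const double* xrow = xsl + (size_t)X * j;
                  double* yrow = ysl + (size_t)X * j;
                  for (int i = ilo; i < ihi; ++i) yrow[i] += wv * xrow[i];
                }
              }
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(X, Y, Z, Co);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xd, NumericVector w,
                    int ks, int Co, NumericVector gy) {
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  const int p = (ks - 1) / 2;
  const size_t plane = (size_t)X * Y, volm = plane * Z;
  NumericVector gx(volm * Ci);
  NumericVector gw(w.size());
  NumericVector gb(Co);
  double* gxp = gx.begin();
  double* gwp = gw.begin();
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gyp = gy.begin();
  for (int co = 0; co < Co; ++co) {
    const double* gc = gyp + co * volm;
    double s = 0.0;
    for (size_t t = 0; t < volm; ++t) s += gc[t];
    gb[co] = s;
  }
  for (int z0 = 0; z0 < Z; z0 += CONV_SLAB) {
    const int z1 = std::min(Z, z0 + CONV_SLAB);
    for (int ci = 0; ci < Ci; ++ci) {
      const double* xc = xp + ci * volm;
      double* gxc = gxp + ci * volm;
      for (int dk = 0; dk < ks; ++dk) {
        int klo, khi;
        valid_range(dk, p, Z, klo, khi);
        klo = std::max(klo, z0); khi = std::min(khi, z1);
        if (klo >= khi) continue;
        for (int dj = 0; dj < ks; ++dj) {
          int jlo, jhi;
          valid_range(dj, p, Y, jlo, jhi);
          int ilo, ihi;
          for (int co = 0; co < Co; ++co) {
            const double* gc = gyp + co * volm;
            const size_t widx = di_base(ks, dj, dk, ci, co, Ci);
            for (int di = 0; di < ks; ++di) {
              const double wv = wp[widx + di];
              valid_range(di, p, X, ilo, ihi);
              const int ishift = di - p, jshift = dj - p, kshift = dk - p;
              double acc = 0.0;
              for (int k = klo; k < khi; ++k) {
                const double* xsl = xc + (size_t)X * (jshift + (size_t)Y *
                                                      (k + kshift)) + ishift;
                double* gxsl = gxc + (size_t)X * (jshift + (size_t)Y *
                                                  (k + kshift)) + ishift;
                const double* gsl = gc + (size_t)X * ((size_t)Y * k);
                for (int j = jlo; j < jhi; ++j) {
                  const double* xrow = xsl + (size_t)X * j;
                  double* gxrow = gxsl + (size_t)X * j;
                  const double* grow = gsl + (size_t)X * j;
                  double a = 0.0;
                  if (wv != 0.0) {
                    for (int i = ilo; i < ihi; ++i) {
                      a += grow[i] * xrow[i];
                      gxrow[i] += wv * grow[i];
                    }
                  } else {
                    for (int i = ilo; i < ihi; ++i) a += grow[i] * xrow[i];
                  }
                  acc += a;
                }
              }
              gwp[widx + di] += acc;
            }
          }
        }
      }
    }
  }
  gw.attr("dim") = w.attr("dim");
  gx.attr("dim") = IntegerVector::create(X, Y, Z, Ci);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Build the (Ci x 8*Co) weight view used by the stride-2 transpose conv.
static arma::mat tconv_wmat(const double* w, int Ci, int Co) {
  arma::mat Wm(Ci, 8 * Co);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int q = 0; q < 8; ++q)
        Wm(ci, q + 8 * co) = w[q + 8 * ci + 8 * (size_t)Ci * co];
  return Wm;
}

// [[Rcpp::export]]
NumericVector cpp_tconv3d_fwd(NumericVector x, IntegerVector xd,
                              NumericVector w, int Co, NumericVector b) {
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  const size_t n = (size_t)X * Y * Z;
  arma::mat Xm(const_cast<double*>(x.begin()), n, Ci, false, true);
  arma::mat Wm = tconv_wmat(w.begin(), Ci, Co);
  arma::mat Y8 = Xm * Wm; // n x 8Co
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector y((size_t)Xo * Yo * Zo * Co);
  for (int co = 0; co < Co; ++co) {
    double* yc = y.begin() + (size_t)co * Xo * Yo * Zo;
    const double bias = b[co];
    for (int q = 0; q < 8; ++q) {
      const int a = q & 1, bb = (q >> 1) & 1, cc = (q >> 2) & 1;
      const double* col = Y8.colptr(q + 8 * co);
      size_t r = 0;
      for (int k = 0; k < Z; ++k)
        for (int j = 0; j < Y; ++j)
          for (int i = 0; i < X; ++i, ++r)
            yc[(size_t)(2 * i + a) +
               (size_t)Xo * ((2 * j + bb) + (size_t)Yo * (2 * k + cc))] = col[r];
    }
    if (bias != 0.0)
      for (size_t t = 0; t < (size_t)Xo * Yo * Zo; ++t) yc[t] += bias;
  }
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Co);
  return y;
}

// [[Rcpp::export]]
List cpp_tconv3d_bwd(NumericVector x, IntegerVector xd, NumericVector w,
                     int Co, NumericVector gy) {
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  const size_t n = (size_t)X * Y * Z;
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  arma::mat Gy8(n, 8 * Co);
  NumericVector gb(Co);
  for (int co = 0; co < Co; ++co) {
    const double* gc = gy.begin() + (size_t)co * Xo * Yo * Zo;
    double s = 0.0;
    for (size_t t = 0; t < (size_t)Xo * Yo * Zo; ++t) s += gc[t];
    gb[co] = s;
    for (int q = 0; q < 8; ++q) {
      const int a = q & 1, bb = (q >> 1) & 1, cc = (q >> 2) & 1;
      double* col = Gy8.colptr(q + 8 * co);
      size_t r = 0;
      for (int k = 0; k < Z; ++k)
        for (int j = 0; j < Y; ++j)
          for (int i = 0; i < X; ++i, ++r)
            col[r] = gc[(size_t)(2 * i + a) +
                        (size_t)Xo * ((2 * j + bb) + (size_t)Yo * (2 * k + cc))];
    }
  }
  arma::mat Xm(const_cast<double*>(x.begin()), n, Ci, false, true);
  arma::mat Wm = tconv_wmat(w.begin(), Ci, Co);
  arma::mat Gx = Gy8 * Wm.t(); // n x Ci
  arma::mat GWm = Xm.t() * Gy8; // Ci x 8Co
  NumericVector gx(n * Ci);
  std::copy(Gx.begin(), Gx.end(), gx.begin());
  gx.attr("dim") = IntegerVector::create(X, Y, Z, Ci);
  NumericVector gw(w.size());
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int q = 0; q < 8; ++q)
        gw[q + 8 * ci + 8 * (size_t)Ci * co] = GWm(ci, q + 8 * co);
  gw.attr("dim") = w.attr("dim");
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x, IntegerVector xd) {
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int fx = X > 1 ? 2 : 1, fy = Y > 1 ? 2 : 1, fz = Z > 1 ? 2 : 1;
  const int Xo = X / fx, Yo = Y / fy, Zo = Z / fz;
  NumericVector y((size_t)Xo * Yo * Zo * C);
  IntegerVector idx((size_t)Xo * Yo * Zo * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * X * Y * Z;
    size_t r = (size_t)c * Xo * Yo * Zo;
    for (int k = 0; k < Zo; ++k)
      for (int j = 0; j < Yo; ++j)
        for (int i = 0; i < Xo; ++i, ++r) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bidx = 0;
          for (int cc = 0; cc < fz; ++cc)
            for (int bb = 0; bb < fy; ++bb)
              for (int a = 0; a < fx; ++a) {
                const size_t src = (size_t)(fx * i + a) +
                  (size_t)X * ((fy * j + bb) + (size_t)Y * (fz * k + cc));
                const double v = xc[src];
                if (v > best) { best = v; bidx = src + (size_t)c * X * Y * Z; }
              }
          y[r] = best;
          idx[r] = (int)bidx;
        }
  }
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(NumericVector gy, IntegerVector idx,
                                IntegerVector xd) {
  NumericVector gx((size_t)xd[0] * xd[1] * xd[2] * xd[3]);
  const size_t n = gy.size();
  for (size_t r = 0; r < n; ++r) gx[idx[r]] += gy[r];
  gx.attr("dim") = xd;
  return gx;
}

// ---- fused batch-norm + ReLU (single volume: statistics over the
// spatial voxels of each channel) ------------------------------------------

// [[Rcpp::export]]
List cpp_bn_relu_fwd(NumericVector x, int n, int C, NumericVector gamma,
                     NumericVector beta, bool training,
                     NumericVector rmean, NumericVector rvar,
                     double eps) {
  NumericVector y((size_t)n * C);
  NumericVector xhat((size_t)n * C);
  NumericVector pre((size_t)n * C);
  NumericVector invstd(C), bmean(C), bvar(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * n;
    double* yc = y.begin() + (size_t)c * n;
    double* xh = xhat.begin() + (size_t)c * n;
    double* pr = pre.begin() + (size_t)c * n;
    double mu, var;
    if (training) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += xc[i];
      mu = s / n;
      double v = 0.0;
      for (int i = 0; i < n; ++i) { const double d = xc[i] - mu; v += d * d; }
      var = v / n;
      bmean[c] = mu;
      bvar[c] = var;
    } else {
      mu = rmean[c];
      var = rvar[c];
    }
    const double iv = 1.0 / std::sqrt(var + eps);
    invstd[c] = iv;
    const double g = gamma[c], b = beta[c];
    for (int i = 0; i < n; ++i) {
      const double h = (xc[i] - mu) * iv;
      xh[i] = h;
      const double o = g * h + b;
      pr[i] = o;
      yc[i] = o > 0.0 ? o : 0.0;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["pre"] = pre,
                      _["invstd"] = invstd, _["bmean"] = bmean,
                      _["bvar"] = bvar);
}

// Backward of ReLU followed by batch-norm backward (training-mode batch
// statistics participate in the gradient).
// [[Rcpp::export]]
List cpp_bn_relu_bwd(NumericVector gy, NumericVector pre,
                     NumericVector xhat, NumericVector invstd,
                     NumericVector gamma, int n, int C) {
  NumericVector gx((size_t)n * C);
  NumericVector ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* gyc = gy.begin() + (size_t)c * n;
    const double* prc = pre.begin() + (size_t)c * n;
    const double* xh = xhat.begin() + (size_t)c * n;
    double* gxc = gx.begin() + (size_t)c * n;
    double sg = 0.0, sgx = 0.0, sy = 0.0;
    for (int i = 0; i < n; ++i) {
      const double g = prc[i] > 0.0 ? gyc[i] : 0.0;
      gxc[i] = g; // stash relu-masked grad
      sg += g;
      sgx += g * xh[i];
    }
    ggamma[c] = sgx;
    gbeta[c] = sg;
    const double gm = gamma[c];
    const double m1 = gm * sg / n;
    const double m2 = gm * sgx / n;
    const double iv = invstd[c];
    for (int i = 0; i < n; ++i)
      gxc[i] = iv * (gm * gxc[i] - m1 - xh[i] * m2);
    (void)sy;
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}

// ---- trilinear sampling (hat-kernel interpolation, zero outside) --------

static inline double src_at(const double* s, int X, int Y, int Z,
                            int i, int j, int k) {
  if (i < 0 || i >= X || j < 0 || j >= Y || k < 0 || k >= Z) return 0.0;
  return s[(size_t)i + (size_t)X * (j + (size_t)Y * k)];
}

// [[Rcpp::export]]
NumericVector cpp_trilinear_fwd(NumericVector src, IntegerVector sd,
                                NumericMatrix coords) {
  const int X = sd[0], Y = sd[1], Z = sd[2];
  const int n = coords.nrow();
  NumericVector out(n);
  const double* s = src.begin();
  for (int t = 0; t < n; ++t) {
    const double xs = coords(t, 0), ys = coords(t, 1), zs = coords(t, 2);
    if (!std::isfinite(xs) || !std::isfinite(ys) || !std::isfinite(zs))
      stop("non-finite sampling coordinate at voxel %d", t + 1);
    const int m0 = (int)std::floor(xs), n0 = (int)std::floor(ys),
              l0 = (int)std::floor(zs);
    const double fx = xs - m0, fy = ys - n0, fz = zs - l0;
    const double wx[2] = {1.0 - fx, fx}, wy[2] = {1.0 - fy, fy},
                 wz[2] = {1.0 - fz, fz};
    double acc = 0.0;
    for (int cc = 0; cc < 2; ++cc)
      for (int bb = 0; bb < 2; ++bb)
        for (int a = 0; a < 2; ++a) {
          const double w = wx[a] * wy[bb] * wz[cc];
          if (w != 0.0)
            acc += w * src_at(s, X, Y, Z, m0 + a, n0 + bb, l0 + cc);
        }
    out[t] = acc;
  }
  return out;
}

// Derivative factor of the hat kernel max(0, 1-|x-m|) w.r.t. x at the two
// enclosing integer nodes; ties (x exactly integer) take the printed
// "x <= m -> +1" branch: d/dx at node m0 is +1 and node m0+1 is outside
// the open support.
static inline void hat_dfac(double f, double* d) {
  if (f > 0.0) { d[0] = -1.0; d[1] = 1.0; }
  else { d[0] = 1.0; d[1] = 0.0; }
}

// [[Rcpp::export]]
List cpp_trilinear_bwd(NumericVector src, IntegerVector sd,
                       NumericMatrix coords, NumericVector gout) {
  const int X = sd[0], Y = sd[1], Z = sd[2];
  const int n = coords.nrow();
  NumericVector gsrc((size_t)X * Y * Z);
  NumericMatrix gcoords(n, 3);
  const double* s = src.begin();
  for (int t = 0; t < n; ++t) {
    const double g = gout[t];
    const double xs = coords(t, 0), ys = coords(t, 1), zs = coords(t, 2);
    const int m0 = (int)std::floor(xs), n0 = (int)std::floor(ys),
              l0 = (int)std::floor(zs);
    const double fx = xs - m0, fy = ys - n0, fz = zs - l0;
    const double wx[2] = {1.0 - fx, fx}, wy[2] = {1.0 - fy, fy},
                 wz[2] = {1.0 - fz, fz};
    double dx[2], dy[2], dz[2];
    hat_dfac(fx, dx); hat_dfac(fy, dy); hat_dfac(fz, dz);
    double gx = 0.0, gy = 0.0, gz = 0.0;
    for (int cc = 0; cc < 2; ++cc)
      for (int bb = 0; bb < 2; ++bb)
        for (int a = 0; a < 2; ++a) {
          const int ii = m0 + a, jj = n0 + bb, kk = l0 + cc;
          const double v = src_at(s, X, Y, Z, ii, jj, kk);
          const double w = wx[a] * wy[bb] * wz[cc];
          if (g != 0.0 && w != 0.0 && ii >= 0 && ii < X && jj >= 0 &&
              jj < Y && kk >= 0 && kk < Z)
            gsrc[(size_t)ii + (size_t)X * (jj + (size_t)Y * kk)] += g * w;
          gx += v * dx[a] * wy[bb] * wz[cc];
          gy += v * wx[a] * dy[bb] * wz[cc];
          gz += v * wx[a] * wy[bb] * dz[cc];
        }
    gcoords(t, 0) = g * gx;
    gcoords(t, 1) = g * gy;
    gcoords(t, 2) = g * gz;
  }
  gsrc.attr("dim") = IntegerVector::create(X, Y, Z);
  return List::create(_["gsrc"] = gsrc, _["gcoords"] = gcoords);
}

// Sparse jacobian of the sampled output: 8 neighbour indices (0-based
// linear into src, -1 when out of bounds) with their hat-kernel weights,
// plus the per-voxel coordinate partials.
// [[Rcpp::export]]
List cpp_trilinear_jac(NumericVector src, IntegerVector sd,
                       NumericMatrix coords) {
  const int X = sd[0], Y = sd[1], Z = sd[2];
  const int n = coords.nrow();
  IntegerMatrix nbr(n, 8);
  NumericMatrix wts(n, 8);
  NumericMatrix dcoords(n, 3);
  const double* s = src.begin();
  for (int t = 0; t < n; ++t) {
    const double xs = coords(t, 0), ys = coords(t, 1), zs = coords(t, 2);
    const int m0 = (int)std::floor(xs), n0 = (int)std::floor(ys),
              l0 = (int)std::floor(zs);
    const double fx = xs - m0, fy = ys - n0, fz = zs - l0;
    const double wx[2] = {1.0 - fx, fx}, wy[2] = {1.0 - fy, fy},
                 wz[2] = {1.0 - fz, fz};
    double dx[2], dy[2], dz[2];
    hat_dfac(fx, dx); hat_dfac(fy, dy); hat_dfac(fz, dz);
    double gx = 0.0, gy = 0.0, gz = 0.0;
    int q = 0;
    for (int cc = 0; cc < 2; ++cc)
      for (int bb = 0; bb < 2; ++bb)
        for (int a = 0; a < 2; ++a, ++q) {
          const int ii = m0 + a, jj = n0 + bb, kk = l0 + cc;
          const bool in = ii >= 0 && ii < X && jj >= 0 && jj < Y &&
                          kk >= 0 && kk < Z;
          nbr(t, q) = in ? (int)((size_t)ii + (size_t)X * (jj + (size_t)Y * kk))
                         : -1;
          wts(t, q) = wx[a] * wy[bb] * wz[cc];
          const double v = src_at(s, X, Y, Z, ii, jj, kk);
          gx += v * dx[a] * wy[bb] * wz[cc];
          gy += v * wx[a] * dy[bb] * wz[cc];
          gz += v * wx[a] * wy[bb] * dz[cc];
        }
    dcoords(t, 0) = gx; dcoords(t, 1) = gy; dcoords(t, 2) = gz;
  }
  return List::create(_["neighbors"] = nbr, _["weights"] = wts,
                      _["dcoords"] = dcoords);
}

// ---- morphology / labelling / surface distances -------------------------

// [[Rcpp::export]]
IntegerVector cpp_dilate3d(IntegerVector mask, IntegerVector md,
                           IntegerVector elem, IntegerVector ed) {
  const int X = md[0], Y = md[1], Z = md[2];
  const int A = ed[0], B = ed[1], C = ed[2];
  const int pa = (A - 1) / 2, pb = (B - 1) / 2, pc = (C - 1) / 2;
  IntegerVector out((size_t)X * Y * Z);
  std::vector<std::array<int, 3>> offs;
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < B; ++b)
      for (int a = 0; a < A; ++a)
        if (elem[(size_t)a + (size_t)A * (b + (size_t)B * c)] != 0)
          offs.push_back({a - pa, b - pb, c - pc});
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        if (mask[(size_t)i + (size_t)X * (j + (size_t)Y * k)] == 0) continue;
        for (const auto& o : offs) {
          const int ii = i + o[0], jj = j + o[1], kk = k + o[2];
          if (ii >= 0 && ii < X && jj >= 0 && jj < Y && kk >= 0 && kk < Z)
            out[(size_t)ii + (size_t)X * (jj + (size_t)Y * kk)] = 1;
        }
      }
  out.attr("dim") = md;
  return out;
}

// 6-connected component labelling (BFS), labels 1..ncomp, 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label6(IntegerVector mask, IntegerVector md) {
  const int X = md[0], Y = md[1], Z = md[2];
  const size_t n = (size_t)X * Y * Z;
  IntegerVector lab(n);
  std::vector<size_t> queue;
  int next = 0;
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  for (size_t s0 = 0; s0 < n; ++s0) {
    if (mask[s0] == 0 || lab[s0] != 0) continue;
    ++next;
    lab[s0] = next;
    queue.clear();
    queue.push_back(s0);
    while (!queue.empty()) {
      const size_t cur = queue.back();
      queue.pop_back();
      const int i = cur % X, j = (cur / X) % Y, k = cur / ((size_t)X * Y);
      for (int d = 0; d < 6; ++d) {
        const int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
        if (ii < 0 || ii >= X || jj < 0 || jj >= Y || kk < 0 || kk >= Z)
          continue;
        const size_t t = (size_t)ii + (size_t)X * (jj + (size_t)Y * kk);
        if (mask[t] != 0 && lab[t] == 0) { lab[t] = next; queue.push_back(t); }
      }
    }
  }
  lab.attr("dim") = md;
  return lab;
}

// For each row of a, the minimum Euclidean distance to any row of b.
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    const double x = a(i, 0), y = a(i, 1), z = a(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dx = x - b(j, 0), dy = y - b(j, 1), dz = z - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
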