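// Compiled kernels: 2D convolution forward/backward, 2x2 max pooling,
// nearest-neighbour upsampling, cubic B-spline volume resampling with
// causal/anticausal prefiltering, separable Gaussian smoothing, 3D
// connected components and binary ball morphology.
//
// Array conventions
//   Network tensors: numeric 4D arrays dim (H, W, C, N), column major.
//   Volumes:         numeric 3D arrays dim (nx, ny, nz), column major.
// All indices in C++ are 0-based; the R wrappers are 1-based.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline int idx4(int i, int j, int c, int n, int H, int W, int C) {
  return i + H * (j + W * (c + C * n));
}

// ---------------------------------------------------------------------------
// conv2d, stride 1, 'same' zero padding
// x: (H, W, Cin, N); w: (KH, KW, Cin, Cout); b: (Cout)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], Cout = wd[3];
  const int ph = KH / 2, pw = KW / 2;
  NumericVector y(static_cast<R_xlen_t>(H) * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  const double *px = x.begin(), *pw_ = w.begin(), *pb = b.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          double acc = pb[co];
          for (int ci = 0; ci < Cin; ++ci)
            for (int kj = 0; kj < KW; ++kj) {
              const int jj = j + kj - pw;
              if (jj < 0 || jj >= W) continue;
              for (int ki = 0; ki < KH; ++ki) {
                const int ii = i + ki - ph;
                if (ii < 0 || ii >= H) continue;
                acc += px[idx4(ii, jj, ci, n, H, W, Cin)] *
                       pw_[ki + KH * (kj + KW * (ci + Cin * co))];
              }
            }
          py[idx4(i, j, co, n, H, W, Cout)] = acc;
        }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], Cout = wd[3];
  const int ph = KH / 2, pw = KW / 2;
  NumericVector dx(x.size()), dw(w.size()), db(Cout);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  const double *px = x.begin(), *pw_ = w.begin(), *pdy = dy.begin();
  double *pdx = dx.begin(), *pdw = dw.begin(), *pdb = db.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const double g = pdy[idx4(i, j, co, n, H, W, Cout)];
          if (g == 0.0) continue;
          pdb[co] += g;
          for (int ci = 0; ci < Cin; ++ci)
            for (int kj = 0; kj < KW; ++kj) {
              const int jj = j + kj - pw;
              if (jj < 0 || jj >= W) continue;
              for (int ki = 0; ki < KH; ++ki) {
                const int ii = i + ki - ph;
                if (ii < 0 || ii >= H) continue;
                const int xi = idx4(ii, jj, ci, n, H, W, Cin);
                const int wi = ki + KH * (kj + KW * (ci + Cin * co));
                pdw[wi] += px[xi] * g;
                pdx[xi] += pw_[wi] * g;
              }
            }
        }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---------------------------------------------------------------------------
// 2x2 max pooling, stride 2 (H, W even)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_maxpool2_fwd")]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  IntegerVector arg(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *px = x.begin();
  double *py = y.begin();
  int *pa = arg.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          double best = -1e300;
          int besti = -1;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              const int xi = idx4(2 * i + di, 2 * j + dj, c, n, H, W, C);
              if (px[xi] > best) { best = px[xi]; besti = xi; }
            }
          const int yi = idx4(i, j, c, n, Ho, Wo, C);
          py[yi] = best;
          pa[yi] = besti;
        }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bwd")]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector arg,
                               IntegerVector xdim) {
  R_xlen_t nx = 1;
  for (int k = 0; k < xdim.size(); ++k) nx *= xdim[k];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  double *pdx = dx.begin();
  const double *pdy = dy.begin();
  const int *pa = arg.begin();
  for (R_xlen_t t = 0; t < dy.size(); ++t) pdx[pa[t]] += pdy[t];
  return dx;
}

// ---------------------------------------------------------------------------
// nearest-neighbour 2x upsampling
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_upsample2_fwd")]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(static_cast<R_xlen_t>(4) * H * W * C * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  const double *px = x.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < 2 * W; ++j)
        for (int i = 0; i < 2 * H; ++i)
          py[idx4(i, j, c, n, 2 * H, 2 * W, C)] =
              px[idx4(i / 2, j / 2, c, n, H, W, C)];
  return y;
}

// [[Rcpp::export(name = ".cpp_upsample2_bwd")]]
NumericVector cpp_upsample2_bwd(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int H = yd[0] / 2, W = yd[1] / 2, C = yd[2], N = yd[3];
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double *pdy = dy.begin();
  double *pdx = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < 2 * W; ++j)
        for (int i = 0; i < 2 * H; ++i)
          pdx[idx4(i / 2, j / 2, c, n, H, W, C)] +=
              pdy[idx4(i, j, c, n, 2 * H, 2 * W, C)];
  return dx;
}

// ---------------------------------------------------------------------------
// cubic B-spline prefilter (Unser et al. recursive filtering, mirror
// boundaries) and trilinear / cubic / nearest resampling of 3D volumes
// ---------------------------------------------------------------------------

static void prefilter_line(std::vector<double> &c) {
  const int n = static_cast<int>(c.size());
  if (n < 2) return;
  const double z1 = std::sqrt(3.0) - 2.0;  // pole of the cubic B-spline
  const double lambda = 6.0;
  for (int k = 0; k < n; ++k) c[k] *= lambda;
  // causal initialization: mirror-boundary geometric sum (truncated for
  // long lines, exact full-period formula for short ones)
  const double tol = 1e-14;
  const int hmax = static_cast<int>(std::ceil(std::log(tol) / std::log(std::fabs(z1))));
  double sum;
  if (hmax < n) {
    sum = c[0];
    double zk = z1;
    for (int k = 1; k < hmax; ++k) { sum += zk * c[k]; zk *= z1; }
  } else {
    const double z2n = std::pow(z1, 2.0 * n - 2.0);
    sum = c[0] + std::pow(z1, n - 1.0) * c[n - 1];
    double zk = z1, zr = z2n / z1;
    for (int k = 1; k <= n - 2; ++k) {
      sum += (zk + zr) * c[k];
      zk *= z1;
      zr /= z1;
    }
    sum /= (1.0 - z2n);
  }
  c[0] = sum;
  for (int k = 1; k < n; ++k) c[k] += z1 * c[k - 1];
  c[n - 1] = (z1 / (z1 * z1 - 1.0)) * (c[n - 1] + z1 * c[n - 2]);
  for (int k = n - 2; k >= 0; --k) c[k] = z1 * (c[k + 1] - c[k]);
}

// [[Rcpp::export(name = ".cpp_bspline_prefilter3d")]]
NumericVector cpp_bspline_prefilter3d(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2];
  NumericVector out = clone(x);
  double *p = out.begin();
  std::vector<double> line;
  // x lines
  line.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double *base = p + static_cast<R_xlen_t>(nx) * (j + static_cast<R_xlen_t>(ny) * k);
      for (int i = 0; i < nx; ++i) line[i] = base[i];
      prefilter_line(line);
      for (int i = 0; i < nx; ++i) base[i] = line[i];
    }
  // y lines
  line.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j)
        line[j] = p[i + static_cast<R_xlen_t>(nx) * (j + static_cast<R_xlen_t>(ny) * k)];
      prefilter_line(line);
      for (int j = 0; j < ny; ++j)
        p[i + static_cast<R_xlen_t>(nx) * (j + static_cast<R_xlen_t>(ny) * k)] = line[j];
    }
  // z lines
  line.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k)
        line[k] = p[i + static_cast<R_xlen_t>(nx) * (j + static_cast<R_xlen_t>(ny) * k)];
      prefilter_line(line);
      for (int k = 0; k < nz; ++k)
        p[i + static_cast<R_xlen_t>(nx) * (j + static_cast<R_xlen_t>(ny) * k)] = line[k];
    }
  return out;
}

static inline int mirror(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n - 2;
  i = std::abs(i) % period;
  return (i < n) ? i : period - i;
}

static inline void cubic_w(double t, double w[4]) {
  const double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

// M maps 0-based target voxel (i,j,k,1) to 0-based source voxel coordinates.
// order: 0 nearest, 1 trilinear, 3 cubic B-spline (x must be prefiltered).
// [[Rcpp::export(name = ".cpp_resample3d")]]
NumericVector cpp_resample3d(NumericVector x, NumericMatrix M,
                             IntegerVector odim, int order, double background) {
  IntegerVector xd = x.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2];
  const int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out(static_cast<R_xlen_t>(ox) * oy * oz, background);
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  const double *px = x.begin();
  double *po = out.begin();
  const double eps = 1e-9;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        const double sx = M(0, 0) * i + M(0, 1) * j + M(0, 2) * k + M(0, 3);
        const double sy = M(1, 0) * i + M(1, 1) * j + M(1, 2) * k + M(1, 3);
        const double sz = M(2, 0) * i + M(2, 1) * j + M(2, 2) * k + M(2, 3);
        if (sx < -eps || sx > nx - 1 + eps || sy < -eps || sy > ny - 1 + eps ||
            sz < -eps || sz > nz - 1 + eps)
          continue;  // keep background outside the source domain
        double v = 0.0;
        if (order == 0) {
          const int ii = mirror(static_cast<int>(std::lround(sx)), nx);
          const int jj = mirror(static_cast<int>(std::lround(sy)), ny);
          const int kk = mirror(static_cast<int>(std::lround(sz)), nz);
          v = px[ii + static_cast<R_xlen_t>(nx) * (jj + static_cast<R_xlen_t>(ny) * kk)];
        } else if (order == 1) {
          const int i0 = static_cast<int>(std::floor(sx));
          const int j0 = static_cast<int>(std::floor(sy));
          const int k0 = static_cast<int>(std::floor(sz));
          const double tx = sx - i0, ty = sy - j0, tz = sz - k0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                const double w = (di ? tx : 1 - tx) * (dj ? ty : 1 - ty) *
                                 (dk ? tz : 1 - tz);
                if (w == 0.0) continue;
                const int ii = mirror(i0 + di, nx), jj = mirror(j0 + dj, ny),
                          kk = mirror(k0 + dk, nz);
                v += w * px[ii + static_cast<R_xlen_t>(nx) *
                                   (jj + static_cast<R_xlen_t>(ny) * kk)];
              }
        } else {
          const int i0 = static_cast<int>(std::floor(sx));
          const int j0 = static_cast<int>(std::floor(sy));
          const int k0 = static_cast<int>(std::floor(sz));
          double wx[4], wy[4], wz[4];
          cubic_w(sx - i0, wx);
          cubic_w(sy - j0, wy);
          cubic_w(sz - k0, wz);
          for (int dk = 0; dk < 4; ++dk) {
            const int kk = mirror(k0 - 1 + dk, nz);
            for (int dj = 0; dj < 4; ++dj) {
              const int jj = mirror(j0 - 1 + dj, ny);
              const double wyz = wy[dj] * wz[dk];
              if (wyz == 0.0) continue;
              for (int di = 0; di < 4; ++di) {
                const int ii = mirror(i0 - 1 + di, nx);
                v += wx[di] * wyz *
                     px[ii + static_cast<R_xlen_t>(nx) *
                              (jj + static_cast<R_xlen_t>(ny) * kk)];
              }
            }
          }
        }
        po[i + static_cast<R_xlen_t>(ox) * (j + static_cast<R_xlen_t>(oy) * k)] = v;
      }
  return out;
}

// ---------------------------------------------------------------------------
// separable Gaussian smoothing, reflect boundary; sigma per axis in voxels
// ---------------------------------------------------------------------------

static void gauss_axis(std::vector<double> &buf, const std::vector<double> &ker) {
  const int n = static_cast<int>(buf.size());
  const int r = (static_cast<int>(ker.size()) - 1) / 2;
  std::vector<double> out(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int d = -r; d <= r; ++d) acc += ker[d + r] * buf[mirror(i + d, n)];
    out[i] = acc;
  }
  buf.swap(out);
}

// [[Rcpp::export(name = ".cpp_gaussian3d")]]
NumericVector cpp_gaussian3d(NumericVector x, NumericVector sigma) {
  IntegerVector xd = x.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2];
  NumericVector out = clone(x);
  double *p = out.begin();
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0.0) continue;
    const int r = std::max(1, static_cast<int>(std::ceil(3.5 * s)));
    std::vector<double> ker(2 * r + 1);
    double ksum = 0.0;
    for (int d = -r; d <= r; ++d) {
      ker[d + r] = std::exp(-0.5 * d * d / (s * s));
      ksum += ker[d + r];
    }
    for (double &kv : ker) kv /= ksum;
    if (ax == 0) {
      std::vector<double> line(nx);
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
          double *base = p + static_cast<R_xlen_t>(nx) * (j + static_cast<R_xlen_t>(ny) * k);
          for (int i = 0; i < nx; ++i) line[i] = base[i];
          gauss_axis(line, ker);
          for (int i = 0; i < nx; ++i) base[i] = line[i];
        }
    } else if (ax == 1) {
      std::vector<double> line(ny);
      for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i) {
          for (int j = 0; j < ny; ++j)
            line[j] = p[i + static_cast<R_xlen_t>(nx) * (j + static_cast<R_xlen_t>(ny) * k)];
          gauss_axis(line, ker);
          for (int j = 0; j < ny; ++j)
            p[i + static_cast<R_xlen_t>(nx) * (j + static_cast<R_xlen_t>(ny) * k)] = line[j];
        }
    } else {
      std::vector<double> line(nz);
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          for (int k = 0; k < nz; ++k)
            line[k] = p[i + static_cast<R_xlen_t>(nx) * (j + static_cast<R_xlen_t>(ny) * k)];
          gauss_axis(line, ker);
          for (int k = 0; k < nz; ++k)
            p[i + static_cast<R_xlen_t>(nx) * (j + static_cast<R_xlen_t>(ny) * k)] = line[k];
        }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 3D connected components (6 or 26 connectivity), BFS labelling
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_cc3d")]]
IntegerVector cpp_cc3d(IntegerVector mask, int connectivity) {
  IntegerVector xd = mask.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  lab.attr("dim") = xd;
  std::vector<int> offs;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        const int man = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && man > 1) continue;
        offs.push_back(di);
        offs.push_back(dj);
        offs.push_back(dk);
      }
  const int *pm = mask.begin();
  int *pl = lab.begin();
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (pm[s] == 0 || pl[s] != 0) continue;
    ++next;
    pl[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int i = static_cast<int>(cur % nx);
      const int j = static_cast<int>((cur / nx) % ny);
      const int k = static_cast<int>(cur / (static_cast<R_xlen_t>(nx) * ny));
      for (size_t o = 0; o < offs.size(); o += 3) {
        const int ii = i + offs[o], jj = j + offs[o + 1], kk = k + offs[o + 2];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        const R_xlen_t t = ii + static_cast<R_xlen_t>(nx) * (jj + static_cast<R_xlen_t>(ny) * kk);
        if (pm[t] != 0 && pl[t] == 0) {
          pl[t] = next;
          stack.push_back(t);
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// binary morphology with a voxel ball of given radius; op 0 erode, 1 dilate.
// Outside the volume counts as background.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_morph3d")]]
IntegerVector cpp_morph3d(IntegerVector mask, int radius, int op) {
  IntegerVector xd = mask.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2];
  IntegerVector out(mask.size(), 0);
  out.attr("dim") = xd;
  std::vector<int> offs;
  for (int dk = -radius; dk <= radius; ++dk)
    for (int dj = -radius; dj <= radius; ++dj)
      for (int di = -radius; di <= radius; ++di)
        if (di * di + dj * dj + dk * dk <= radius * radius) {
          offs.push_back(di);
          offs.push_back(dj);
          offs.push_back(dk);
        }
  const int *pm = mask.begin();
  int *po = out.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        bool any = false, all = true;
        for (size_t o = 0; o < offs.size(); o += 3) {
          const int ii = i + offs[o], jj = j + offs[o + 1], kk = k + offs[o + 2];
          int v = 0;
          if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz)
            v = pm[ii + static_cast<R_xlen_t>(nx) * (jj + static_cast<R_xlen_t>(ny) * kk)];
          if (v) any = true; else all = false;
          if (op == 1 && any) break;
          if (op == 0 && !all) break;
        }
        po[i + static_cast<R_xlen_t>(nx) * (j + static_cast<R_xlen_t>(ny) * k)] =
            (op == 1) ? (any ? 1 : 0) : (all ? 1 : 0);
      }
  return out;
}
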