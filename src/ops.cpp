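#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Array layout everywhere: column-major R arrays, spatial dims first,
// channel last: x[ix + nx*(iy + ny*(iz + nz*c))].

static inline R_xlen_t idx4(int ix, int iy, int iz, int c,
                            int nx, int ny, int nz) {
  return (R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * (iz + (R_xlen_t)nz * c));
}

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                             IntegerVector xdim, IntegerVector wdim) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], ci_n = xdim[3];
  const int k = wdim[0], co_n = wdim[4];
  const int pad = (k - 1) / 2;
  NumericVector y((R_xlen_t)nx * ny * nz * co_n);
  const double *X = x.begin(), *W = w.begin(), *B = b.begin();
  double *Y = y.begin();
  for (int co = 0; co < co_n; ++co) {
    const double bco = B[co];
    for (int iz = 0; iz < nz; ++iz) {
      for (int iy = 0; iy < ny; ++iy) {
        for (int ix = 0; ix < nx; ++ix) {
          double acc = bco;
          for (int ci = 0; ci < ci_n; ++ci) {
            for (int kz = 0; kz < k; ++kz) {
              const int jz = iz + kz - pad;
              if (jz < 0 || jz >= nz) continue;
              for (int ky = 0; ky < k; ++ky) {
                const int jy = iy + ky - pad;
                if (jy < 0 || jy >= ny) continue;
                const R_xlen_t xbase = idx4(0, jy, jz, ci, nx, ny, nz);
                const R_xlen_t wbase = (R_xlen_t)k * (ky + (R_xlen_t)k * (kz + (R_xlen_t)k * (ci + (R_xlen_t)ci_n * co)));
                for (int kx = 0; kx < k; ++kx) {
                  const int jx = ix + kx - pad;
                  if (jx < 0 || jx >= nx) continue;
                  acc += X[xbase + jx] * W[wbase + kx];
                }
              }
            }
          }
          Y[idx4(ix, iy, iz, co, nx, ny, nz)] = acc;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(nx, ny, nz, co_n);
  return y;
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    IntegerVector xdim, IntegerVector wdim) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], ci_n = xdim[3];
  const int k = wdim[0], co_n = wdim[4];
  const int pad = (k - 1) / 2;
  NumericVector dx((R_xlen_t)nx * ny * nz * ci_n);
  NumericVector dw(w.size());
  NumericVector db(co_n);
  const double *X = x.begin(), *W = w.begin(), *DY = dy.begin();
  double *DX = dx.begin(), *DW = dw.begin(), *DB = db.begin();
  for (int co = 0; co < co_n; ++co) {
    double dbacc = 0.0;
    for (int iz = 0; iz < nz; ++iz) {
      for (int iy = 0; iy < ny; ++iy) {
        for (int ix = 0; ix < nx; ++ix) {
          const double g = DY[idx4(ix, iy, iz, co, nx, ny, nz)];
          dbacc += g;
          if (g == 0.0) continue;
          for (int ci = 0; ci < ci_n; ++ci) {
            for (int kz = 0; kz < k; ++kz) {
              const int jz = iz + kz - pad;
              if (jz < 0 || jz >= nz) continue;
              for (int ky = 0; ky < k; ++ky) {
                const int jy = iy + ky - pad;
                if (jy < 0 || jy >= ny) continue;
                const R_xlen_t xbase = idx4(0, jy, jz, ci, nx, ny, nz);
                const R_xlen_t wbase = (R_xlen_t)k * (ky + (R_xlen_t)k * (kz + (R_xlen_t)k * (ci + (R_xlen_t)ci_n * co)));
                for (int kx = 0; kx < k; ++kx) {
                  const int jx = ix + kx - pad;
                  if (jx < 0 || jx >= nx) continue;
                  DX[xbase + jx] += W[wbase + kx] * g;
                  DW[wbase + kx] += X[xbase + jx] * g;
                }
              }
            }
          }
        }
      }
    }
    DB[co] = dbacc;
  }
  dx.attr("dim") = IntegerVector::create(nx, ny, nz, ci_n);
  dw.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2x2 max pooling; spatial dims must be even.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x, IntegerVector xdim) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], nc = xdim[3];
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  NumericVector y((R_xlen_t)ox * oy * oz * nc);
  IntegerVector amax(y.size());
  const double *X = x.begin();
  double *Y = y.begin();
  int *A = amax.begin();
  R_xlen_t o = 0;
  for (int c = 0; c < nc; ++c)
    for (int iz = 0; iz < oz; ++iz)
      for (int iy = 0; iy < oy; ++iy)
        for (int ix = 0; ix < ox; ++ix, ++o) {
          double best = -std::numeric_limits<double>::infinity();
          R_xlen_t besti = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy_ = 0; dy_ < 2; ++dy_)
              for (int dx_ = 0; dx_ < 2; ++dx_) {
                R_xlen_t ii = idx4(2 * ix + dx_, 2 * iy + dy_, 2 * iz + dz, c, nx, ny, nz);
                if (X[ii] > best) { best = X[ii]; besti = ii; }
              }
          Y[o] = best;
          A[o] = (int)besti; // fits: grids here are far below 2^31 voxels
        }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dy, IntegerVector amax, IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  double *DX = dx.begin();
  const double *DY = dy.begin();
  const int *A = amax.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) DX[A[i]] += DY[i];
  dx.attr("dim") = xdim;
  return dx;
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export]]
NumericVector upsample2_fwd_cpp(NumericVector x, IntegerVector xdim) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], nc = xdim[3];
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  NumericVector y((R_xlen_t)ox * oy * oz * nc);
  const double *X = x.begin();
  double *Y = y.begin();
  for (int c = 0; c < nc; ++c)
    for (int iz = 0; iz < oz; ++iz)
      for (int iy = 0; iy < oy; ++iy)
        for (int ix = 0; ix < ox; ++ix)
          Y[idx4(ix, iy, iz, c, ox, oy, oz)] =
            X[idx4(ix / 2, iy / 2, iz / 2, c, nx, ny, nz)];
  y.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd_cpp(NumericVector dy, IntegerVector ydim) {
  const int ox = ydim[0], oy = ydim[1], oz = ydim[2], nc = ydim[3];
  const int nx = ox / 2, ny = oy / 2, nz = oz / 2;
  NumericVector dx((R_xlen_t)nx * ny * nz * nc);
  const double *DY = dy.begin();
  double *DX = dx.begin();
  for (int c = 0; c < nc; ++c)
    for (int iz = 0; iz < oz; ++iz)
      for (int iy = 0; iy < oy; ++iy)
        for (int ix = 0; ix < ox; ++ix)
          DX[idx4(ix / 2, iy / 2, iz / 2, c, nx, ny, nz)] +=
            DY[idx4(ix, iy, iz, c, ox, oy, oz)];
  dx.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  return dx;
}

// ---- anisotropic squared Euclidean distance transform -----------------
// Felzenszwalb & Huttenlocher lower-envelope 1D transform, run per axis
// with squared physical spacing as the parabola width.

static void dt1d(std::vector<double> &f, std::vector<double> &d, double s2) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int q0 = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const int p = v[q0];
      s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (s <= z[q0]) { --q0; } else break;
    }
    ++q0;
    v[q0] = q;
    z[q0] = s;
    z[q0 + 1] = std::numeric_limits<double>::infinity();
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    const int p = v[j];
    d[q] = s2 * (q - p) * (q - p) + f[p];
  }
}

// squared distance (mm^2) from each voxel centre to the nearest nonzero
// voxel centre of `mask`; Inf everywhere when mask is empty.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(NumericVector mask, IntegerVector mdim, NumericVector spacing) {
  const int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // large finite sentinel: Inf breaks the lower-envelope intersection
  // (Inf - Inf = NaN), so absent distances stay finite until the end
  const double INF = 1e20;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (mask[i] > 0.5) ? 0.0 : INF;
  std::vector<double> f, d;
  // x axis
  f.resize(nx); d.resize(nx);
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      const R_xlen_t base = (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
      bool any = false;
      for (int ix = 0; ix < nx; ++ix) { f[ix] = out[base + ix]; if (f[ix] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, spacing[0] * spacing[0]);
      for (int ix = 0; ix < nx; ++ix) out[base + ix] = d[ix];
    }
  // y axis
  f.resize(ny); d.resize(ny);
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      bool any = false;
      for (int iy = 0; iy < ny; ++iy) {
        f[iy] = out[(R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
        if (f[iy] < INF) any = true;
      }
      if (!any) continue;
      dt1d(f, d, spacing[1] * spacing[1]);
      for (int iy = 0; iy < ny; ++iy)
        out[(R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] = d[iy];
    }
  // z axis
  f.resize(nz); d.resize(nz);
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      bool any = false;
      for (int iz = 0; iz < nz; ++iz) {
        f[iz] = out[(R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
        if (f[iz] < INF) any = true;
      }
      if (!any) continue;
      dt1d(f, d, spacing[2] * spacing[2]);
      for (int iz = 0; iz < nz; ++iz)
        out[(R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] = d[iz];
    }
  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] >= 1e19) out[i] = std::numeric_limits<double>::infinity();
  out.attr("dim") = mdim;
  return out;
}

// connected-component labelling, connectivity 6 or 26
// [[Rcpp::export]]
IntegerVector label_components_cpp(NumericVector mask, IntegerVector mdim, int connectivity) {
  const int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (mask[seed] <= 0.5 || lab[seed] != 0) continue;
    ++cur;
    lab[seed] = cur;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      const R_xlen_t p = stack.back();
      stack.pop_back();
      const int ix = (int)(p % nx);
      const int iy = (int)((p / nx) % ny);
      const int iz = (int)(p / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1) continue;
            const int jx = ix + dx, jy = iy + dy, jz = iz + dz;
            if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz) continue;
            const R_xlen_t q = (R_xlen_t)jx + (R_xlen_t)nx * (jy + (R_xlen_t)ny * jz);
            if (mask[q] > 0.5 && lab[q] == 0) { lab[q] = cur; stack.push_back(q); }
          }
    }
  }
  lab.attr("dim") = mdim;
  return lab;
}

// separable Gaussian smoothing; truncated kernel renormalised at edges
// [[Rcpp::export]]
NumericVector gauss_smooth_cpp(NumericVector x, IntegerVector mdim, NumericVector sigma_vox) {
  const int nd[3] = { mdim[0], mdim[1], mdim[2] };
  NumericVector cur = clone(x);
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma_vox[ax];
    if (s <= 0) continue;
    const int r = (int)std::ceil(3.0 * s);
    std::vector<double> kern(2 * r + 1);
    for (int i = -r; i <= r; ++i) kern[i + r] = std::exp(-0.5 * i * i / (s * s));
    NumericVector nxt(cur.size());
    const int nx = nd[0], ny = nd[1], nz = nd[2];
    for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix) {
          double acc = 0.0, wsum = 0.0;
          const int pos[3] = { ix, iy, iz };
          for (int o = -r; o <= r; ++o) {
            int jp[3] = { ix, iy, iz };
            jp[ax] = pos[ax] + o;
            if (jp[ax] < 0 || jp[ax] >= nd[ax]) continue;
            const double w = kern[o + r];
            acc += w * cur[(R_xlen_t)jp[0] + (R_xlen_t)nx * (jp[1] + (R_xlen_t)ny * jp[2])];
            wsum += w;
          }
          nxt[(R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] = acc / wsum;
        }
    cur = nxt;
  }
  cur.attr("dim") = mdim;
  return cur;
}
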