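#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Volumes are stored as N x C matrices (N = dx*dy*dz voxels, column-major,
// x fastest) with the grid dimensions passed separately.  Convolutions are
// lowered to matrix products via im2col; the patch-matrix column for input
// channel c and kernel offset (kx,ky,kz) is c*k^3 + kx + k*(ky + k*kz).

static inline int out_len(int n, int k, int stride, int plo, int phi) {
  return (n + plo + phi - k) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col3(const NumericMatrix& x, const IntegerVector& dim,
                      int k, int stride, int plo, int phi) {
  const int dx = dim[0], dy = dim[1], dz = dim[2], C = x.ncol();
  const int ox = out_len(dx, k, stride, plo, phi);
  const int oy = out_len(dy, k, stride, plo, phi);
  const int oz = out_len(dz, k, stride, plo, phi);
  const int nout = ox * oy * oz, k3 = k * k * k;
  NumericMatrix cols(nout, C * k3);
  const double* xp = x.begin();
  double* cp = cols.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (R_xlen_t)c * dx * dy * dz;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const int col = c * k3 + kx + k * (ky + k * kz);
          double* dst = cp + (R_xlen_t)col * nout;
          for (int z = 0; z < oz; ++z) {
            const int iz = z * stride - plo + kz;
            for (int y = 0; y < oy; ++y) {
              const int iy = y * stride - plo + ky;
              double* row = dst + (R_xlen_t)(y + oy * z) * ox;
              if (iz < 0 || iz >= dz || iy < 0 || iy >= dy) {
                for (int xx = 0; xx < ox; ++xx) row[xx] = 0.0;
              } else {
                const double* src = xc + (R_xlen_t)(iy + dy * iz) * dx;
                for (int xx = 0; xx < ox; ++xx) {
                  const int ix = xx * stride - plo + kx;
                  row[xx] = (ix < 0 || ix >= dx) ? 0.0 : src[ix];
                }
              }
            }
          }
        }
  }
  return cols;
}

// [[Rcpp::export]]
NumericMatrix col2im3(const NumericMatrix& cols, const IntegerVector& dim,
                      int C, int k, int stride, int plo, int phi) {
  const int dx = dim[0], dy = dim[1], dz = dim[2];
  const int ox = out_len(dx, k, stride, plo, phi);
  const int oy = out_len(dy, k, stride, plo, phi);
  const int oz = out_len(dz, k, stride, plo, phi);
  const int nout = ox * oy * oz, k3 = k * k * k;
  NumericMatrix out(dx * dy * dz, C);
  const double* cp = cols.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    double* xc = op + (R_xlen_t)c * dx * dy * dz;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const int col = c * k3 + kx + k * (ky + k * kz);
          const double* src = cp + (R_xlen_t)col * nout;
          for (int z = 0; z < oz; ++z) {
            const int iz = z * stride - plo + kz;
            if (iz < 0 || iz >= dz) continue;
            for (int y = 0; y < oy; ++y) {
              const int iy = y * stride - plo + ky;
              if (iy < 0 || iy >= dy) continue;
              const double* row = src + (R_xlen_t)(y + oy * z) * ox;
              double* dst = xc + (R_xlen_t)(iy + dy * iz) * dx;
              for (int xx = 0; xx < ox; ++xx) {
                const int ix = xx * stride - plo + kx;
                if (ix >= 0 && ix < dx) dst[ix] += row[xx];
              }
            }
          }
        }
  }
  return out;
}

// 2x2x2 max pooling; idx records the 1-based input row of each maximum so
// the backward pass can scatter gradients.
// [[Rcpp::export]]
List maxpool3_fwd(const NumericMatrix& x, const IntegerVector& dim) {
  const int dx = dim[0], dy = dim[1], dz = dim[2], C = x.ncol();
  const int ox = dx / 2, oy = dy / 2, oz = dz / 2;
  const int nout = ox * oy * oz;
  NumericMatrix out(nout, C);
  IntegerMatrix idx(nout, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (R_xlen_t)c * dx * dy * dz;
    double* oc = out.begin() + (R_xlen_t)c * nout;
    int* ic = idx.begin() + (R_xlen_t)c * nout;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int xx = 0; xx < ox; ++xx) {
          double best = -std::numeric_limits<double>::infinity();
          int bi = -1;
          for (int pz = 0; pz < 2; ++pz)
            for (int py = 0; py < 2; ++py)
              for (int px = 0; px < 2; ++px) {
                const int i = (2 * xx + px) + dx * ((2 * y + py) + dy * (2 * z + pz));
                if (xc[i] > best) { best = xc[i]; bi = i; }
              }
          const int o = xx + ox * (y + oy * z);
          oc[o] = best;
          ic[o] = bi + 1;
        }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix maxpool3_bwd(const NumericMatrix& g, const IntegerMatrix& idx,
                           int nin) {
  const int nout = g.nrow(), C = g.ncol();
  NumericMatrix gx(nin, C);
  for (int c = 0; c < C; ++c)
    for (int o = 0; o < nout; ++o)
      gx(idx(o, c) - 1, c) += g(o, c);
  return gx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
NumericMatrix upnn3_fwd(const NumericMatrix& x, const IntegerVector& dim) {
  const int dx = dim[0], dy = dim[1], dz = dim[2], C = x.ncol();
  const int ox = 2 * dx, oy = 2 * dy, oz = 2 * dz;
  NumericMatrix out((R_xlen_t)ox * oy * oz, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (R_xlen_t)c * dx * dy * dz;
    double* oc = out.begin() + (R_xlen_t)c * ox * oy * oz;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y) {
        const double* src = xc + (R_xlen_t)((y / 2) + dy * (z / 2)) * dx;
        double* dst = oc + (R_xlen_t)(y + oy * z) * ox;
        for (int xx = 0; xx < ox; ++xx) dst[xx] = src[xx / 2];
      }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix upnn3_bwd(const NumericMatrix& g, const IntegerVector& dim_in) {
  const int dx = dim_in[0], dy = dim_in[1], C = g.ncol();
  const int ox = 2 * dx, oy = 2 * dy;
  NumericMatrix gx((R_xlen_t)dx * dy * dim_in[2], C);
  const int oz = 2 * dim_in[2];
  for (int c = 0; c < C; ++c) {
    const double* gc = g.begin() + (R_xlen_t)c * ox * oy * oz;
    double* xc = gx.begin() + (R_xlen_t)c * dx * dy * dim_in[2];
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y) {
        const double* src = gc + (R_xlen_t)(y + oy * z) * ox;
        double* dst = xc + (R_xlen_t)((y / 2) + dy * (z / 2)) * dx;
        for (int xx = 0; xx < ox; ++xx) dst[xx / 2] += src[xx];
      }
  }
  return gx;
}

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas), separable, with anisotropic voxel spacing in mm.
// Returns, for every voxel, the distance to the nearest feature voxel.
static void dt1d(const std::vector<double>& f, double s,
                 std::vector<double>& d, std::vector<int>& v,
                 std::vector<double>& z) {
  const int n = (int)f.size();
  const double inf = std::numeric_limits<double>::infinity();
  const double s2 = s * s;
  int kk = -1;
  // Build the lower envelope from finite parabolas only: an infinite
  // sample (a row with no feature voxel yet) contributes nothing, and
  // inf - inf in the intersection formula would poison the envelope.
  for (int q = 0; q < n; ++q) {
    if (!std::isfinite(f[q])) continue;
    if (kk < 0) {
      kk = 0;
      v[0] = q;
      z[0] = -inf;
      z[1] = inf;
      continue;
    }
    double sp;
    while (true) {
      const int p = v[kk];
      sp = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (sp > z[kk]) break;
      --kk;
    }
    ++kk;
    v[kk] = q;
    z[kk] = sp;
    z[kk + 1] = inf;
  }
  if (kk < 0) {
    for (int q = 0; q < n; ++q) d[q] = inf;
    return;
  }
  // z[] holds intersection abscissae in index units (the parabolas are
  // f[p] + s^2 (x - p)^2 over the index coordinate x), so query at x = q.
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < (double)q) ++j;
    const int p = v[j];
    d[q] = s2 * (q - p) * (q - p) + f[p];
  }
}

// [[Rcpp::export]]
NumericVector edt3(const LogicalVector& feature, const IntegerVector& dim,
                   const NumericVector& spacing) {
  const int dx = dim[0], dy = dim[1], dz = dim[2];
  const R_xlen_t n = (R_xlen_t)dx * dy * dz;
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> sq(n);
  for (R_xlen_t i = 0; i < n; ++i) sq[i] = feature[i] ? 0.0 : inf;

  const int maxdim = std::max(dx, std::max(dy, dz));
  std::vector<double> d(maxdim), z(maxdim + 1);
  std::vector<int> v(maxdim);

  // x axis
  for (int zi = 0; zi < dz; ++zi)
    for (int yi = 0; yi < dy; ++yi) {
      const R_xlen_t base = (R_xlen_t)(yi + dy * zi) * dx;
      std::vector<double> ff(sq.begin() + base, sq.begin() + base + dx);
      dt1d(ff, spacing[0], d, v, z);
      for (int xi = 0; xi < dx; ++xi) sq[base + xi] = d[xi];
    }
  // y axis
  for (int zi = 0; zi < dz; ++zi)
    for (int xi = 0; xi < dx; ++xi) {
      std::vector<double> ff(dy);
      for (int yi = 0; yi < dy; ++yi) ff[yi] = sq[xi + (R_xlen_t)(yi + dy * zi) * dx];
      dt1d(ff, spacing[1], d, v, z);
      for (int yi = 0; yi < dy; ++yi) sq[xi + (R_xlen_t)(yi + dy * zi) * dx] = d[yi];
    }
  // z axis
  for (int yi = 0; yi < dy; ++yi)
    for (int xi = 0; xi < dx; ++xi) {
      std::vector<double> ff(dz);
      for (int zi = 0; zi < dz; ++zi) ff[zi] = sq[xi + (R_xlen_t)(yi + dy * zi) * dx];
      dt1d(ff, spacing[2], d, v, z);
      for (int zi = 0; zi < dz; ++zi) sq[xi + (R_xlen_t)(yi + dy * zi) * dx] = d[zi];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(sq[i]);
  return out;
}
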