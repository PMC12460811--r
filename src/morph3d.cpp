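#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 3-D voxel utilities: grayscale min/max filtering with an arbitrary
// structuring element, 26-connected component labeling, trilinear
// resampling, separable Gaussian smoothing, and central-difference
// gradients. All volumes are [x, y, z] column-major arrays.

// [[Rcpp::export(name = ".cpp_minmax3d")]]
NumericVector minmax3d(NumericVector vol, IntegerVector dims,
                       IntegerMatrix offsets, bool take_max) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int no = offsets.nrow();
  NumericVector out(vol.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double best = take_max ? R_NegInf : R_PosInf;
        for (int o = 0; o < no; ++o) {
          int xx = x + offsets(o, 0), yy = y + offsets(o, 1),
              zz = z + offsets(o, 2);
          if (xx < 0) xx = 0; else if (xx >= nx) xx = nx - 1;
          if (yy < 0) yy = 0; else if (yy >= ny) yy = ny - 1;
          if (zz < 0) zz = 0; else if (zz >= nz) zz = nz - 1;
          double v = vol[xx + nx * (yy + (R_xlen_t)ny * zz)];
          if (take_max) { if (v > best) best = v; }
          else { if (v < best) best = v; }
        }
        out[x + nx * (y + (R_xlen_t)ny * z)] = best;
      }
  return out;
}

// [[Rcpp::export(name = ".cpp_label3d")]]
List label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  std::vector<int> sizes;
  std::vector<int> touches;
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    int size = 0, touch = 0;
    stack.clear();
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      ++size;
      int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((R_xlen_t)nx * ny));
      // singleton axes (2-D slices stored as one-plane volumes) have no
      // border in that direction
      if ((nx > 1 && (x == 0 || x == nx - 1)) ||
          (ny > 1 && (y == 0 || y == ny - 1)) ||
          (nz > 1 && (z == 0 || z == nz - 1)))
        touch = 1;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
            if (connectivity == 6 && man > 1) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            R_xlen_t q = xx + nx * (yy + (R_xlen_t)ny * zz);
            if (mask[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
          }
    }
    sizes.push_back(size);
    touches.push_back(touch);
  }
  return List::create(_["labels"] = lab, _["sizes"] = wrap(sizes),
                      _["touches_border"] = wrap(touches));
}

static inline double tri_sample(const double* v, int nx, int ny, int nz,
                                double x, double y, double z) {
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  int x0 = (int)x, y0 = (int)y, z0 = (int)z;
  if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  R_xlen_t b = x0 + nx * (y0 + (R_xlen_t)ny * z0);
  R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  double c00 = v[b] * (1 - fx) + v[b + sx] * fx;
  double c10 = v[b + sy] * (1 - fx) + v[b + sy + sx] * fx;
  double c01 = v[b + sz] * (1 - fx) + v[b + sz + sx] * fx;
  double c11 = v[b + sz + sy] * (1 - fx) + v[b + sz + sy + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export(name = ".cpp_resample3d")]]
NumericVector resample3d(NumericVector vol, IntegerVector dims,
                         NumericVector scale, IntegerVector out_dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = out_dims[0], oy = out_dims[1], oz = out_dims[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double* v = REAL(vol);
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x)
        out[x + ox * (y + (R_xlen_t)oy * z)] =
            tri_sample(v, nx, ny, nz, x * scale[0], y * scale[1], z * scale[2]);
  return out;
}

// [[Rcpp::export(name = ".cpp_gauss3d")]]
NumericVector gauss3d(NumericVector vol, IntegerVector dims,
                      NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector cur = clone(vol);
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int rad = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * rad + 1);
    double sum = 0;
    for (int i = -rad; i <= rad; ++i) {
      k[i + rad] = std::exp(-0.5 * i * i / (s * s));
      sum += k[i + rad];
    }
    for (double& w : k) w /= sum;
    NumericVector nxt(cur.size());
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int idx3[3] = {x, y, z};
          R_xlen_t base = x + nx * (y + (R_xlen_t)ny * z);
          double acc = 0;
          for (int i = -rad; i <= rad; ++i) {
            int p = idx3[ax] + i;
            if (p < 0) p = 0; else if (p >= n[ax]) p = n[ax] - 1;
            acc += k[i + rad] * cur[base + (p - idx3[ax]) * stride[ax]];
          }
          nxt[base] = acc;
        }
    cur = nxt;
  }
  return cur;
}

// [[Rcpp::export(name = ".cpp_gradient3d")]]
List gradient3d(NumericVector vol, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector gx(vol.size()), gy(vol.size()), gz(vol.size());
  const double* v = REAL(vol);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t p = x + nx * (y + (R_xlen_t)ny * z);
        int xm = x > 0 ? x - 1 : 0, xp = x < nx - 1 ? x + 1 : nx - 1;
        int ym = y > 0 ? y - 1 : 0, yp = y < ny - 1 ? y + 1 : ny - 1;
        int zm = z > 0 ? z - 1 : 0, zp = z < nz - 1 ? z + 1 : nz - 1;
        gx[p] = (v[xp + nx * (y + (R_xlen_t)ny * z)] -
                 v[xm + nx * (y + (R_xlen_t)ny * z)]) / (xp - xm);
        gy[p] = (v[x + nx * (yp + (R_xlen_t)ny * z)] -
                 v[x + nx * (ym + (R_xlen_t)ny * z)]) / (yp - ym);
        gz[p] = (v[x + nx * (y + (R_xlen_t)ny * zp)] -
                 v[x + nx * (y + (R_xlen_t)ny * zm)]) / (zp - zm);
      }
  return List::create(_["gx"] = gx, _["gy"] = gy, _["gz"] = gz);
}
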