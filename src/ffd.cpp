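#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Cyclic free-form deformation engine: displacement is a tensor-product
// cubic B-spline on a regular control lattice (spatial part) times a
// truncated Fourier basis over the cardiac cycle (temporal part). The
// temporal basis rows are supplied by R and vanish at the reference phase,
// so u(x, reference) = 0 and u is exactly periodic by construction.
//
// Layout: volumes are [x,y,z] column-major; coefficients are a
// (ncp x 3 x nb) array (control point, displacement component, temporal
// basis function), displacements in voxel units.

namespace {

inline void bspline_w(double t, double* w) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
  w[1] = (4 - 6 * t2 + 3 * t3) / 6.0;
  w[2] = (1 + 3 * t + 3 * t2 - 3 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

struct AxisTab {
  std::vector<int> i0;
  std::vector<double> w; // 4 per sample
};

AxisTab axis_table(int n, double sp, int ncells) {
  AxisTab tab;
  tab.i0.resize(n);
  tab.w.resize(4 * n);
  for (int x = 0; x < n; ++x) {
    double u = x / sp;
    int i0 = (int)std::floor(u);
    if (i0 > ncells - 1) i0 = ncells - 1;
    if (i0 < 0) i0 = 0;
    tab.i0[x] = i0;
    bspline_w(u - i0, &tab.w[4 * x]);
  }
  return tab;
}

// trilinear sample with the exact gradient of the interpolant (clamped at
// the border, where the outward derivative is zero)
inline double tri_sample(const double* v, int nx, int ny, int nz, double x,
                         double y, double z, double* g = nullptr) {
  bool cx = false, cy = false, cz = false;
  if (x < 0) { x = 0; cx = true; }
  if (x > nx - 1) { x = nx - 1; cx = true; }
  if (y < 0) { y = 0; cy = true; }
  if (y > ny - 1) { y = ny - 1; cy = true; }
  if (z < 0) { z = 0; cz = true; }
  if (z > nz - 1) { z = nz - 1; cz = true; }
  int x0 = (int)x, y0 = (int)y, z0 = (int)z;
  if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  R_xlen_t b = x0 + nx * (y0 + (R_xlen_t)ny * z0);
  R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  double v000 = v[b], v100 = v[b + 1];
  double v010 = v[b + sy], v110 = v[b + sy + 1];
  double v001 = v[b + sz], v101 = v[b + sz + 1];
  double v011 = v[b + sz + sy], v111 = v[b + sz + sy + 1];
  double c00 = v000 * (1 - fx) + v100 * fx;
  double c10 = v010 * (1 - fx) + v110 * fx;
  double c01 = v001 * (1 - fx) + v101 * fx;
  double c11 = v011 * (1 - fx) + v111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  if (g) {
    double d00 = v100 - v000, d10 = v110 - v010, d01 = v101 - v001,
           d11 = v111 - v011;
    g[0] = cx ? 0 : ((d00 * (1 - fy) + d10 * fy) * (1 - fz) +
                     (d01 * (1 - fy) + d11 * fy) * fz);
    g[1] = cy ? 0 : ((c10 - c00) * (1 - fz) + (c11 - c01) * fz);
    g[2] = cz ? 0 : (c1 - c0);
  }
  return c0 * (1 - fz) + c1 * fz;
}

} // namespace

// Displacement at arbitrary voxel-space points for one temporal basis row.
// [[Rcpp::export(name = ".cpp_ffd_eval_points")]]
NumericMatrix ffd_eval_points(NumericVector coef, IntegerVector gdims,
                              NumericVector sp, NumericVector tb,
                              NumericMatrix pts) {
  const int gx = gdims[0], gy = gdims[1], gz = gdims[2];
  const int ncp = gx * gy * gz, nb = tb.size();
  const int np = pts.nrow();
  // combine temporal basis
  std::vector<double> ck((size_t)ncp * 3, 0.0);
  for (int b = 0; b < nb; ++b) {
    double t = tb[b];
    if (t == 0) continue;
    const double* cb = REAL(coef) + (R_xlen_t)ncp * 3 * b;
    for (int i = 0; i < ncp * 3; ++i) ck[i] += t * cb[i];
  }
  NumericMatrix out(np, 3);
  double wx[4], wy[4], wz[4];
  const int ncellx = gx - 3, ncelly = gy - 3, ncellz = gz - 3;
  for (int p = 0; p < np; ++p) {
    double ux = pts(p, 0) / sp[0], uy = pts(p, 1) / sp[1],
           uz = pts(p, 2) / sp[2];
    if (ux < -0.5 || ux > ncellx + 0.5 || uy < -0.5 || uy > ncelly + 0.5 ||
        uz < -0.5 || uz > ncellz + 0.5)
      stop("point outside control-grid support");
    int ix = (int)std::floor(ux), iy = (int)std::floor(uy),
        iz = (int)std::floor(uz);
    if (ix > ncellx - 1) ix = ncellx - 1; if (ix < 0) ix = 0;
    if (iy > ncelly - 1) iy = ncelly - 1; if (iy < 0) iy = 0;
    if (iz > ncellz - 1) iz = ncellz - 1; if (iz < 0) iz = 0;
    bspline_w(ux - ix, wx);
    bspline_w(uy - iy, wy);
    bspline_w(uz - iz, wz);
    double acc[3] = {0, 0, 0};
    for (int c = 0; c < 4; ++c)
      for (int b2 = 0; b2 < 4; ++b2) {
        double wyz = wz[c] * wy[b2];
        int base = gx * ((iy + b2) + gy * (iz + c)) + ix;
        for (int a = 0; a < 4; ++a) {
          double w = wyz * wx[a];
          int g = base + a;
          acc[0] += w * ck[g];
          acc[1] += w * ck[g + ncp];
          acc[2] += w * ck[g + 2 * ncp];
        }
      }
    out(p, 0) = acc[0];
    out(p, 1) = acc[1];
    out(p, 2) = acc[2];
  }
  return out;
}

// Full-grid displacement field for one temporal basis row.
// [[Rcpp::export(name = ".cpp_ffd_field")]]
NumericMatrix ffd_field(NumericVector coef, IntegerVector gdims,
                        NumericVector sp, NumericVector tb,
                        IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int gx = gdims[0], gy = gdims[1], gz = gdims[2];
  const int ncp = gx * gy * gz, nb = tb.size();
  std::vector<double> ck((size_t)ncp * 3, 0.0);
  for (int b = 0; b < nb; ++b) {
    double t = tb[b];
    if (t == 0) continue;
    const double* cb = REAL(coef) + (R_xlen_t)ncp * 3 * b;
    for (int i = 0; i < ncp * 3; ++i) ck[i] += t * cb[i];
  }
  AxisTab tx = axis_table(nx, sp[0], gx - 3);
  AxisTab ty = axis_table(ny, sp[1], gy - 3);
  AxisTab tz = axis_table(nz, sp[2], gz - 3);
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericMatrix out(nvox, 3);
  R_xlen_t v = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++v) {
        const double *wx = &tx.w[4 * x], *wy = &ty.w[4 * y],
                     *wz = &tz.w[4 * z];
        int ix = tx.i0[x], iy = ty.i0[y], iz = tz.i0[z];
        double acc[3] = {0, 0, 0};
        for (int c = 0; c < 4; ++c)
          for (int b2 = 0; b2 < 4; ++b2) {
            double wyz = wz[c] * wy[b2];
            int base = gx * ((iy + b2) + gy * (iz + c)) + ix;
            for (int a = 0; a < 4; ++a) {
              double w = wyz * wx[a];
              int g = base + a;
              acc[0] += w * ck[g];
              acc[1] += w * ck[g + ncp];
              acc[2] += w * ck[g + 2 * ncp];
            }
          }
        out(v, 0) = acc[0];
        out(v, 1) = acc[1];
        out(v, 2) = acc[2];
      }
  return out;
}

// Cost (image dissimilarity summed over phases + lambda * bending energy)
// and its gradient with respect to the coefficient array. The model is
// fitted in the forward direction: each phase volume sampled at x + u(x,k)
// must match the fixed reference volume, so u maps reference positions to
// their phase-k positions and can displace the reference mesh directly.
// [[Rcpp::export(name = ".cpp_ffd_cost_grad")]]
List ffd_cost_grad(NumericVector ref, List targets,
                   IntegerVector dims, NumericVector coef,
                   IntegerVector gdims, NumericVector sp, NumericMatrix Tmat,
                   IntegerVector phases_use, double lambda,
                   std::string metric, Nullable<List> base_fields) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int gx = gdims[0], gy = gdims[1], gz = gdims[2];
  const int ncp = gx * gy * gz, nb = Tmat.ncol();
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const double* R0 = REAL(ref);
  const bool use_ncc = (metric == "ncc");

  AxisTab tabx = axis_table(nx, sp[0], gx - 3);
  AxisTab taby = axis_table(ny, sp[1], gy - 3);
  AxisTab tabz = axis_table(nz, sp[2], gz - 3);

  NumericVector grad((R_xlen_t)ncp * 3 * nb);
  std::vector<double> ck((size_t)ncp * 3);
  std::vector<double> gck((size_t)ncp * 3);
  std::vector<double> ubuf((size_t)nvox * 3);
  std::vector<double> iw((size_t)nvox), dmet((size_t)nvox);
  double cost = 0;
  NumericVector phase_metric(phases_use.size());

  for (int pi = 0; pi < phases_use.size(); ++pi) {
    int k = phases_use[pi];
    NumericVector tgt = targets[k];
    const double* Ik = REAL(tgt);
    const double* base = nullptr;
    if (base_fields.isNotNull()) {
      List bf(base_fields);
      NumericMatrix bm = bf[k];
      base = REAL(bm);
    }
    // combine temporal basis for this phase
    std::fill(ck.begin(), ck.end(), 0.0);
    for (int b = 0; b < nb; ++b) {
      double t = Tmat(k, b);
      if (t == 0) continue;
      const double* cb = REAL(coef) + (R_xlen_t)ncp * 3 * b;
      for (int i = 0; i < ncp * 3; ++i) ck[i] += t * cb[i];
    }
    // forward pass: displacement + phase image warped back onto reference
    R_xlen_t v = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++v) {
          const double *wx = &tabx.w[4 * x], *wy = &taby.w[4 * y],
                       *wz = &tabz.w[4 * z];
          int ix = tabx.i0[x], iy = taby.i0[y], iz = tabz.i0[z];
          double acc[3] = {0, 0, 0};
          for (int c = 0; c < 4; ++c)
            for (int b2 = 0; b2 < 4; ++b2) {
              double wyz = wz[c] * wy[b2];
              int gbase = gx * ((iy + b2) + gy * (iz + c)) + ix;
              for (int a = 0; a < 4; ++a) {
                double w = wyz * wx[a];
                int g = gbase + a;
                acc[0] += w * ck[g];
                acc[1] += w * ck[g + ncp];
                acc[2] += w * ck[g + 2 * ncp];
              }
            }
          if (base) {
            acc[0] += base[v];
            acc[1] += base[v + nvox];
            acc[2] += base[v + 2 * nvox];
          }
          ubuf[v] = acc[0];
          ubuf[v + nvox] = acc[1];
          ubuf[v + 2 * nvox] = acc[2];
          iw[v] = tri_sample(Ik, nx, ny, nz, x + acc[0], y + acc[1],
                             z + acc[2]);
        }
    // metric and its derivative wrt warped intensities
    double mval = 0;
    if (!use_ncc) {
      double s = 0;
      for (R_xlen_t i = 0; i < nvox; ++i) {
        double r = iw[i] - R0[i];
        s += r * r;
        dmet[i] = 2.0 * r / nvox;
      }
      mval = s / nvox;
    } else {
      double ma = 0, mb = 0;
      for (R_xlen_t i = 0; i < nvox; ++i) { ma += iw[i]; mb += R0[i]; }
      ma /= nvox; mb /= nvox;
      double sab = 0, sa2 = 0, sb2 = 0;
      for (R_xlen_t i = 0; i < nvox; ++i) {
        double a = iw[i] - ma, b = R0[i] - mb;
        sab += a * b; sa2 += a * a; sb2 += b * b;
      }
      double D = std::sqrt(sa2 * sb2);
      if (D < 1e-12) {
        mval = 0;
        std::fill(dmet.begin(), dmet.end(), 0.0);
      } else {
        double ncc = sab / D;
        mval = -ncc;
        for (R_xlen_t i = 0; i < nvox; ++i) {
          double a = iw[i] - ma, b = R0[i] - mb;
          dmet[i] = -(b / D - ncc * a / sa2);
        }
      }
    }
    cost += mval;
    phase_metric[pi] = mval;
    // backward pass: scatter into control-point gradient
    std::fill(gck.begin(), gck.end(), 0.0);
    v = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++v) {
          double d = dmet[v];
          if (d == 0) continue;
          double px = x + ubuf[v], py = y + ubuf[v + nvox],
                 pz = z + ubuf[v + 2 * nvox];
          double gv[3];
          tri_sample(Ik, nx, ny, nz, px, py, pz, gv);
          double rx = d * gv[0], ry = d * gv[1], rz = d * gv[2];
          const double *wx = &tabx.w[4 * x], *wy = &taby.w[4 * y],
                       *wz = &tabz.w[4 * z];
          int ix = tabx.i0[x], iy = taby.i0[y], iz = tabz.i0[z];
          for (int c = 0; c < 4; ++c)
            for (int b2 = 0; b2 < 4; ++b2) {
              double wyz = wz[c] * wy[b2];
              int gbase = gx * ((iy + b2) + gy * (iz + c)) + ix;
              for (int a = 0; a < 4; ++a) {
                double w = wyz * wx[a];
                int g = gbase + a;
                gck[g] += w * rx;
                gck[g + ncp] += w * ry;
                gck[g + 2 * ncp] += w * rz;
              }
            }
        }
    for (int b = 0; b < nb; ++b) {
      double t = Tmat(k, b);
      if (t == 0) continue;
      double* gb = REAL(grad) + (R_xlen_t)ncp * 3 * b;
      for (int i = 0; i < ncp * 3; ++i) gb[i] += t * gck[i];
    }
  }

  // bending penalty: mean squared second difference of the control lattice,
  // per temporal basis function and component
  if (lambda > 0) {
    double be = 0;
    double norm = 1.0 / ((double)ncp * 3 * nb);
    for (int b = 0; b < nb; ++b) {
      const double* cb = REAL(coef) + (R_xlen_t)ncp * 3 * b;
      double* gb = REAL(grad) + (R_xlen_t)ncp * 3 * b;
      for (int comp = 0; comp < 3; ++comp) {
        const double* c = cb + (R_xlen_t)ncp * comp;
        double* g = gb + (R_xlen_t)ncp * comp;
        for (int z = 0; z < gz; ++z)
          for (int y = 0; y < gy; ++y)
            for (int x = 0; x < gx; ++x) {
              int i = x + gx * (y + gy * z);
              if (x > 0 && x < gx - 1) {
                double d2 = c[i - 1] - 2 * c[i] + c[i + 1];
                be += d2 * d2 * norm;
                double f = 2 * lambda * d2 * norm;
                g[i - 1] += f; g[i] -= 2 * f; g[i + 1] += f;
              }
              if (y > 0 && y < gy - 1) {
                double d2 = c[i - gx] - 2 * c[i] + c[i + gx];
                be += d2 * d2 * norm;
                double f = 2 * lambda * d2 * norm;
                g[i - gx] += f; g[i] -= 2 * f; g[i + gx] += f;
              }
              if (z > 0 && z < gz - 1) {
                int s = gx * gy;
                double d2 = c[i - s] - 2 * c[i] + c[i + s];
                be += d2 * d2 * norm;
                double f = 2 * lambda * d2 * norm;
                g[i - s] += f; g[i] -= 2 * f; g[i + s] += f;
              }
            }
      }
    }
    cost += lambda * be;
    return List::create(_["cost"] = cost, _["grad"] = grad,
                        _["phase_metric"] = phase_metric,
                        _["bending"] = be);
  }
  return List::create(_["cost"] = cost, _["grad"] = grad,
                      _["phase_metric"] = phase_metric, _["bending"] = 0.0);
}
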