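#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Region codes used throughout: 0 background, 1 lumen, 2 CP, 3 NCP, 4 LAP.
// The wall defaults to NCP tissue; deposits override it within their
// axial interval x angular sector (full wall thickness).

static inline double lut_interp(const NumericVector &s, const NumericVector &v,
                                double x) {
  int n = s.size();
  if (x <= s[0]) return v[0];
  if (x >= s[n - 1]) return v[n - 1];
  double ds = s[1] - s[0];
  int i = (int)std::floor((x - s[0]) / ds);
  if (i > n - 2) i = n - 2;
  double t = (x - s[i]) / ds;
  return v[i] * (1.0 - t) + v[i + 1] * t;
}

struct TubeGeom {
  const NumericMatrix &cl;
  const NumericVector &cl_s;
  bool straight;
  double x0, y0, z0, zlen;
  TubeGeom(const NumericMatrix &cl_, const NumericVector &cl_s_, bool str_)
      : cl(cl_), cl_s(cl_s_), straight(str_) {
    x0 = cl(0, 0); y0 = cl(0, 1); z0 = cl(0, 2);
    zlen = cl(cl.nrow() - 1, 2) - z0;
  }
  // returns false if outside the axial extent (beyond the end caps)
  bool locate(double px, double py, double pz, double &s, double &d,
              double &theta) const {
    if (straight) {
      s = pz - z0;
      if (s < 0.0 || s > zlen) return false;
      double dx = px - x0, dy = py - y0;
      d = std::sqrt(dx * dx + dy * dy);
      theta = std::atan2(dy, dx) * 57.29577951308232;
      if (theta < 0) theta += 360.0;
      return true;
    }
    int nseg = cl.nrow() - 1;
    double best = R_PosInf, bt = 0.0;
    int bi = 0;
    for (int i = 0; i < nseg; ++i) {
      double ax = cl(i, 0), ay = cl(i, 1), az = cl(i, 2);
      double ux = cl(i + 1, 0) - ax, uy = cl(i + 1, 1) - ay,
             uz = cl(i + 1, 2) - az;
      double L2 = ux * ux + uy * uy + uz * uz;
      double t = ((px - ax) * ux + (py - ay) * uy + (pz - az) * uz) / L2;
      double tc = t < 0.0 ? 0.0 : (t > 1.0 ? 1.0 : t);
      double qx = ax + tc * ux - px, qy = ay + tc * uy - py,
             qz = az + tc * uz - pz;
      double dd = qx * qx + qy * qy + qz * qz;
      if (dd < best) { best = dd; bi = i; bt = t; }
    }
    // beyond the proximal/distal flat caps
    if ((bi == 0 && bt < 0.0) || (bi == nseg - 1 && bt > 1.0)) return false;
    double tc = bt < 0.0 ? 0.0 : (bt > 1.0 ? 1.0 : bt);
    double ax = cl(bi, 0), ay = cl(bi, 1), az = cl(bi, 2);
    double ux = cl(bi + 1, 0) - ax, uy = cl(bi + 1, 1) - ay,
           uz = cl(bi + 1, 2) - az;
    double L = std::sqrt(ux * ux + uy * uy + uz * uz);
    ux /= L; uy /= L; uz /= L;
    double qx = ax + tc * L * ux, qy = ay + tc * L * uy, qz = az + tc * L * uz;
    s = cl_s[bi] + tc * L;
    double vx = px - qx, vy = py - qy, vz = pz - qz;
    d = std::sqrt(vx * vx + vy * vy + vz * vz);
    // in-plane frame from the global x-axis (fallback y-axis near parallel)
    double rx = 1.0, ry = 0.0, rz = 0.0;
    if (std::fabs(ux) > 0.9) { rx = 0.0; ry = 1.0; }
    double dp = rx * ux + ry * uy + rz * uz;
    double e1x = rx - dp * ux, e1y = ry - dp * uy, e1z = rz - dp * uz;
    double n1 = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
    e1x /= n1; e1y /= n1; e1z /= n1;
    double e2x = uy * e1z - uz * e1y, e2y = uz * e1x - ux * e1z,
           e2z = ux * e1y - uy * e1x;
    theta = std::atan2(vx * e2x + vy * e2y + vz * e2z,
                       vx * e1x + vy * e1y + vz * e1z) * 57.29577951308232;
    if (theta < 0) theta += 360.0;
    return true;
  }
};

static inline int region_at(const TubeGeom &g, const NumericVector &lut_s,
                            const NumericVector &lut_rlum,
                            const NumericVector &lut_rout,
                            const NumericMatrix &dep, double px, double py,
                            double pz) {
  double s, d, th;
  if (!g.locate(px, py, pz, s, d, th)) return 0;
  double rl = lut_interp(lut_s, lut_rlum, s);
  if (d < rl) return 1;
  double ro = lut_interp(lut_s, lut_rout, s);
  if (d >= ro) return 0;
  for (int j = 0; j < dep.nrow(); ++j) {
    if (s >= dep(j, 0) && s < dep(j, 1)) {
      double a0 = dep(j, 2), a1 = dep(j, 3);
      double t2 = th < a0 ? th + 360.0 : th;
      if (t2 < a1) return (int)dep(j, 4);
    }
  }
  return 3;
}

// [[Rcpp::export]]
List render_phantom_cpp(IntegerVector dim, NumericVector spacing,
                        NumericVector origin, NumericMatrix cl,
                        NumericVector cl_s, bool straight,
                        NumericVector lut_s, NumericVector lut_rlum,
                        NumericVector lut_rout, NumericMatrix deposits,
                        int supersample) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector occ(nvox * 5);
  IntegerVector lab(nvox);
  TubeGeom geom(cl, cl_s, straight);
  int S = supersample < 1 ? 1 : supersample;
  std::vector<double> off(S);
  for (int k = 0; k < S; ++k) off[k] = ((2.0 * k + 1.0) / (2.0 * S)) - 0.5;
  double w = 1.0 / (S * S * S);
  R_xlen_t idx = 0;
  for (int iz = 0; iz < nz; ++iz) {
    double cz = origin[2] + iz * spacing[2];
    for (int iy = 0; iy < ny; ++iy) {
      double cy = origin[1] + iy * spacing[1];
      for (int ix = 0; ix < nx; ++ix, ++idx) {
        double cx = origin[0] + ix * spacing[0];
        double f[5] = {0, 0, 0, 0, 0};
        for (int a = 0; a < S; ++a)
          for (int b = 0; b < S; ++b)
            for (int c = 0; c < S; ++c) {
              int r = region_at(geom, lut_s, lut_rlum, lut_rout, deposits,
                                cx + off[a] * spacing[0],
                                cy + off[b] * spacing[1],
                                cz + off[c] * spacing[2]);
              f[r] += w;
            }
        for (int r = 0; r < 5; ++r) occ[idx + nvox * r] = f[r];
        lab[idx] = region_at(geom, lut_s, lut_rlum, lut_rout, deposits, cx,
                             cy, cz);
      }
    }
  }
  occ.attr("dim") = IntegerVector::create(nx, ny, nz, 5);
  lab.attr("dim") = dim;
  return List::create(_["occupancy"] = occ, _["region"] = lab);
}

// Separable Gaussian convolution with reflecting boundaries.
// [[Rcpp::export]]
NumericVector gauss_blur3d_cpp(NumericVector arr, IntegerVector dim,
                               NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector cur = clone(arr);
  NumericVector tmp(nvox);
  int n[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double sg = sigma_vox[ax];
    if (sg <= 0) continue;
    int r = (int)std::ceil(3.0 * sg);
    std::vector<double> k(2 * r + 1);
    double ksum = 0.0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * i * i / (sg * sg));
      ksum += k[i + r];
    }
    for (int i = 0; i <= 2 * r; ++i) k[i] /= ksum;
    int na = n[ax];
    R_xlen_t st = stride[ax];
    // iterate over all lines along axis ax
    int nb = (ax == 0) ? ny : nx;
    int nc = (ax == 2) ? ny : nz;
    R_xlen_t stb = (ax == 0) ? stride[1] : stride[0];
    R_xlen_t stc = (ax == 2) ? stride[1] : stride[2];
    for (int c = 0; c < nc; ++c)
      for (int b = 0; b < nb; ++b) {
        R_xlen_t base = b * stb + c * stc;
        for (int i = 0; i < na; ++i) {
          double acc = 0.0;
          for (int j = -r; j <= r; ++j) {
            int ii = i + j;
            if (ii < 0) ii = -ii - 1;
            if (ii >= na) ii = 2 * na - ii - 1;
            acc += k[j + r] * cur[base + (R_xlen_t)ii * st];
          }
          tmp[base + (R_xlen_t)i * st] = acc;
        }
      }
    std::copy(tmp.begin(), tmp.end(), cur.begin());
  }
  cur.attr("dim") = dim;
  return cur;
}
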