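#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear HU sample at continuous voxel index (0-based, voxel centres at
// integer indices). Outside the centre grid the volume is air (-1000 HU).
static inline double sample_hu(const double *hu, const int *d,
                               double fx, double fy, double fz) {
  if (fx < 0 || fy < 0 || fz < 0 ||
      fx > d[0] - 1 || fy > d[1] - 1 || fz > d[2] - 1)
    return -1000.0;
  int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy), z0 = (int)std::floor(fz);
  if (x0 > d[0] - 2) x0 = d[0] - 2;
  if (y0 > d[1] - 2) y0 = d[1] - 2;
  if (z0 > d[2] - 2) z0 = d[2] - 2;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  if (z0 < 0) z0 = 0;
  double ax = fx - x0, ay = fy - y0, az = fz - z0;
  const R_xlen_t nx = d[0], nxy = (R_xlen_t)d[0] * d[1];
  const double *p = hu + x0 + (R_xlen_t)y0 * nx + (R_xlen_t)z0 * nxy;
  double c00 = p[0] * (1 - ax) + p[1] * ax;
  double c10 = p[nx] * (1 - ax) + p[nx + 1] * ax;
  double c01 = p[nxy] * (1 - ax) + p[nxy + 1] * ax;
  double c11 = p[nxy + nx] * (1 - ax) + p[nxy + nx + 1] * ax;
  double c0 = c00 * (1 - ay) + c10 * ay;
  double c1 = c01 * (1 - ay) + c11 * ay;
  return c0 * (1 - az) + c1 * az;
}

// piecewise-linear HU -> relative electron density, clamped at endpoints
static inline double hu_to_den(double h, const double *chu, const double *cden,
                               int nc) {
  if (h <= chu[0]) return cden[0];
  if (h >= chu[nc - 1]) return cden[nc - 1];
  int k = 1;
  while (h > chu[k]) ++k;
  double t = (h - chu[k - 1]) / (chu[k] - chu[k - 1]);
  return cden[k - 1] + t * (cden[k] - cden[k - 1]);
}

// Water-equivalent path length (mm) from one source point to each target:
// the line integral of relative electron density, sampled uniformly at a
// step no larger than `step` over the part of the segment that intersects
// the voxel-centre bounding box (outside it the volume is air, density 0).
// [[Rcpp::export(name = ".weplRaysCpp")]]
NumericVector wepl_rays(NumericVector hu, IntegerVector dims,
                        NumericVector spacing, NumericVector origin,
                        NumericVector source, NumericMatrix targets,
                        double step, NumericVector curveHU,
                        NumericVector curveDen) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  const double org[3] = {origin[0], origin[1], origin[2]};
  const double src[3] = {source[0], source[1], source[2]};
  const int nc = curveHU.size();
  const double *chu = curveHU.begin(), *cden = curveDen.begin();
  const double *pv = hu.begin();
  const int nt = targets.nrow();
  NumericVector out(nt);

  for (int t = 0; t < nt; ++t) {
    double tgt[3] = {targets(t, 0), targets(t, 1), targets(t, 2)};
    double dir[3] = {tgt[0] - src[0], tgt[1] - src[1], tgt[2] - src[2]};
    double len = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] + dir[2] * dir[2]);
    if (len <= 0) { out[t] = 0.0; continue; }
    // clip [0, len] against the voxel-centre box (slab method)
    double t0 = 0.0, t1 = len;
    bool empty = false;
    for (int a = 0; a < 3 && !empty; ++a) {
      double u = dir[a] / len;
      double lo = org[a], hi = org[a] + (d[a] - 1) * sp[a];
      if (std::fabs(u) < 1e-12) {
        if (src[a] < lo || src[a] > hi) empty = true;
      } else {
        double ta = (lo - src[a]) / u, tb = (hi - src[a]) / u;
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
        if (t0 >= t1) empty = true;
      }
    }
    if (empty) { out[t] = 0.0; continue; }
    double seg = t1 - t0;
    int n = (int)std::ceil(seg / step);
    if (n < 1) n = 1;
    double h = seg / n;
    double acc = 0.0;
    for (int k = 0; k < n; ++k) {
      double s = t0 + (k + 0.5) * h;
      double fx = (src[0] + dir[0] / len * s - org[0]) / sp[0];
      double fy = (src[1] + dir[1] / len * s - org[1]) / sp[1];
      double fz = (src[2] + dir[2] / len * s - org[2]) / sp[2];
      acc += hu_to_den(sample_hu(pv, d, fx, fy, fz), chu, cden, nc);
    }
    out[t] = acc * h;
  }
  return out;
}
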