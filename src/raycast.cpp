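#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Primitive rows: type (0 sphere, 1 cylinder), x1,y1,z1, x2,y2,z2, radius.
// All coordinates are in the camera-aligned frame: camera at (0, 0, H)
// looking down -z, image x ~ +x, image y ~ -y.

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Nearest intersection of ray o + t*d (d unit) with one primitive.
// Returns t (> eps) or +Inf; fills hit normal if requested.
static double hit_primitive(const double* row, const double* o,
                            const double* d, double* normal) {
  const double inf = std::numeric_limits<double>::infinity();
  const double eps = 1e-9;
  double r = row[7];
  if (row[0] < 0.5) {  // sphere
    double oc[3] = { o[0] - row[1], o[1] - row[2], o[2] - row[3] };
    double b = dot3(oc, d);
    double c0 = dot3(oc, oc) - r * r;
    double disc = b * b - c0;
    if (disc < 0) return inf;
    double sq = std::sqrt(disc);
    double t = -b - sq;
    if (t <= eps) t = -b + sq;
    if (t <= eps) return inf;
    if (normal) {
      for (int k = 0; k < 3; ++k)
        normal[k] = (o[k] + t * d[k] - row[1 + k]) / r;
    }
    return t;
  }
  // finite open cylinder between p1 and p2
  double a[3] = { row[4] - row[1], row[5] - row[2], row[6] - row[3] };
  double len = std::sqrt(dot3(a, a));
  if (len < eps) return inf;
  for (int k = 0; k < 3; ++k) a[k] /= len;
  double op[3] = { o[0] - row[1], o[1] - row[2], o[2] - row[3] };
  double da = dot3(d, a), oa = dot3(op, a);
  double dd[3], oo[3];
  for (int k = 0; k < 3; ++k) {
    dd[k] = d[k] - da * a[k];
    oo[k] = op[k] - oa * a[k];
  }
  double A = dot3(dd, dd);
  if (A < 1e-14) return inf;  // ray parallel to axis; caps are joint spheres
  double B = dot3(oo, dd);
  double C = dot3(oo, oo) - r * r;
  double disc = B * B - A * C;
  if (disc < 0) return inf;
  double sq = std::sqrt(disc);
  for (int root = 0; root < 2; ++root) {
    double t = (root == 0) ? (-B - sq) / A : (-B + sq) / A;
    if (t <= eps) continue;
    double s = oa + t * da;
    if (s < 0 || s > len) continue;
    if (normal) {
      for (int k = 0; k < 3; ++k)
        normal[k] = (op[k] + t * d[k] - s * a[k]) / r;
    }
    return t;
  }
  return inf;
}

// [[Rcpp::export]]
IntegerMatrix render_cpp(NumericMatrix prims, int width, int height,
                         double f_px, double cam_h, int background,
                         int body_gray, double ambient) {
  const double inf = std::numeric_limits<double>::infinity();
  IntegerMatrix img(height, width);
  std::fill(img.begin(), img.end(), background);
  NumericMatrix zbuf(height, width);
  std::fill(zbuf.begin(), zbuf.end(), inf);

  int n = prims.nrow();
  double o[3] = { 0.0, 0.0, cam_h };
  for (int i = 0; i < n; ++i) {
    NumericMatrix::Row rw = prims(i, _);
    double row[8];
    for (int k = 0; k < 8; ++k) row[k] = rw[k];
    // conservative screen bounding box from the endpoint projections
    double r = row[7];
    double umin = 1e18, umax = -1e18, vmin = 1e18, vmax = -1e18;
    int nend = (row[0] < 0.5) ? 1 : 2;
    bool ok = true;
    for (int e = 0; e < nend; ++e) {
      double px = row[1 + 3 * e], py = row[2 + 3 * e], pz = row[3 + 3 * e];
      double depth = cam_h - pz;
      if (depth - r <= 1e-6) { ok = false; break; }
      double u = width / 2.0 + f_px * px / depth;
      double v = height / 2.0 - f_px * py / depth;
      double pad = f_px * r / (depth - r) + 2.0;
      umin = std::min(umin, u - pad); umax = std::max(umax, u + pad);
      vmin = std::min(vmin, v - pad); vmax = std::max(vmax, v + pad);
    }
    if (!ok) continue;
    int c0 = std::max(0, (int)std::floor(umin));
    int c1 = std::min(width - 1, (int)std::ceil(umax));
    int r0 = std::max(0, (int)std::floor(vmin));
    int r1 = std::min(height - 1, (int)std::ceil(vmax));
    for (int rr = r0; rr <= r1; ++rr) {
      for (int cc = c0; cc <= c1; ++cc) {
        double u = cc + 0.5, v = rr + 0.5;
        double d[3] = { (u - width / 2.0) / f_px,
                        (height / 2.0 - v) / f_px, -1.0 };
        double nd = std::sqrt(dot3(d, d));
        for (int k = 0; k < 3; ++k) d[k] /= nd;
        double normal[3];
        double t = hit_primitive(row, o, d, normal);
        if (t < zbuf(rr, cc)) {
          zbuf(rr, cc) = t;
          double ndotl = -dot3(normal, d);  // light from the camera
          if (ndotl < 0) ndotl = 0;
          double val = body_gray * (ambient + (1.0 - ambient) * ndotl);
          if (val > 255) val = 255;
          if (val < 0) val = 0;
          img(rr, cc) = (int)std::lround(val);
        }
      }
    }
  }
  return img;
}

// Distance to the nearest primitive hit along rays from the camera to each
// target point, skipping per-target primitive indices (1-based). Used for
// landmark occlusion testing.
// [[Rcpp::export]]
NumericVector nearest_hit_cpp(NumericMatrix prims, double cam_h,
                              NumericMatrix targets, List skip) {
  const double inf = std::numeric_limits<double>::infinity();
  int m = targets.nrow(), n = prims.nrow();
  NumericVector out(m);
  double o[3] = { 0.0, 0.0, cam_h };
  for (int j = 0; j < m; ++j) {
    double d[3] = { targets(j, 0) - o[0], targets(j, 1) - o[1],
                    targets(j, 2) - o[2] };
    double dist = std::sqrt(dot3(d, d));
    for (int k = 0; k < 3; ++k) d[k] /= dist;
    IntegerVector sk = skip[j];
    double best = inf;
    for (int i = 0; i < n; ++i) {
      bool skipped = false;
      for (int q = 0; q < sk.size(); ++q)
        if (sk[q] == i + 1) { skipped = true; break; }
      if (skipped) continue;
      double row[8];
      for (int k = 0; k < 8; ++k) row[k] = prims(i, k);
      double t = hit_primitive(row, o, d, nullptr);
      if (t < best) best = t;
    }
    out[j] = best;
  }
  return out;
}
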