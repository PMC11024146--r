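#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p, after Ericson, Real-Time
// Collision Detection ch. 5.1.5.  Writes the closest point into out[3].
static inline void closest_point_triangle(const double *p, const double *a,
                                          const double *b, const double *c,
                                          double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }

  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }

  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }

  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }

  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }

  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i]*v + ac[i]*w;
}

// flat copies of mesh data: per-triangle corner coordinates (9 doubles),
// centroid + bounding radius for pruning
struct FlatMesh {
  int nf;
  std::vector<double> tri;    // 9 * nf
  std::vector<double> cent;   // 3 * nf
  std::vector<double> rad;    // nf
};

static FlatMesh flatten_mesh(const NumericMatrix &verts,
                             const IntegerMatrix &faces) {
  FlatMesh m;
  m.nf = faces.nrow();
  int nv = verts.nrow();
  const int *f0 = &faces(0, 0);
  const int *f1 = f0 + m.nf;
  const int *f2 = f1 + m.nf;
  const double *vx = &verts(0, 0);
  const double *vy = vx + nv;
  const double *vz = vy + nv;
  m.tri.resize(9 * (size_t)m.nf);
  m.cent.resize(3 * (size_t)m.nf);
  m.rad.resize(m.nf);
  for (int f = 0; f < m.nf; ++f) {
    int i0 = f0[f], i1 = f1[f], i2 = f2[f];
    double *t = &m.tri[9 * (size_t)f];
    t[0] = vx[i0]; t[1] = vy[i0]; t[2] = vz[i0];
    t[3] = vx[i1]; t[4] = vy[i1]; t[5] = vz[i1];
    t[6] = vx[i2]; t[7] = vy[i2]; t[8] = vz[i2];
    double mx = (t[0] + t[3] + t[6]) / 3.0;
    double my = (t[1] + t[4] + t[7]) / 3.0;
    double mz = (t[2] + t[5] + t[8]) / 3.0;
    m.cent[3 * (size_t)f] = mx;
    m.cent[3 * (size_t)f + 1] = my;
    m.cent[3 * (size_t)f + 2] = mz;
    double r2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      double dx = t[3*k] - mx, dy = t[3*k+1] - my, dz = t[3*k+2] - mz;
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > r2) r2 = d2;
    }
    m.rad[f] = std::sqrt(r2);
  }
  return m;
}

// nearest triangle scan for one point; exact (bounding-sphere pruning only
// rejects triangles that provably cannot strictly improve); lowest-index
// tie-break via strict improvement in ascending order
static inline void nearest_on_mesh(const FlatMesh &m, const double *p,
                                   double &best, int &bestf, double *bq,
                                   int hint = -1) {
  best = R_PosInf;
  bestf = -1;
  double q[3];
  if (hint >= 0 && hint < m.nf) {
    // warm start from a candidate triangle (e.g. last iteration's nearest):
    // a tight initial bound lets the bounding-sphere prune reject most of
    // the scan; the scan below remains exhaustive and exact
    const double *t = &m.tri[9 * (size_t)hint];
    closest_point_triangle(p, t, t + 3, t + 6, q);
    double ex = p[0]-q[0], ey = p[1]-q[1], ez = p[2]-q[2];
    best = std::sqrt(ex*ex + ey*ey + ez*ez);
    bestf = hint;
    bq[0] = q[0]; bq[1] = q[1]; bq[2] = q[2];
  }
  for (int f = 0; f < m.nf; ++f) {
    const double *ce = &m.cent[3 * (size_t)f];
    double dx = p[0]-ce[0], dy = p[1]-ce[1], dz = p[2]-ce[2];
    double dcent = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (dcent - m.rad[f] > best) continue;
    const double *t = &m.tri[9 * (size_t)f];
    closest_point_triangle(p, t, t + 3, t + 6, q);
    double ex = p[0]-q[0], ey = p[1]-q[1], ez = p[2]-q[2];
    double d = std::sqrt(ex*ex + ey*ey + ez*ez);
    if (d < best) {
      best = d; bestf = f;
      bq[0] = q[0]; bq[1] = q[1]; bq[2] = q[2];
    }
  }
}

// generalized winding number of one point (van Oosterom & Strackee solid
// angle per triangle, summed / 4pi)
static inline double winding_of_point(const FlatMesh &m, const double *p) {
  double acc = 0.0;
  for (int f = 0; f < m.nf; ++f) {
    const double *t = &m.tri[9 * (size_t)f];
    double ax = t[0]-p[0], ay = t[1]-p[1], az = t[2]-p[2];
    double bx = t[3]-p[0], by = t[4]-p[1], bz = t[5]-p[2];
    double cx = t[6]-p[0], cy = t[7]-p[1], cz = t[8]-p[2];
    double la = std::sqrt(ax*ax + ay*ay + az*az);
    double lb = std::sqrt(bx*bx + by*by + bz*bz);
    double lc = std::sqrt(cx*cx + cy*cy + cz*cz);
    double num = ax*(by*cz - bz*cy) - ay*(bx*cz - bz*cx) + az*(bx*cy - by*cx);
    double den = la*lb*lc + (ax*bx + ay*by + az*bz)*lc
               + (bx*cx + by*cy + bz*cz)*la
               + (ax*cx + ay*cy + az*cz)*lb;
    acc += 2.0 * std::atan2(num, den);
  }
  return acc / (4.0 * M_PI);
}

// Unsigned point-to-surface distances, nearest triangle (1-based) and
// nearest surface point per query point.
// [[Rcpp::export]]
List cpp_point_mesh_distance(NumericMatrix points, NumericMatrix verts,
                             IntegerMatrix faces) {
  int np = points.nrow();
  FlatMesh m = flatten_mesh(verts, faces);
  NumericVector dist(np);
  IntegerVector tri(np);
  NumericMatrix closest(np, 3);
  const double *px = &points(0, 0);
  const double *py = px + np;
  const double *pz = py + np;
  double p[3], bq[3];
  for (int ip = 0; ip < np; ++ip) {
    p[0] = px[ip]; p[1] = py[ip]; p[2] = pz[ip];
    double best; int bestf;
    bq[0] = bq[1] = bq[2] = 0.0;
    nearest_on_mesh(m, p, best, bestf, bq);
    dist[ip] = best;
    tri[ip] = bestf + 1;
    closest(ip, 0) = bq[0]; closest(ip, 1) = bq[1]; closest(ip, 2) = bq[2];
  }
  return List::create(_["distance"] = dist, _["triangle"] = tri,
                      _["closest"] = closest);
}

// Generalized winding numbers (~1 inside a closed outward surface).
// [[Rcpp::export]]
NumericVector cpp_winding_number(NumericMatrix points, NumericMatrix verts,
                                 IntegerMatrix faces) {
  int np = points.nrow();
  FlatMesh m = flatten_mesh(verts, faces);
  NumericVector w(np);
  const double *px = &points(0, 0);
  const double *py = px + np;
  const double *pz = py + np;
  double p[3];
  for (int ip = 0; ip < np; ++ip) {
    p[0] = px[ip]; p[1] = py[ip]; p[2] = pz[ip];
    w[ip] = winding_of_point(m, p);
  }
  return w;
}

// Fused signed query: unsigned nearest distance + winding-number sign in
// one pass (hot path of the elastic meniscus fit).  Points farther than
// sign_band from the surface skip the O(n_faces) winding evaluation and
// are reported positive; callers must guarantee no query point can lie
// deeper inside the surface than sign_band.
// [[Rcpp::export]]
List cpp_signed_mesh_query(NumericMatrix points, NumericMatrix verts,
                           IntegerMatrix faces,
                           double sign_band = R_PosInf,
                           IntegerVector hint = IntegerVector(0)) {
  int np = points.nrow();
  FlatMesh m = flatten_mesh(verts, faces);
  NumericVector dist(np);
  IntegerVector tri(np);
  NumericMatrix closest(np, 3);
  const double *px = &points(0, 0);
  const double *py = px + np;
  const double *pz = py + np;
  bool use_hint = hint.size() == np;
  double p[3], bq[3];
  for (int ip = 0; ip < np; ++ip) {
    p[0] = px[ip]; p[1] = py[ip]; p[2] = pz[ip];
    double best; int bestf;
    bq[0] = bq[1] = bq[2] = 0.0;
    nearest_on_mesh(m, p, best, bestf, bq,
                    use_hint ? hint[ip] - 1 : -1);
    if (best <= sign_band && winding_of_point(m, p) > 0.5) best = -best;
    dist[ip] = best;
    tri[ip] = bestf + 1;
    closest(ip, 0) = bq[0]; closest(ip, 1) = bq[1]; closest(ip, 2) = bq[2];
  }
  return List::create(_["distance"] = dist, _["triangle"] = tri,
                      _["closest"] = closest);
}
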