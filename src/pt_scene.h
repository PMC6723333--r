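#ifndef PT_SCENE_H
#define PT_SCENE_H

#include <cmath>
#include <cfloat>
#include <vector>

// Flattened scene used by the transport loop. Lengths are mm; interaction
// coefficients are mm^-1 (converted from the user-facing cm^-1 once, at
// scene build). Entities are tested in descending priority order so the
// innermost (tumour inside flesh inside air) wins point queries.

namespace pt {

struct Mat {
  double mua, mus, mu, g, n;
};

enum EntShape { ENT_BOX = 0, ENT_ELLIPSOID = 1, ENT_MESH = 2 };

struct Ent {
  int shape;
  int mat;                 // material index
  double p[6];             // box: lo/hi; ellipsoid: center + semi-axes
  const double *V;         // mesh vertices (nV x 3, column-major from R)
  int nV;
  const int *F;            // mesh faces (nF x 3, 0-based, column-major)
  int nF;
  double bb[6];            // mesh AABB
};

struct Hit {
  double t;
  double nrm[3];
  int ent;                 // -1 = domain boundary
};

inline double dot3(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

inline void cross3(const double *a, const double *b, double *o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}

inline bool insideBox(const double *p, const double *lo_hi) {
  return p[0] >= lo_hi[0] && p[0] <= lo_hi[3] && p[1] >= lo_hi[1] &&
         p[1] <= lo_hi[4] && p[2] >= lo_hi[2] && p[2] <= lo_hi[5];
}

inline bool insideEllipsoid(const double *p, const double *cs) {
  double s = 0;
  for (int a = 0; a < 3; ++a) {
    double u = (p[a] - cs[a]) / cs[3 + a];
    s += u * u;
  }
  return s <= 1.0;
}

// Nearest crossing (t > eps) of an axis-aligned box *surface*, from inside
// or outside. Returns false on miss. Normal is the face axis, oriented
// against the ray.
inline bool rayBox(const double *p, const double *d, const double *lo_hi,
                   double eps, double &t, double *nrm) {
  double tmin = -DBL_MAX, tmax = DBL_MAX;
  int axmin = -1, axmax = -1;
  for (int a = 0; a < 3; ++a) {
    double lo = lo_hi[a], hi = lo_hi[3 + a];
    if (d[a] != 0.0) {
      double t1 = (lo - p[a]) / d[a];
      double t2 = (hi - p[a]) / d[a];
      if (t1 > t2) { double tmp = t1; t1 = t2; t2 = tmp; }
      if (t1 > tmin) { tmin = t1; axmin = a; }
      if (t2 < tmax) { tmax = t2; axmax = a; }
    } else if (p[a] < lo || p[a] > hi) {
      return false;
    }
  }
  if (tmax < tmin) return false;
  int ax;
  if (tmin > eps) { t = tmin; ax = axmin; }
  else if (tmax > eps) { t = tmax; ax = axmax; }
  else return false;
  nrm[0] = nrm[1] = nrm[2] = 0.0;
  nrm[ax] = (d[ax] > 0) ? -1.0 : 1.0; // against the ray
  return true;
}

inline bool rayEllipsoid(const double *p, const double *d, const double *cs,
                         double eps, double &t, double *nrm) {
  double q[3], w[3];
  for (int a = 0; a < 3; ++a) {
    q[a] = (p[a] - cs[a]) / cs[3 + a];
    w[a] = d[a] / cs[3 + a];
  }
  double A = dot3(w, w), B = dot3(q, w), C = dot3(q, q) - 1.0;
  double disc = B * B - A * C;
  if (disc < 0) return false;
  double sq = std::sqrt(disc);
  double t1 = (-B - sq) / A, t2 = (-B + sq) / A;
  if (t1 > eps) t = t1;
  else if (t2 > eps) t = t2;
  else return false;
  double nn = 0;
  for (int a = 0; a < 3; ++a) {
    double x = p[a] + t * d[a];
    nrm[a] = (x - cs[a]) / (cs[3 + a] * cs[3 + a]);
    nn += nrm[a] * nrm[a];
  }
  nn = std::sqrt(nn);
  for (int a = 0; a < 3; ++a) nrm[a] /= nn;
  if (dot3(nrm, d) > 0)
    for (int a = 0; a < 3; ++a) nrm[a] = -nrm[a];
  return true;
}

// Moller-Trumbore; vertices/faces are column-major R matrices.
inline bool rayTriangle(const double *p, const double *d, const double *V,
                        int nV, const int *F, int nF, int f, double eps,
                        double &t, double *nrm) {
  int i0 = F[f], i1 = F[f + nF], i2 = F[f + 2 * nF];
  double v0[3], e1[3], e2[3];
  for (int a = 0; a < 3; ++a) {
    v0[a] = V[i0 + a * nV];
    e1[a] = V[i1 + a * nV] - v0[a];
    e2[a] = V[i2 + a * nV] - v0[a];
  }
  double pv[3];
  cross3(d, e2, pv);
  double det = dot3(e1, pv);
  if (std::fabs(det) < 1e-14) return false;
  double inv = 1.0 / det;
  double tv[3] = {p[0] - v0[0], p[1] - v0[1], p[2] - v0[2]};
  double u = dot3(tv, pv) * inv;
  if (u < 0 || u > 1) return false;
  double qv[3];
  cross3(tv, e1, qv);
  double v = dot3(d, qv) * inv;
  if (v < 0 || u + v > 1) return false;
  double tt = dot3(e2, qv) * inv;
  if (tt <= eps) return false;
  t = tt;
  cross3(e1, e2, nrm);
  double nn = std::sqrt(dot3(nrm, nrm));
  for (int a = 0; a < 3; ++a) nrm[a] /= nn;
  if (dot3(nrm, d) > 0)
    for (int a = 0; a < 3; ++a) nrm[a] = -nrm[a];
  return true;
}

inline bool rayAABBany(const double *p, const double *d, const double *bb) {
  double tmin = -DBL_MAX, tmax = DBL_MAX;
  for (int a = 0; a < 3; ++a) {
    if (d[a] != 0.0) {
      double t1 = (bb[a] - p[a]) / d[a];
      double t2 = (bb[3 + a] - p[a]) / d[a];
      if (t1 > t2) { double tmp = t1; t1 = t2; t2 = tmp; }
      if (t1 > tmin) tmin = t1;
      if (t2 < tmax) tmax = t2;
    } else if (p[a] < bb[a] || p[a] > bb[3 + a]) {
      return false;
    }
  }
  return tmax >= tmin && tmax > 0;
}

inline bool rayMesh(const double *p, const double *d, const Ent &e, double eps,
                    double &t, double *nrm) {
  if (!rayAABBany(p, d, e.bb)) return false;
  double best = DBL_MAX, tn[3], tt;
  bool found = false;
  for (int f = 0; f < e.nF; ++f) {
    if (rayTriangle(p, d, e.V, e.nV, e.F, e.nF, f, eps, tt, tn) && tt < best) {
      best = tt;
      nrm[0] = tn[0]; nrm[1] = tn[1]; nrm[2] = tn[2];
      found = true;
    }
  }
  if (found) t = best;
  return found;
}

// Parity test along +z with a tilted direction to dodge edge-on hits.
inline bool insideMesh(const double *p, const Ent &e) {
  if (!insideBox(p, e.bb)) return false;
  const double d[3] = {1.23456789e-4, 7.6543219e-5, 1.0};
  int crossings = 0;
  double t, nrm[3];
  for (int f = 0; f < e.nF; ++f)
    if (rayTriangle(p, d, e.V, e.nV, e.F, e.nF, f, 0.0, t, nrm)) ++crossings;
  return (crossings % 2) == 1;
}

struct Scene {
  double domain[6];                 // xlo,ylo,zlo,xhi,yhi,zhi
  std::vector<Mat> mats;
  std::vector<Ent> ents;            // sorted by priority, descending
  int ambient;

  bool insideEnt(const double *p, const Ent &e) const {
    switch (e.shape) {
    case ENT_BOX: return insideBox(p, e.p);
    case ENT_ELLIPSOID: return insideEllipsoid(p, e.p);
    default: return insideMesh(p, e);
    }
  }

  int mediumAt(const double *p) const {
    for (size_t i = 0; i < ents.size(); ++i)
      if (insideEnt(p, ents[i])) return ents[i].mat;
    return ambient;
  }

  // Nearest boundary (entity surface or domain exit) along d, t > eps.
  // The domain always bounds the walk, so a hit is guaranteed for rays
  // starting inside.
  bool nearestBoundary(const double *p, const double *d, double eps,
                       Hit &h) const {
    double t, nrm[3];
    h.t = DBL_MAX;
    h.ent = -2;
    if (rayBox(p, d, domain, eps, t, nrm)) {
      h.t = t;
      h.nrm[0] = nrm[0]; h.nrm[1] = nrm[1]; h.nrm[2] = nrm[2];
      h.ent = -1;
    }
    for (size_t i = 0; i < ents.size(); ++i) {
      const Ent &e = ents[i];
      bool got = false;
      switch (e.shape) {
      case ENT_BOX: got = rayBox(p, d, e.p, eps, t, nrm); break;
      case ENT_ELLIPSOID: got = rayEllipsoid(p, d, e.p, eps, t, nrm); break;
      default: got = rayMesh(p, d, e, eps, t, nrm); break;
      }
      if (got && t < h.t) {
        h.t = t;
        h.nrm[0] = nrm[0]; h.nrm[1] = nrm[1]; h.nrm[2] = nrm[2];
        h.ent = (int)i;
      }
    }
    return h.ent != -2;
  }
};

} // namespace pt

#endif
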