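#include <Rcpp.h>
#include "pt_rng.h"
#include "pt_scene.h"

using namespace Rcpp;

// Keeps the R matrices backing mesh entities alive while the flattened
// scene is in use.
struct SceneHolder {
  pt::Scene scene;
  std::vector<NumericMatrix> keepV;
  std::vector<IntegerMatrix> keepF;
};

static void unpackScene(const List &sceneList, SceneHolder &H) {
  NumericVector dom = sceneList["domain"];
  for (int i = 0; i < 6; ++i) H.scene.domain[i] = dom[i];
  NumericMatrix M = sceneList["materials"];
  H.scene.mats.resize(M.nrow());
  for (int i = 0; i < M.nrow(); ++i) {
    pt::Mat &m = H.scene.mats[i];
    m.mua = M(i, 0);
    m.mus = M(i, 1);
    m.mu = m.mua + m.mus;
    m.g = M(i, 2);
    m.n = M(i, 3);
  }
  H.scene.ambient = as<int>(sceneList["ambient"]) - 1;
  List ents = sceneList["entities"];
  H.scene.ents.resize(ents.size());
  // reserve so stored data pointers are never invalidated by reallocation
  H.keepV.reserve(ents.size());
  H.keepF.reserve(ents.size());
  for (int i = 0; i < ents.size(); ++i) {
    List e = ents[i];
    pt::Ent &E = H.scene.ents[i];
    E.shape = as<int>(e["shape"]);
    E.mat = as<int>(e["material"]) - 1;
    NumericVector p = e["params"];
    for (int j = 0; j < 6 && j < p.size(); ++j) E.p[j] = p[j];
    E.V = nullptr; E.F = nullptr; E.nV = 0; E.nF = 0;
    if (E.shape == pt::ENT_MESH) {
      NumericMatrix V = e["vertices"];
      IntegerMatrix F = e["faces"];
      H.keepV.push_back(V);
      H.keepF.push_back(F);
      E.V = H.keepV.back().begin();
      E.nV = V.nrow();
      E.F = H.keepF.back().begin();
      E.nF = F.nrow();
      for (int a = 0; a < 3; ++a) {
        double lo = R_PosInf, hi = R_NegInf;
        for (int v = 0; v < E.nV; ++v) {
          double x = E.V[v + a * E.nV];
          if (x < lo) lo = x;
          if (x > hi) hi = x;
        }
        E.bb[a] = lo - 1e-9;
        E.bb[3 + a] = hi + 1e-9;
      }
    }
  }
}

struct GridSpec {
  double lo[3], h[3];
  int n[3];
};

// Incremental 3-D DDA voxel walk (Amanatides & Woo): adds w * mua * dl
// for the in-voxel path dl of the segment p0 -> p1 to the tally.
static void tallySegment(double *acc, const GridSpec &g, const double *p0,
                         const double *p1, double wmua) {
  double seg[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
  double len = std::sqrt(pt::dot3(seg, seg));
  if (len <= 0 || wmua <= 0) return;
  double d[3] = {seg[0] / len, seg[1] / len, seg[2] / len};
  int idx[3], step[3];
  double tMax[3], tDelta[3];
  for (int a = 0; a < 3; ++a) {
    int i = (int)std::floor((p0[a] - g.lo[a]) / g.h[a]);
    if (i < 0) i = 0;
    if (i >= g.n[a]) i = g.n[a] - 1;
    idx[a] = i;
    if (d[a] > 0) {
      step[a] = 1;
      tMax[a] = (g.lo[a] + (i + 1) * g.h[a] - p0[a]) / d[a];
      tDelta[a] = g.h[a] / d[a];
    } else if (d[a] < 0) {
      step[a] = -1;
      tMax[a] = (g.lo[a] + i * g.h[a] - p0[a]) / d[a];
      tDelta[a] = -g.h[a] / d[a];
    } else {
      step[a] = 0;
      tMax[a] = DBL_MAX;
      tDelta[a] = DBL_MAX;
    }
  }
  double t = 0.0;
  while (t < len) {
    int ax = 0;
    if (tMax[1] < tMax[ax]) ax = 1;
    if (tMax[2] < tMax[ax]) ax = 2;
    double tNext = tMax[ax] < len ? tMax[ax] : len;
    double dl = tNext - t;
    if (dl > 0)
      acc[idx[0] + (size_t)g.n[0] * (idx[1] + (size_t)g.n[1] * idx[2])] +=
          wmua * dl;
    t = tNext;
    if (tMax[ax] >= len) break;
    idx[ax] += step[ax];
    if (idx[ax] < 0 || idx[ax] >= g.n[ax]) break; // left the grid
    tMax[ax] += tDelta[ax];
  }
}

static inline double fresnelR(double n1, double n2, double ci) {
  if (n1 == n2) return 0.0;
  double r = n1 / n2;
  double st2 = r * r * (1.0 - ci * ci);
  if (st2 >= 1.0) return 1.0; // total internal reflection
  double ct = std::sqrt(1.0 - st2);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

static inline void scatterHG(double *d, double g, double u1, double u2) {
  double ct;
  if (std::fabs(g) < 1e-8) {
    ct = 1.0 - 2.0 * u1;
  } else {
    double s = (1.0 - g * g) / (1.0 - g + 2.0 * g * u1);
    ct = (1.0 + g * g - s * s) / (2.0 * g);
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
  }
  double st = std::sqrt(1.0 - ct * ct);
  double phi = 2.0 * M_PI * u2;
  double cp = std::cos(phi), sp = std::sin(phi);
  // local frame around current direction
  double w[3] = {d[0], d[1], d[2]};
  double a[3] = {0, 0, 1};
  if (std::fabs(w[2]) > 0.99999) { a[0] = 1; a[2] = 0; }
  double u[3], v[3];
  pt::cross3(a, w, u);
  double un = std::sqrt(pt::dot3(u, u));
  for (int i = 0; i < 3; ++i) u[i] /= un;
  pt::cross3(w, u, v);
  for (int i = 0; i < 3; ++i)
    d[i] = st * cp * u[i] + st * sp * v[i] + ct * w[i];
  double dn = std::sqrt(pt::dot3(d, d));
  for (int i = 0; i < 3; ++i) d[i] /= dn;
}

static const double EPS_HIT = 1e-9;  // minimum accepted hit distance (mm)
static const double NUDGE = 1e-7;    // post-event advance (mm)

// [[Rcpp::export]]
List runTransportC(List sceneList, NumericMatrix srcTri, NumericVector srcDir,
                   double nPackets, IntegerVector nCells, double wMin,
                   double pSurvive, double seed, double maxEvents) {
  SceneHolder H;
  unpackScene(sceneList, H);
  const pt::Scene &S = H.scene;

  GridSpec G;
  for (int a = 0; a < 3; ++a) {
    G.lo[a] = S.domain[a];
    G.n[a] = nCells[a];
    G.h[a] = (S.domain[3 + a] - S.domain[a]) / nCells[a];
  }

  // source triangle fan: cumulative areas for area-uniform emission
  int nT = srcTri.nrow();
  std::vector<double> cdf(nT);
  double atot = 0;
  for (int f = 0; f < nT; ++f) {
    double e1[3], e2[3], cr[3];
    for (int a = 0; a < 3; ++a) {
      e1[a] = srcTri(f, 3 + a) - srcTri(f, a);
      e2[a] = srcTri(f, 6 + a) - srcTri(f, a);
    }
    pt::cross3(e1, e2, cr);
    atot += 0.5 * std::sqrt(pt::dot3(cr, cr));
    cdf[f] = atot;
  }
  double dir0[3] = {srcDir[0], srcDir[1], srcDir[2]};
  double d0n = std::sqrt(pt::dot3(dir0, dir0));
  for (int a = 0; a < 3; ++a) dir0[a] /= d0n;

  size_t nvox = (size_t)G.n[0] * G.n[1] * G.n[2];
  NumericVector tally(nvox); // sum of w * l * mua, dimensionless
  double *acc = tally.begin();

  double absorbed = 0, escaped = 0, killed = 0, lost = 0;
  double nEvents = 0;
  long long N = (long long)nPackets;
  uint64_t useed = (uint64_t)seed;

  for (long long i = 0; i < N; ++i) {
    if ((i & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    pt::Rng rng(useed, (uint64_t)i);

    // emit from a random point on the source surface, along its normal
    double r = rng.u01() * atot;
    int f = 0;
    while (f < nT - 1 && cdf[f] < r) ++f;
    double b1 = rng.u01(), b2 = rng.u01();
    if (b1 + b2 > 1.0) { b1 = 1.0 - b1; b2 = 1.0 - b2; }
    double pos[3], dir[3] = {dir0[0], dir0[1], dir0[2]};
    for (int a = 0; a < 3; ++a) {
      double v0 = srcTri(f, a), v1 = srcTri(f, 3 + a), v2 = srcTri(f, 6 + a);
      pos[a] = v0 + b1 * (v1 - v0) + b2 * (v2 - v0) + NUDGE * dir[a];
    }
    double w = 1.0;
    int med = S.mediumAt(pos);
    long events = 0;

    while (true) {
      if (++events > maxEvents) { lost += w; break; }
      const pt::Mat &m = S.mats[med];
      pt::Hit h;
      if (!S.nearestBoundary(pos, dir, EPS_HIT, h)) { lost += w; break; }

      bool toBoundary;
      double l;
      if (m.mu <= 0) {          // non-interacting (air): fly to boundary
        toBoundary = true;
        l = h.t;
      } else {
        l = -std::log(1.0 - rng.u01()) / m.mu;
        toBoundary = (h.t <= l);
        if (toBoundary) l = h.t;
      }

      double pend[3] = {pos[0] + l * dir[0], pos[1] + l * dir[1],
                        pos[2] + l * dir[2]};
      if (m.mua > 0) tallySegment(acc, G, pos, pend, w * m.mua);
      pos[0] = pend[0]; pos[1] = pend[1]; pos[2] = pend[2];

      if (toBoundary) {
        if (h.ent == -1) { escaped += w; break; } // left the domain
        double ci = -pt::dot3(dir, h.nrm);        // normal is against the ray
        if (ci < 0) ci = 0;
        double probe[3] = {pos[0] + 1e-6 * dir[0], pos[1] + 1e-6 * dir[1],
                           pos[2] + 1e-6 * dir[2]};
        int medOut = S.mediumAt(probe);
        double n1 = S.mats[med].n, n2 = S.mats[medOut].n;
        double R = fresnelR(n1, n2, ci);
        if (R > 0 && rng.u01() < R) {
          for (int a = 0; a < 3; ++a) dir[a] += 2.0 * ci * h.nrm[a];
          double dn = std::sqrt(pt::dot3(dir, dir));
          for (int a = 0; a < 3; ++a) dir[a] /= dn;
        } else {
          if (n1 != n2) {
            double rr = n1 / n2;
            double st2 = rr * rr * (1.0 - ci * ci);
            double ct = std::sqrt(st2 < 1.0 ? 1.0 - st2 : 0.0);
            for (int a = 0; a < 3; ++a)
              dir[a] = rr * dir[a] + (rr * ci - ct) * h.nrm[a];
            double dn = std::sqrt(pt::dot3(dir, dir));
            for (int a = 0; a < 3; ++a) dir[a] /= dn;
          }
          med = medOut;
        }
        for (int a = 0; a < 3; ++a) pos[a] += NUDGE * dir[a];
      } else {
        // scattering event: deposit the absorbed fraction, keep the rest
        absorbed += w * m.mua / m.mu;
        w *= m.mus / m.mu;
        nEvents += 1;
        if (w <= 0) break; // pure absorber
        scatterHG(dir, m.g, rng.u01(), rng.u01());
        if (wMin > 0 && w < wMin) {
          if (rng.u01() < pSurvive) w /= pSurvive;
          else { killed += w; break; }
        }
      }
    }
  }

  return List::create(_["tally"] = tally, _["absorbed"] = absorbed,
                      _["escaped"] = escaped, _["killed"] = killed,
                      _["lost"] = lost, _["n_events"] = nEvents,
                      _["source_area"] = atot);
}

// Material index (1-based) at each voxel center, x fastest.
// [[Rcpp::export]]
IntegerVector classifyGridC(List sceneList, IntegerVector nCells) {
  SceneHolder H;
  unpackScene(sceneList, H);
  const pt::Scene &S = H.scene;
  int nx = nCells[0], ny = nCells[1], nz = nCells[2];
  double h[3], lo[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = S.domain[a];
    h[a] = (S.domain[3 + a] - S.domain[a]) / nCells[a];
  }
  IntegerVector out((size_t)nx * ny * nz);
  size_t k = 0;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        double p[3] = {lo[0] + (ix + 0.5) * h[0], lo[1] + (iy + 0.5) * h[1],
                       lo[2] + (iz + 0.5) * h[2]};
        out[k++] = S.mediumAt(p) + 1;
      }
  return out;
}

// Per-voxel path lengths of one segment (dense cube, test use only).
// [[Rcpp::export]]
NumericVector tallySegmentC(NumericVector domain, IntegerVector nCells,
                            NumericVector p0, NumericVector p1) {
  GridSpec G;
  for (int a = 0; a < 3; ++a) {
    G.lo[a] = domain[a];
    G.n[a] = nCells[a];
    G.h[a] = (domain[3 + a] - domain[a]) / nCells[a];
  }
  NumericVector out((size_t)G.n[0] * G.n[1] * G.n[2]);
  double q0[3] = {p0[0], p0[1], p0[2]}, q1[3] = {p1[0], p1[1], p1[2]};
  tallySegment(out.begin(), G, q0, q1, 1.0); // unit w * mua => raw lengths
  return out;
}

// Henyey-Greenstein deflection cosines from the engine's sampler.
// [[Rcpp::export]]
NumericVector sampleHGC(double g, int n, double seed) {
  pt::Rng rng((uint64_t)seed, 12345u);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double d[3] = {0, 0, 1};
    scatterHG(d, g, rng.u01(), rng.u01());
    out[i] = d[2];
  }
  return out;
}

// Nearest mesh intersection for the R-level ray query.
// [[Rcpp::export]]
List rayMeshC(NumericMatrix V, IntegerMatrix F, NumericVector origin,
              NumericVector dir, double eps) {
  pt::Ent E;
  E.shape = pt::ENT_MESH;
  E.mat = 0;
  E.V = V.begin(); E.nV = V.nrow();
  E.F = F.begin(); E.nF = F.nrow();
  for (int a = 0; a < 3; ++a) {
    double lo = R_PosInf, hi = R_NegInf;
    for (int v = 0; v < E.nV; ++v) {
      double x = E.V[v + a * E.nV];
      if (x < lo) lo = x;
      if (x > hi) hi = x;
    }
    E.bb[a] = lo - 1e-9;
    E.bb[3 + a] = hi + 1e-9;
  }
  double p[3] = {origin[0], origin[1], origin[2]};
  double d[3] = {dir[0], dir[1], dir[2]};
  double t, nrm[3];
  if (pt::rayMesh(p, d, E, eps, t, nrm))
    return List::create(_["hit"] = true, _["distance"] = t,
                        _["normal"] = NumericVector::create(nrm[0], nrm[1],
                                                            nrm[2]));
  return List::create(_["hit"] = false);
}

// Point-in-mesh parity test for a set of points (rows of P).
// [[Rcpp::export]]
LogicalVector insideMeshC(NumericMatrix V, IntegerMatrix F, NumericMatrix P) {
  pt::Ent E;
  E.shape = pt::ENT_MESH;
  E.mat = 0;
  E.V = V.begin(); E.nV = V.nrow();
  E.F = F.begin(); E.nF = F.nrow();
  for (int a = 0; a < 3; ++a) {
    double lo = R_PosInf, hi = R_NegInf;
    for (int v = 0; v < E.nV; ++v) {
      double x = E.V[v + a * E.nV];
      if (x < lo) lo = x;
      if (x > hi) hi = x;
    }
    E.bb[a] = lo - 1e-9;
    E.bb[3 + a] = hi + 1e-9;
  }
  LogicalVector out(P.nrow());
  for (int i = 0; i < P.nrow(); ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    out[i] = pt::insideMesh(p, E);
  }
  return out;
}
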