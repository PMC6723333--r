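#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Explicit forward-Euler stepping of Pennes' bioheat equation
//   rho c dT/dt = k lap(T) - B (T - Ta) + Q
// on a uniform voxel grid. Voxel labels: 0 = excluded (air; interfaces to
// it are adiabatic), 1 = active tissue, 2 = clamped (held at its initial
// value, used for the far-field faces of the flesh cube). Neighbours
// beyond the grid edge mirror the centre value (insulated outer wall).
// Only voxels inside the supplied bounding box are visited; the box must
// contain every non-air voxel.

// [[Rcpp::export]]
NumericVector heatStepsC(NumericVector T0, NumericVector q,
                         IntegerVector label, IntegerVector dims,
                         NumericVector voxel_m, double rho, double cp,
                         double k, double B, double Ta, double dt,
                         int nsteps, IntegerVector bbox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nvox = (size_t)nx * ny * nz;
  const double ix2 = 1.0 / (voxel_m[0] * voxel_m[0]);
  const double iy2 = 1.0 / (voxel_m[1] * voxel_m[1]);
  const double iz2 = 1.0 / (voxel_m[2] * voxel_m[2]);
  const double a = dt / (rho * cp);

  std::vector<double> A(T0.begin(), T0.end());
  std::vector<double> Bf(T0.begin(), T0.end());
  double *cur = A.data(), *nxt = Bf.data();
  const double *Q = q.begin();
  const int *lab = label.begin();

  const int x0 = bbox[0], x1 = bbox[1], y0 = bbox[2], y1 = bbox[3],
            z0 = bbox[4], z1 = bbox[5];
  const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;

  for (int s = 0; s < nsteps; ++s) {
    if ((s & 1023) == 0) Rcpp::checkUserInterrupt();
    for (int iz = z0; iz <= z1; ++iz) {
      for (int iy = y0; iy <= y1; ++iy) {
        size_t base = sy * iy + sz * iz;
        for (int ix = x0; ix <= x1; ++ix) {
          size_t i = base + ix;
          if (lab[i] != 1) continue;
          double Tc = cur[i];
          double Txm = (ix > 0 && lab[i - sx] != 0) ? cur[i - sx] : Tc;
          double Txp = (ix < nx - 1 && lab[i + sx] != 0) ? cur[i + sx] : Tc;
          double Tym = (iy > 0 && lab[i - sy] != 0) ? cur[i - sy] : Tc;
          double Typ = (iy < ny - 1 && lab[i + sy] != 0) ? cur[i + sy] : Tc;
          double Tzm = (iz > 0 && lab[i - sz] != 0) ? cur[i - sz] : Tc;
          double Tzp = (iz < nz - 1 && lab[i + sz] != 0) ? cur[i + sz] : Tc;
          double lap = (Txm - 2.0 * Tc + Txp) * ix2 +
                       (Tym - 2.0 * Tc + Typ) * iy2 +
                       (Tzm - 2.0 * Tc + Tzp) * iz2;
          nxt[i] = Tc + a * (k * lap - B * (Tc - Ta) + Q[i]);
        }
      }
    }
    std::swap(cur, nxt);
  }

  NumericVector out(nvox);
  std::copy(cur, cur + nvox, out.begin());
  return out;
}
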