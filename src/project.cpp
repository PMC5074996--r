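// Parallel-beam maximum intensity projection at an arbitrary view angle
// about the vertical (y) axis. Angle 0 views along +z, so the projection
// plane is the (x, y) plane of the volume.
#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_mip(NumericVector vol, IntegerVector dims, double angle_deg) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *pv = REAL(vol);
  NumericMatrix out(nx, ny);
  double a = std::fmod(angle_deg, 360.0);
  if (a < 0) a += 360.0;
  if (a == 0.0) {
    // exact per-column maximum
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double m = -std::numeric_limits<double>::infinity();
        for (int k = 0; k < nz; ++k) {
          double v = pv[i + (size_t)nx * (j + (size_t)ny * k)];
          if (v > m) m = v;
        }
        out(i, j) = m;
      }
    return out;
  }
  double th = a * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  double cx = (nx - 1) / 2.0, cz = (nz - 1) / 2.0;
  double diag = std::sqrt((double)nx * nx + (double)nz * nz);
  int nsteps = (int)std::ceil(diag / 0.5) + 1;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double m = NA_REAL;
      bool hit = false;
      double u = i - cx;
      for (int s = 0; s < nsteps; ++s) {
        double w = s * 0.5 - diag / 2.0;
        // rotate view coords (u, w) back into volume coords
        double x = cx + ct * u - st * w;
        double z = cz + st * u + ct * w;
        if (x < 0 || x > nx - 1 || z < 0 || z > nz - 1) continue;
        int x0 = (int)std::floor(x), z0 = (int)std::floor(z);
        if (x0 == nx - 1) x0 = nx - 2;
        if (z0 == nz - 1) z0 = nz - 2;
        double fx = x - x0, fz = z - z0;
        size_t b00 = x0 + (size_t)nx * (j + (size_t)ny * z0);
        size_t b01 = x0 + (size_t)nx * (j + (size_t)ny * (z0 + 1));
        double v = (1 - fx) * (1 - fz) * pv[b00] + fx * (1 - fz) * pv[b00 + 1]
                 + (1 - fx) * fz * pv[b01] + fx * fz * pv[b01 + 1];
        if (!hit || v > m) { m = v; hit = true; }
      }
      out(i, j) = m;
    }
  return out;
}
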