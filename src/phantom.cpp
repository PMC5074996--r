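// Rasterization of analytic tube/capsule phantoms with subvoxel
// (supersampled) partial-volume averaging at the surfaces.
#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Tubes are straight cylinders given by a point p0, a unit axis u, a radius,
// and an axial parameter range [tmin, tmax] (+/-Inf for "long" tubes that
// span the whole volume). Finite segments are capsules (rounded ends) so
// that consecutive tree segments join smoothly.
// Voxel (i,j,k) (0-based) has its center at world coordinate (i,j,k).
// [[Rcpp::export]]
NumericVector cpp_rasterize_tubes(IntegerVector dims, NumericMatrix p0,
                                  NumericMatrix axis, NumericVector radius,
                                  NumericVector tmin, NumericVector tmax,
                                  double fg, double bg, int ss) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  int nt = radius.size();
  NumericVector out(nvox);
  std::fill(REAL(out), REAL(out) + nvox, bg);
  double halfdiag = 0.8660254037844386;  // sqrt(3)/2, voxel circumradius
  std::vector<double> offs(ss);
  for (int s = 0; s < ss; ++s) offs[s] = (s + 0.5) / ss - 0.5;
  double *po = REAL(out);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t v = i + (size_t)nx * (j + (size_t)ny * k);
        bool inside_any = false, near_any = false;
        for (int t = 0; t < nt; ++t) {
          double wx = i - p0(t, 0), wy = j - p0(t, 1), wz = k - p0(t, 2);
          double tt = wx * axis(t, 0) + wy * axis(t, 1) + wz * axis(t, 2);
          if (tt < tmin[t]) tt = tmin[t];
          if (tt > tmax[t]) tt = tmax[t];
          double dx = wx - tt * axis(t, 0);
          double dy = wy - tt * axis(t, 1);
          double dz = wz - tt * axis(t, 2);
          double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (d <= radius[t] - halfdiag) { inside_any = true; break; }
          if (d < radius[t] + halfdiag) near_any = true;
        }
        if (inside_any) { po[v] = fg; continue; }
        if (!near_any) continue;
        // surface voxel: supersample
        int cnt = 0;
        for (int sz = 0; sz < ss; ++sz)
          for (int sy = 0; sy < ss; ++sy)
            for (int sx = 0; sx < ss; ++sx) {
              double px = i + offs[sx], py = j + offs[sy], pz = k + offs[sz];
              bool in = false;
              for (int t = 0; t < nt && !in; ++t) {
                double wx = px - p0(t, 0), wy = py - p0(t, 1),
                       wz = pz - p0(t, 2);
                double tt = wx * axis(t, 0) + wy * axis(t, 1)
                          + wz * axis(t, 2);
                if (tt < tmin[t]) tt = tmin[t];
                if (tt > tmax[t]) tt = tmax[t];
                double dx = wx - tt * axis(t, 0);
                double dy = wy - tt * axis(t, 1);
                double dz = wz - tt * axis(t, 2);
                if (dx * dx + dy * dy + dz * dz <= radius[t] * radius[t])
                  in = true;
              }
              if (in) ++cnt;
            }
        po[v] = bg + (fg - bg) * (double)cnt / ((double)ss * ss * ss);
      }
  return out;
}
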