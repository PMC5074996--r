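// Gaussian scale-space primitives: separable FIR smoothing with symmetric
// (reflected) boundaries, central-difference derivatives, and the streaming
// multi-scale vesselness driver. All grids are passed as flat doubles in
// R array order (first index fastest): idx = i + nx*(j + ny*k).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline int reflect_idx(int j, int n) {
  // symmetric boundary: (d c b a | a b c d | d c b a)
  while (j < 0 || j >= n) {
    if (j < 0) j = -j - 1;
    if (j >= n) j = 2 * n - 1 - j;
  }
  return j;
}

static std::vector<double> gauss_kernel(double sigma) {
  int R = (int)std::ceil(3.0 * sigma);
  if (R < 1) R = 1;
  std::vector<double> k(2 * R + 1);
  double s = 0.0;
  for (int t = -R; t <= R; ++t) {
    double v = std::exp(-0.5 * (double)t * t / (sigma * sigma));
    k[t + R] = v;
    s += v;
  }
  for (auto &v : k) v /= s;
  return k;
}

static void conv_line(const double *in, double *out, int n,
                      const double *k, int R) {
  int w = 2 * R + 1;
  int lo = R < n ? R : n;
  int hi = n - R;
  if (hi < lo) hi = lo;
  for (int p = 0; p < lo; ++p) {
    double s = 0.0;
    for (int t = -R; t <= R; ++t) s += in[reflect_idx(p + t, n)] * k[t + R];
    out[p] = s;
  }
  for (int p = lo; p < hi; ++p) {
    const double *q = in + p;
    double s = q[0] * k[R];
    for (int t = 1; t <= R; ++t) s += (q[-t] + q[t]) * k[R + t];
    out[p] = s;
  }
  (void)w;
  for (int p = hi; p < n; ++p) {
    if (p < lo) continue;
    double s = 0.0;
    for (int t = -R; t <= R; ++t) s += in[reflect_idx(p + t, n)] * k[t + R];
    out[p] = s;
  }
}

// Convolve along a strided axis for a block of BL adjacent x positions at
// once; the block is staged in a contiguous (n x BL) buffer so both the
// gather and the inner convolution loop stream through cache lines.
#define CONV_BLOCK 16

static void conv_block_strided(const double *base, double *obase,
                               size_t stride, int n, int bl,
                               const double *k, int R,
                               std::vector<double> &buf,
                               std::vector<double> &obuf) {
  for (int j = 0; j < n; ++j) {
    const double *src = base + (size_t)j * stride;
    double *d = &buf[(size_t)(j + R) * bl];
    for (int b = 0; b < bl; ++b) d[b] = src[b];
  }
  // reflected padding on both ends
  for (int j = 0; j < R; ++j) {
    int jr = reflect_idx(-1 - j, n);
    const double *src = base + (size_t)jr * stride;
    double *d = &buf[(size_t)(R - 1 - j) * bl];
    for (int b = 0; b < bl; ++b) d[b] = src[b];
    jr = reflect_idx(n + j, n);
    src = base + (size_t)jr * stride;
    d = &buf[(size_t)(n + R + j) * bl];
    for (int b = 0; b < bl; ++b) d[b] = src[b];
  }
  int w = 2 * R + 1;
  for (int j = 0; j < n; ++j) {
    double *acc = &obuf[0];
    for (int b = 0; b < bl; ++b) acc[b] = 0.0;
    const double *q = &buf[(size_t)j * bl];
    for (int t = 0; t < w; ++t) {
      double kv = k[t];
      const double *qq = q + (size_t)t * bl;
      for (int b = 0; b < bl; ++b) acc[b] += kv * qq[b];
    }
    double *dst = obase + (size_t)j * stride;
    for (int b = 0; b < bl; ++b) dst[b] = acc[b];
  }
}

// axis: 0 = x (stride 1), 1 = y (stride nx), 2 = z (stride nx*ny)
static void smooth_axis(const double *in, double *out,
                        int nx, int ny, int nz, int axis,
                        const std::vector<double> &k) {
  int R = ((int)k.size() - 1) / 2;
  if (axis == 0) {
    std::vector<double> lb(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        const double *src = in + (size_t)nx * (y + (size_t)ny * z);
        double *dst = out + (size_t)nx * (y + (size_t)ny * z);
        conv_line(src, lb.data(), nx, k.data(), R);
        for (int i = 0; i < nx; ++i) dst[i] = lb[i];
      }
    return;
  }
  int n = (axis == 1) ? ny : nz;
  size_t stride = (axis == 1) ? (size_t)nx : (size_t)nx * ny;
  std::vector<double> buf((size_t)(n + 2 * R) * CONV_BLOCK);
  std::vector<double> obuf(CONV_BLOCK);
  int nouter = (axis == 1) ? nz : ny;
  for (int o = 0; o < nouter; ++o) {
    size_t plane = (axis == 1) ? (size_t)nx * ny * o : (size_t)nx * o;
    for (int i0 = 0; i0 < nx; i0 += CONV_BLOCK) {
      int bl = std::min(CONV_BLOCK, nx - i0);
      conv_block_strided(in + plane + i0, out + plane + i0, stride, n, bl,
                         k.data(), R, buf, obuf);
    }
  }
}

static void gaussian_smooth_3d(const double *in, double *out, double *tmp,
                               int nx, int ny, int nz, double sigma) {
  std::vector<double> k = gauss_kernel(sigma);
  smooth_axis(in, out, nx, ny, nz, 0, k);
  smooth_axis(out, tmp, nx, ny, nz, 1, k);
  smooth_axis(tmp, out, nx, ny, nz, 2, k);
}

// central differences, one-sided at the borders (np.gradient convention)
static void diff_axis(const double *in, double *out,
                      int nx, int ny, int nz, int axis) {
  size_t stride = (axis == 0) ? 1 : (axis == 1) ? (size_t)nx : (size_t)nx * ny;
  int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      size_t row = (size_t)nx * (y + (size_t)ny * z);
      int idx0 = (axis == 0) ? -1 : (axis == 1) ? y : z;
      if (axis == 0) {
        out[row] = in[row + 1] - in[row];
        for (int i = 1; i < nx - 1; ++i)
          out[row + i] = 0.5 * (in[row + i + 1] - in[row + i - 1]);
        out[row + nx - 1] = in[row + nx - 1] - in[row + nx - 2];
      } else if (idx0 == 0) {
        for (int i = 0; i < nx; ++i)
          out[row + i] = in[row + i + stride] - in[row + i];
      } else if (idx0 == n - 1) {
        for (int i = 0; i < nx; ++i)
          out[row + i] = in[row + i] - in[row + i - stride];
      } else {
        for (int i = 0; i < nx; ++i)
          out[row + i] = 0.5 * (in[row + i + stride] - in[row + i - stride]);
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector vol, IntegerVector dims,
                                  double sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  NumericVector out(vol.size());
  std::vector<double> tmp(nvox);
  gaussian_smooth_3d(REAL(vol), REAL(out), tmp.data(), nx, ny, nz, sigma);
  return out;
}

// [[Rcpp::export]]
List cpp_hessian_at_scale(NumericVector vol, IntegerVector dims,
                          double sigma, double snorm) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  std::vector<double> sm(nvox), tmp(nvox), g(nvox);
  gaussian_smooth_3d(REAL(vol), sm.data(), tmp.data(), nx, ny, nz, sigma);
  NumericVector hxx(nvox), hxy(nvox), hxz(nvox), hyy(nvox), hyz(nvox), hzz(nvox);
  diff_axis(sm.data(), g.data(), nx, ny, nz, 0);
  diff_axis(g.data(), REAL(hxx), nx, ny, nz, 0);
  diff_axis(g.data(), REAL(hxy), nx, ny, nz, 1);
  diff_axis(g.data(), REAL(hxz), nx, ny, nz, 2);
  diff_axis(sm.data(), g.data(), nx, ny, nz, 1);
  diff_axis(g.data(), REAL(hyy), nx, ny, nz, 1);
  diff_axis(g.data(), REAL(hyz), nx, ny, nz, 2);
  diff_axis(sm.data(), g.data(), nx, ny, nz, 2);
  diff_axis(g.data(), REAL(hzz), nx, ny, nz, 2);
  for (size_t v = 0; v < nvox; ++v) {
    REAL(hxx)[v] *= snorm; REAL(hxy)[v] *= snorm; REAL(hxz)[v] *= snorm;
    REAL(hyy)[v] *= snorm; REAL(hyz)[v] *= snorm; REAL(hzz)[v] *= snorm;
  }
  return List::create(_["xx"] = hxx, _["xy"] = hxy, _["xz"] = hxz,
                      _["yy"] = hyy, _["yz"] = hyz, _["zz"] = hzz);
}

// analytic eigenvalues of a symmetric 3x3 matrix, sorted |l1| <= |l2| <= |l3|
static inline void eig_sym3(double a11, double a12, double a13,
                            double a22, double a23, double a33,
                            double &l1, double &l2, double &l3) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  double e1, e2, e3;
  if (p1 == 0.0) {
    e1 = a11; e2 = a22; e3 = a33;
  } else {
    double q = (a11 + a22 + a33) / 3.0;
    double b11 = a11 - q, b22 = a22 - q, b33 = a33 - q;
    double p2 = b11 * b11 + b22 * b22 + b33 * b33 + 2.0 * p1;
    double p = std::sqrt(p2 / 6.0);
    // det(B)/2 with B = (A - qI)/p
    double detB = b11 * (b22 * b33 - a23 * a23)
                - a12 * (a12 * b33 - a23 * a13)
                + a13 * (a12 * a23 - b22 * a13);
    double r = detB / (2.0 * p * p * p);
    if (r < -1.0) r = -1.0;
    if (r > 1.0) r = 1.0;
    double phi = std::acos(r) / 3.0;
    e1 = q + 2.0 * p * std::cos(phi);
    e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    e2 = 3.0 * q - e1 - e3;
  }
  // sort by absolute value ascending
  double a[3] = {e1, e2, e3};
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2 - i; ++j)
      if (std::fabs(a[j]) > std::fabs(a[j + 1])) std::swap(a[j], a[j + 1]);
  l1 = a[0]; l2 = a[1]; l3 = a[2];
}

// [[Rcpp::export]]
List cpp_eigvals_sym3(NumericVector hxx, NumericVector hxy, NumericVector hxz,
                      NumericVector hyy, NumericVector hyz, NumericVector hzz) {
  size_t n = hxx.size();
  NumericVector l1(n), l2(n), l3(n);
  for (size_t v = 0; v < n; ++v) {
    double a, b, c;
    eig_sym3(hxx[v], hxy[v], hxz[v], hyy[v], hyz[v], hzz[v], a, b, c);
    l1[v] = a; l2[v] = b; l3[v] = c;
  }
  return List::create(_["lam1"] = l1, _["lam2"] = l2, _["lam3"] = l3);
}

static inline double frangi_v(double l1, double l2, double l3,
                              double alpha, double beta, double c,
                              bool bright) {
  if (bright) {
    if (l2 > 0.0 || l3 > 0.0) return 0.0;
  } else {
    if (l2 < 0.0 || l3 < 0.0) return 0.0;
  }
  double a3 = std::fabs(l3);
  if (a3 == 0.0) return 0.0;
  double a2 = std::fabs(l2);
  double prod = a2 * a3;
  if (prod == 0.0) return 0.0;
  double Ra = a2 / a3;
  double Rb = std::fabs(l1) / std::sqrt(prod);
  double S2 = l1 * l1 + l2 * l2 + l3 * l3;
  double va = 1.0 - std::exp(-Ra * Ra / (2.0 * alpha * alpha));
  double vb = std::exp(-Rb * Rb / (2.0 * beta * beta));
  double vc = 1.0 - std::exp(-S2 / (2.0 * c * c));
  return va * vb * vc;
}

// [[Rcpp::export]]
NumericVector cpp_vesselness_from_eigs(NumericVector l1, NumericVector l2,
                                       NumericVector l3, double alpha,
                                       double beta, double c, bool bright) {
  size_t n = l1.size();
  NumericVector out(n);
  for (size_t v = 0; v < n; ++v)
    out[v] = frangi_v(l1[v], l2[v], l3[v], alpha, beta, c, bright);
  return out;
}

struct HessWork {
  std::vector<double> sm, tmp, g, hxx, hxy, hxz, hyy, hyz, hzz;
  HessWork(size_t n) : sm(n), tmp(n), g(n), hxx(n), hxy(n), hxz(n),
                       hyy(n), hyz(n), hzz(n) {}
};

static void hessian_pass(const double *vol, HessWork &w,
                         int nx, int ny, int nz, double sigma, double snorm) {
  size_t nvox = (size_t)nx * ny * nz;
  gaussian_smooth_3d(vol, w.sm.data(), w.tmp.data(), nx, ny, nz, sigma);
  diff_axis(w.sm.data(), w.g.data(), nx, ny, nz, 0);
  diff_axis(w.g.data(), w.hxx.data(), nx, ny, nz, 0);
  diff_axis(w.g.data(), w.hxy.data(), nx, ny, nz, 1);
  diff_axis(w.g.data(), w.hxz.data(), nx, ny, nz, 2);
  diff_axis(w.sm.data(), w.g.data(), nx, ny, nz, 1);
  diff_axis(w.g.data(), w.hyy.data(), nx, ny, nz, 1);
  diff_axis(w.g.data(), w.hyz.data(), nx, ny, nz, 2);
  diff_axis(w.sm.data(), w.g.data(), nx, ny, nz, 2);
  diff_axis(w.g.data(), w.hzz.data(), nx, ny, nz, 2);
  for (size_t v = 0; v < nvox; ++v) {
    w.hxx[v] *= snorm; w.hxy[v] *= snorm; w.hxz[v] *= snorm;
    w.hyy[v] *= snorm; w.hyz[v] *= snorm; w.hzz[v] *= snorm;
  }
}

// Streaming multi-scale Frangi vesselness. c_in <= 0 requests auto mode:
// c = half the maximum Hessian Frobenius norm over the volume across all
// scales of the run (computed in a first pass over scales).
// [[Rcpp::export]]
List cpp_multiscale_vesselness(NumericVector vol, IntegerVector dims,
                               NumericVector scales, double alpha, double beta,
                               double c_in, double gamma, bool bright) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  int ns = scales.size();
  HessWork w(nvox);
  NumericVector scale_norm(ns);
  double c = c_in;
  if (c_in <= 0.0) {
    double m = 0.0;
    for (int s = 0; s < ns; ++s) {
      double S = scales[s];
      double snorm = std::pow(S, gamma);
      hessian_pass(REAL(vol), w, nx, ny, nz, S, snorm);
      double ms = 0.0;
      for (size_t v = 0; v < nvox; ++v) {
        double f2 = w.hxx[v] * w.hxx[v] + w.hyy[v] * w.hyy[v]
                  + w.hzz[v] * w.hzz[v]
                  + 2.0 * (w.hxy[v] * w.hxy[v] + w.hxz[v] * w.hxz[v]
                           + w.hyz[v] * w.hyz[v]);
        if (f2 > ms) ms = f2;
      }
      scale_norm[s] = std::sqrt(ms);
      if (scale_norm[s] > m) m = scale_norm[s];
      Rcpp::checkUserInterrupt();
    }
    c = m / 2.0;
    if (c <= 0.0) c = 1.0;  // structureless volume; any c gives V = 0
  }
  NumericVector prob(nvox), smax(nvox);
  std::fill(REAL(smax), REAL(smax) + nvox, NA_REAL);
  for (int s = 0; s < ns; ++s) {
    double S = scales[s];
    double snorm = std::pow(S, gamma);
    hessian_pass(REAL(vol), w, nx, ny, nz, S, snorm);
    double *pp = REAL(prob), *ps = REAL(smax);
    for (size_t v = 0; v < nvox; ++v) {
      double l1, l2, l3;
      eig_sym3(w.hxx[v], w.hxy[v], w.hxz[v], w.hyy[v], w.hyz[v], w.hzz[v],
               l1, l2, l3);
      double V = frangi_v(l1, l2, l3, alpha, beta, c, bright);
      if (V > pp[v]) { pp[v] = V; ps[v] = S; }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["probability"] = prob, _["s_max"] = smax,
                      _["c"] = c, _["scale_max_norm"] = scale_norm);
}
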