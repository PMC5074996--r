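// Binary 3D morphology: seeded 26-connected flood fill and sequential
// 6-subiteration topological thinning to a unit-width centerline skeleton.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
LogicalVector cpp_flood_fill(NumericVector prob, IntegerVector dims,
                             IntegerMatrix seeds, double threshold) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  LogicalVector mask(nvox);
  std::vector<int> stack;
  int *pm = LOGICAL(mask);
  const double *pp = REAL(prob);
  for (int s = 0; s < seeds.nrow(); ++s) {
    size_t v = seeds(s, 0) + (size_t)nx * (seeds(s, 1) + (size_t)ny * seeds(s, 2));
    if (!pm[v] && pp[v] >= threshold) { pm[v] = 1; stack.push_back((int)v); }
  }
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          size_t w = ii + (size_t)nx * (jj + (size_t)ny * kk);
          if (!pm[w] && pp[w] >= threshold) { pm[w] = 1; stack.push_back((int)w); }
        }
  }
  return mask;
}

// --- topological thinning -------------------------------------------------
// A foreground voxel is "simple" (deletable without changing topology, with
// 26-connected foreground / 6-connected background) iff:
//  (a) the foreground voxels of its 26-neighbourhood form exactly one
//      26-connected component, and
//  (b) the background voxels of its 18-neighbourhood that are 6-adjacent to
//      it form exactly one 6-connected component within that neighbourhood.
// (Malandain-Bertrand local characterization.)

static int NB_OFF[27][3]; // filled once: all (dx,dy,dz) in {-1,0,1}^3

static void fill_offsets() {
  int n = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        NB_OFF[n][0] = dx; NB_OFF[n][1] = dy; NB_OFF[n][2] = dz; ++n;
      }
}

static inline int off_index(int dx, int dy, int dz) {
  return (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1));
}

// nb[27]: foreground occupancy of the 3x3x3 neighbourhood (center = 13)
static bool is_simple(const bool nb[27]) {
  // (a) one 26-component of foreground among the 26 neighbours
  bool seen[27] = {false};
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comps;
    if (comps > 1) return false;
    int stack[26], top = 0;
    stack[top++] = s; seen[s] = true;
    while (top) {
      int cur = stack[--top];
      int cx = NB_OFF[cur][0], cy = NB_OFF[cur][1], cz = NB_OFF[cur][2];
      for (int q = 0; q < 27; ++q) {
        if (q == 13 || seen[q] || !nb[q]) continue;
        int ax = NB_OFF[q][0] - cx, ay = NB_OFF[q][1] - cy, az = NB_OFF[q][2] - cz;
        if (ax >= -1 && ax <= 1 && ay >= -1 && ay <= 1 && az >= -1 && az <= 1)
          { seen[q] = true; stack[top++] = q; }
      }
    }
  }
  if (comps != 1) return false;
  // (b) one 6-component of background within the 18-neighbourhood that
  //     touches a face neighbour of the center
  bool bseen[27] = {false};
  int bcomps = 0;
  for (int s = 0; s < 27; ++s) {
    int dx = NB_OFF[s][0], dy = NB_OFF[s][1], dz = NB_OFF[s][2];
    int nn = std::abs(dx) + std::abs(dy) + std::abs(dz);
    if (nn != 1) continue;           // components are grown from face nbrs
    if (nb[s] || bseen[s]) continue; // background only
    ++bcomps;
    if (bcomps > 1) return false;
    int stack[18], top = 0;
    stack[top++] = s; bseen[s] = true;
    while (top) {
      int cur = stack[--top];
      int cx = NB_OFF[cur][0], cy = NB_OFF[cur][1], cz = NB_OFF[cur][2];
      for (int q = 0; q < 27; ++q) {
        if (bseen[q] || nb[q]) continue;
        int qx = NB_OFF[q][0], qy = NB_OFF[q][1], qz = NB_OFF[q][2];
        if (std::abs(qx) + std::abs(qy) + std::abs(qz) > 2) continue; // 18-nbhd
        int ax = qx - cx, ay = qy - cy, az = qz - cz;
        if (std::abs(ax) + std::abs(ay) + std::abs(az) == 1)
          { bseen[q] = true; stack[top++] = q; }
      }
    }
  }
  return bcomps == 1;
}

// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dims) {
  fill_offsets();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  LogicalVector skel = clone(mask);
  int *pm = LOGICAL(skel);
  // active set: foreground voxels with at least one 6-neighbour background
  std::vector<int> active;
  std::vector<char> inact(nvox, 0);
  const int fdx[6] = {1, -1, 0, 0, 0, 0};
  const int fdy[6] = {0, 0, 1, -1, 0, 0};
  const int fdz[6] = {0, 0, 0, 0, 1, -1};
  auto fg_at = [&](int i, int j, int k) -> bool {
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return false;
    return pm[i + (size_t)nx * (j + (size_t)ny * k)] != 0;
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t v = i + (size_t)nx * (j + (size_t)ny * k);
        if (!pm[v]) continue;
        for (int d = 0; d < 6; ++d)
          if (!fg_at(i + fdx[d], j + fdy[d], k + fdz[d])) {
            active.push_back((int)v); inact[v] = 1; break;
          }
      }
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      std::vector<int> deleted;
      for (size_t a = 0; a < active.size(); ++a) {
        int v = active[a];
        if (!pm[v]) continue;
        int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
        // border in this direction?
        if (fg_at(i + fdx[dir], j + fdy[dir], k + fdz[dir])) continue;
        // endpoint preservation
        bool nb[27];
        int cnt = 0;
        for (int q = 0; q < 27; ++q) {
          nb[q] = fg_at(i + NB_OFF[q][0], j + NB_OFF[q][1], k + NB_OFF[q][2]);
          if (q != 13 && nb[q]) ++cnt;
        }
        if (cnt <= 1) continue;
        if (!is_simple(nb)) continue;
        pm[v] = 0;          // sequential deletion preserves topology
        deleted.push_back(v);
        changed = true;
      }
      for (int v : deleted) {
        int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
        for (int q = 0; q < 27; ++q) {
          if (q == 13) continue;
          int ii = i + NB_OFF[q][0], jj = j + NB_OFF[q][1], kk = k + NB_OFF[q][2];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          size_t w = ii + (size_t)nx * (jj + (size_t)ny * kk);
          if (pm[w] && !inact[w]) { inact[w] = 1; active.push_back((int)w); }
        }
      }
    }
    // compact the active list
    std::vector<int> keep;
    keep.reserve(active.size());
    for (int v : active) if (pm[v]) keep.push_back(v); else inact[v] = 0;
    active.swap(keep);
    Rcpp::checkUserInterrupt();
  }
  return skel;
}
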