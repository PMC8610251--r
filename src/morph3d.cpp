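#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shared helpers for 3D (and 2D as nz = 1) morphology on column-major arrays
// with dim = (ny, nx, nz). Linear index: y + ny * (x + nx * z), 0-based here.

static inline int lin(int y, int x, int z, int ny, int nx) {
  return y + ny * (x + nx * z);
}

// Connected-component labelling, 26-connectivity in 3D (8 in 2D when nz == 1)
// or 6-connectivity (4 in 2D). Labels are dense from 1, assigned in raster
// scan order so the result is deterministic.
// [[Rcpp::export]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dims, int connectivity = 26) {
  int ny = dims[0], nx = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  int n = ny * nx * nz;
  IntegerVector labels(n, 0);
  bool full = (connectivity == 26 || connectivity == 8);
  std::vector<int> stack;
  int next_label = 0;
  for (int i = 0; i < n; i++) {
    if (!mask[i] || labels[i] != 0) continue;
    next_label++;
    labels[i] = next_label;
    stack.push_back(i);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int z = cur / (ny * nx);
      int rem = cur - z * ny * nx;
      int x = rem / ny;
      int y = rem - x * ny;
      for (int dz = -1; dz <= 1; dz++) {
        int zz = z + dz; if (zz < 0 || zz >= nz) continue;
        for (int dx = -1; dx <= 1; dx++) {
          int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          for (int dy = -1; dy <= 1; dy++) {
            int yy = y + dy; if (yy < 0 || yy >= ny) continue;
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (!full && (std::abs(dx) + std::abs(dy) + std::abs(dz)) != 1) continue;
            int j = lin(yy, xx, zz, ny, nx);
            if (mask[j] && labels[j] == 0) {
              labels[j] = next_label;
              stack.push_back(j);
            }
          }
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// One-dimensional squared-distance transform (lower envelope of parabolas)
// on a grid with physical spacing w.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, double w) {
  int n = (int) f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -1e30; z[1] = 1e30;
  for (int q = 1; q < n; q++) {
    double qa = q * w, va = v[k] * w;
    double s = ((f[q] + qa * qa) - (f[v[k]] + va * va)) / (2.0 * qa - 2.0 * va);
    while (s <= z[k]) {
      k--;
      va = v[k] * w;
      s = ((f[q] + qa * qa) - (f[v[k]] + va * va)) / (2.0 * qa - 2.0 * va);
    }
    k++;
    v[k] = q; z[k] = s; z[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double qa = q * w;
    while (z[k + 1] < qa) k++;
    double va = v[k] * w;
    d[q] = (qa - va) * (qa - va) + f[v[k]];
  }
}

// Anisotropic squared Euclidean distance transform: for each foreground voxel,
// squared distance (in physical units, voxel sizes vs = (wy, wx, wz)) to the
// nearest background voxel. Background voxels get 0. Image borders are not
// treated as background.
// [[Rcpp::export]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dims, NumericVector vs) {
  int ny = dims[0], nx = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  double wy = vs[0], wx = vs[1], wz = vs.size() > 2 ? vs[2] : 1.0;
  int n = ny * nx * nz;
  NumericVector d(n);
  for (int i = 0; i < n; i++) d[i] = mask[i] ? 1e30 : 0.0;

  std::vector<double> f, g;
  // along y
  f.resize(ny); g.resize(ny);
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      for (int y = 0; y < ny; y++) f[y] = d[lin(y, x, z, ny, nx)];
      dt1d(f, g, wy);
      for (int y = 0; y < ny; y++) d[lin(y, x, z, ny, nx)] = g[y];
    }
  // along x
  f.resize(nx); g.resize(nx);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      for (int x = 0; x < nx; x++) f[x] = d[lin(y, x, z, ny, nx)];
      dt1d(f, g, wx);
      for (int x = 0; x < nx; x++) d[lin(y, x, z, ny, nx)] = g[x];
    }
  // along z
  if (nz > 1) {
    f.resize(nz); g.resize(nz);
    for (int x = 0; x < nx; x++)
      for (int y = 0; y < ny; y++) {
        for (int z = 0; z < nz; z++) f[z] = d[lin(y, x, z, ny, nx)];
        dt1d(f, g, wz);
        for (int z = 0; z < nz; z++) d[lin(y, x, z, ny, nx)] = g[z];
      }
  }
  d.attr("dim") = dims;
  return d;
}

struct WsItem {
  double priority; // distance-transform value; larger floods first
  int label;
  int order;       // insertion sequence, for full determinism
  int idx;
};
struct WsCompare {
  bool operator()(const WsItem& a, const WsItem& b) const {
    if (a.priority != b.priority) return a.priority < b.priority; // max-heap on priority
    // FIFO within an equal-distance plateau: flooding advances breadth-first
    // from every front at once, so no label can annex a whole plateau.
    // Seeds enqueue in label order, making simultaneous claims resolve to
    // the lower label deterministically.
    return a.order > b.order;
  }
};

// Marker-based watershed flooding of `mask` guided by the distance transform
// `dist` (flooded from high to low). Equal-priority claims resolve to the
// lower seed label. Every mask voxel reachable from a seed receives a label,
// so voxels are conserved within seeded components.
// [[Rcpp::export]]
IntegerVector ws_flood(NumericVector dist, IntegerVector seeds, LogicalVector mask,
                       IntegerVector dims, int connectivity = 26) {
  int ny = dims[0], nx = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  int n = ny * nx * nz;
  bool full = (connectivity == 26 || connectivity == 8);
  IntegerVector out(n, 0);
  std::priority_queue<WsItem, std::vector<WsItem>, WsCompare> pq;
  int order = 0;
  for (int i = 0; i < n; i++) {
    if (seeds[i] > 0 && mask[i]) {
      pq.push(WsItem{dist[i], seeds[i], order++, i});
    }
  }
  while (!pq.empty()) {
    WsItem it = pq.top(); pq.pop();
    if (out[it.idx] != 0) continue;
    out[it.idx] = it.label;
    int z = it.idx / (ny * nx);
    int rem = it.idx - z * ny * nx;
    int x = rem / ny;
    int y = rem - x * ny;
    for (int dz = -1; dz <= 1; dz++) {
      int zz = z + dz; if (zz < 0 || zz >= nz) continue;
      for (int dx = -1; dx <= 1; dx++) {
        int xx = x + dx; if (xx < 0 || xx >= nx) continue;
        for (int dy = -1; dy <= 1; dy++) {
          int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          if (dx == 0 && dy == 0 && dz == 0) continue;
          if (!full && (std::abs(dx) + std::abs(dy) + std::abs(dz)) != 1) continue;
          int j = lin(yy, xx, zz, ny, nx);
          if (mask[j] && out[j] == 0) {
            pq.push(WsItem{dist[j], it.label, order++, j});
          }
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
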