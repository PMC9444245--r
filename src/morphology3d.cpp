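// 3D binary morphology used by the axon quantification stage:
//  - 26-connected component labeling (small-object removal)
//  - topology-preserving curve thinning (centerline extraction)
//
// Arrays are passed as R logical/integer vectors with dim = c(nz, ny, nx);
// linear index = z + nz*y + nz*ny*x (0-based), matching R's column-major
// layout for [z, y, x] arrays.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Grid {
  int nz, ny, nx;
  long idx(int z, int y, int x) const {
    return (long)z + (long)nz * ((long)y + (long)ny * (long)x);
  }
  bool inside(int z, int y, int x) const {
    return z >= 0 && z < nz && y >= 0 && y < ny && x >= 0 && x < nx;
  }
};

// ---- simple-point test (26-connectivity for foreground, 6 for background) --
//
// A foreground voxel is "simple" (deletable without changing topology) iff
//   (a) its 26-neighborhood foreground forms exactly one 26-connected
//       component, and
//   (b) the background within its 18-neighborhood forms exactly one
//       6-connected component that touches a face neighbor.
// Neighborhood is packed into nb[27], local coords (dz,dy,dx) in {-1,0,1},
// index 9*(dx+1) + 3*(dy+1) + (dz+1). Center (index 13) excluded from tests.

inline int nb_index(int dz, int dy, int dx) {
  return 9 * (dx + 1) + 3 * (dy + 1) + (dz + 1);
}

int count_fg_components_26(const uint8_t nb[27]) {
  bool seen[27] = {false};
  int ncomp = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++ncomp;
    std::queue<int> q;
    q.push(i);
    seen[i] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx = c / 9 - 1, cy = (c / 3) % 3 - 1, cz = c % 3 - 1;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (!dx && !dy && !dz) continue;
            int x = cx + dx, y = cy + dy, z = cz + dz;
            if (x < -1 || x > 1 || y < -1 || y > 1 || z < -1 || z > 1) continue;
            int j = nb_index(z, y, x);
            if (j == 13 || seen[j] || !nb[j]) continue;
            seen[j] = true;
            q.push(j);
          }
    }
  }
  return ncomp;
}

int count_bg_components_6(const uint8_t nb[27]) {
  // only the 18-neighborhood (face + edge neighbors) participates
  bool seen[27] = {false};
  int ncomp = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || nb[i] || seen[i]) continue;
    int ix = i / 9 - 1, iy = (i / 3) % 3 - 1, iz = i % 3 - 1;
    int manh = std::abs(ix) + std::abs(iy) + std::abs(iz);
    if (manh != 1) continue;  // seed components only from face neighbors
    ++ncomp;
    std::queue<int> q;
    q.push(i);
    seen[i] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx = c / 9 - 1, cy = (c / 3) % 3 - 1, cz = c % 3 - 1;
      const int face[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int f = 0; f < 6; ++f) {
        int x = cx + face[f][0], y = cy + face[f][1], z = cz + face[f][2];
        if (x < -1 || x > 1 || y < -1 || y > 1 || z < -1 || z > 1) continue;
        int m = std::abs(x) + std::abs(y) + std::abs(z);
        if (m > 2) continue;  // stay within the 18-neighborhood
        int j = nb_index(z, y, x);
        if (j == 13 || seen[j] || nb[j]) continue;
        seen[j] = true;
        q.push(j);
      }
    }
  }
  return ncomp;
}

void fill_neighborhood(const std::vector<uint8_t>& img, const Grid& g,
                       int z, int y, int x, uint8_t nb[27]) {
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz, yy = y + dy, xx = x + dx;
        uint8_t v = 0;
        if (g.inside(zz, yy, xx)) v = img[g.idx(zz, yy, xx)];
        nb[nb_index(dz, dy, dx)] = v;
      }
}

inline int n26_count(const uint8_t nb[27]) {
  int n = 0;
  for (int i = 0; i < 27; ++i)
    if (i != 13 && nb[i]) ++n;
  return n;
}

inline bool is_simple(const uint8_t nb[27]) {
  return count_fg_components_26(nb) == 1 && count_bg_components_6(nb) == 1;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_label_components_26")]]
IntegerVector cpp_label_components_26(LogicalVector mask, IntegerVector dims) {
  Grid g{dims[0], dims[1], dims[2]};
  long n = (long)g.nz * g.ny * g.nx;
  IntegerVector labels(n, 0);
  int next = 0;
  std::queue<long> q;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || labels[s]) continue;
    ++next;
    labels[s] = next;
    q.push(s);
    while (!q.empty()) {
      long c = q.front(); q.pop();
      int z = (int)(c % g.nz);
      int y = (int)((c / g.nz) % g.ny);
      int x = (int)(c / ((long)g.nz * g.ny));
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (!dx && !dy && !dz) continue;
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (!g.inside(zz, yy, xx)) continue;
            long j = g.idx(zz, yy, xx);
            if (mask[j] && !labels[j]) {
              labels[j] = next;
              q.push(j);
            }
          }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_thin_3d")]]
LogicalVector cpp_thin_3d(LogicalVector mask, IntegerVector dims) {
  Grid g{dims[0], dims[1], dims[2]};
  long n = (long)g.nz * g.ny * g.nx;
  std::vector<uint8_t> img(n);
  for (long i = 0; i < n; ++i) img[i] = mask[i] ? 1 : 0;

  // directional border checks: U, D, N, S, E, W in (dz, dy, dx)
  const int dirs[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  uint8_t nb[27];
  std::vector<long> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int x = 0; x < g.nx; ++x)
        for (int y = 0; y < g.ny; ++y)
          for (int z = 0; z < g.nz; ++z) {
            long i = g.idx(z, y, x);
            if (!img[i]) continue;
            int zz = z + dirs[d][0], yy = y + dirs[d][1], xx = x + dirs[d][2];
            // border in direction d (stack faces do not count as background,
            // so structures touching the boundary are not eaten from outside)
            if (!g.inside(zz, yy, xx) || img[g.idx(zz, yy, xx)]) continue;
            fill_neighborhood(img, g, z, y, x, nb);
            if (n26_count(nb) < 2) continue;  // keep endpoints/isolated voxels
            if (is_simple(nb)) cand.push_back(i);
          }
      // sequential re-check: deleting one candidate can make a neighbor
      // non-simple, so each deletion is re-validated on the current image
      for (long i : cand) {
        int z = (int)(i % g.nz);
        int y = (int)((i / g.nz) % g.ny);
        int x = (int)(i / ((long)g.nz * g.ny));
        fill_neighborhood(img, g, z, y, x, nb);
        if (n26_count(nb) >= 2 && is_simple(nb)) {
          img[i] = 0;
          changed = true;
        }
      }
    }
  }

  LogicalVector out(n);
  for (long i = 0; i < n; ++i) out[i] = img[i] != 0;
  out.attr("dim") = dims;
  return out;
}
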