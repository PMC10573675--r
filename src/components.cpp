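#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Neighbor offsets for 6/18/26 connectivity on a 3D grid.
// 6  = faces; 18 = faces + edges; 26 = faces + edges + corners.
static void neighbor_offsets(int connectivity,
                             std::vector<int>& dx,
                             std::vector<int>& dy,
                             std::vector<int>& dz) {
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        int nz_abs = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (nz_abs == 0) continue;
        bool keep = (connectivity == 26) ||
                    (connectivity == 18 && nz_abs <= 2) ||
                    (connectivity == 6  && nz_abs == 1);
        if (keep) { dx.push_back(cx); dy.push_back(cy); dz.push_back(cz); }
      }
}

// BFS labeling of a binary 3D mask (column-major, dims nx,ny,nz).
// Returns integer labels (0 = background) and per-component voxel counts.
// [[Rcpp::export(name = ".cc_label3d")]]
List cc_label3d(IntegerVector mask, IntegerVector dims, int connectivity) {
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");

  std::vector<int> dx, dy, dz;
  neighbor_offsets(connectivity, dx, dy, dz);
  const int nnb = (int)dx.size();

  IntegerVector labels(n, 0);
  std::vector<int> sizes;
  std::vector<R_xlen_t> queue;
  queue.reserve(1024);
  int next_label = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (mask[start] == 0 || labels[start] != 0) continue;
    ++next_label;
    int count = 0;
    queue.clear();
    queue.push_back(start);
    labels[start] = next_label;
    while (!queue.empty()) {
      R_xlen_t idx = queue.back();
      queue.pop_back();
      ++count;
      int x = (int)(idx % nx);
      int y = (int)((idx / nx) % ny);
      int z = (int)(idx / ((R_xlen_t)nx * ny));
      for (int k = 0; k < nnb; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t nidx = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[nidx] != 0 && labels[nidx] == 0) {
          labels[nidx] = next_label;
          queue.push_back(nidx);
        }
      }
    }
    sizes.push_back(count);
  }

  return List::create(_["labels"] = labels,
                      _["n_components"] = next_label,
                      _["sizes"] = wrap(sizes));
}

// 0-based linear indices of voxels of `label` that touch (6-connectivity)
// a voxel with a different label or the grid border. For a component this
// boundary set contains all convex-hull vertices, so the exact maximum
// pairwise distance is preserved.
// [[Rcpp::export(name = ".cc_boundary")]]
IntegerVector cc_boundary(IntegerVector labels, IntegerVector dims, int label) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> out;
  static const int fx[6] = {-1, 1, 0, 0, 0, 0};
  static const int fy[6] = {0, 0, -1, 1, 0, 0};
  static const int fz[6] = {0, 0, 0, 0, -1, 1};
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (labels[idx] != label) continue;
    int x = (int)(idx % nx);
    int y = (int)((idx / nx) % ny);
    int z = (int)(idx / ((R_xlen_t)nx * ny));
    bool boundary = false;
    for (int k = 0; k < 6 && !boundary; ++k) {
      int xx = x + fx[k], yy = y + fy[k], zz = z + fz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) {
        boundary = true;
      } else {
        R_xlen_t nidx = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (labels[nidx] != label) boundary = true;
      }
    }
    if (boundary) out.push_back((int)idx);
  }
  return wrap(out);
}

// Exact maximum pairwise Euclidean distance between rows of an n x 3
// coordinate matrix (physical mm).
// [[Rcpp::export(name = ".max_pairwise_dist")]]
double max_pairwise_dist(NumericMatrix coords) {
  const int n = coords.nrow();
  double best = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    for (int j = i + 1; j < n; ++j) {
      double dx = xi - coords(j, 0);
      double dy = yi - coords(j, 1);
      double dz = zi - coords(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  }
  return std::sqrt(best);
}
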