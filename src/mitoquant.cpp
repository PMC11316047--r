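#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary array laid out as [y, x, z]
// (column-major, dims = ny, nx, nz; nz = 1 for 2D). Connectivity: 26 in 3D,
// 8 in 2D (full neighbourhood), or 6/4 when full_connectivity = false.
// Labels are consecutive positive integers in first-voxel scan order.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   bool full_connectivity = true) {
  const int ny = dims[0], nx = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  IntegerVector labels(n, 0);

  std::vector<int> off_y, off_x, off_z;
  for (int dz = -1; dz <= 1; ++dz) {
    if (nz == 1 && dz != 0) continue;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        if (dy == 0 && dx == 0 && dz == 0) continue;
        if (!full_connectivity && (std::abs(dy) + std::abs(dx) + std::abs(dz)) != 1)
          continue;
        off_y.push_back(dy); off_x.push_back(dx); off_z.push_back(dz);
      }
    }
  }
  const int n_off = (int)off_y.size();

  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next_label;
    labels[i] = next_label;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int z = (int)(cur / ((R_xlen_t)ny * nx));
      int rem = (int)(cur % ((R_xlen_t)ny * nx));
      int x = rem / ny;
      int y = rem % ny;
      for (int k = 0; k < n_off; ++k) {
        int yy = y + off_y[k], xx = x + off_x[k], zz = z + off_z[k];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        R_xlen_t j = (R_xlen_t)zz * ny * nx + (R_xlen_t)xx * ny + yy;
        if (mask[j] && labels[j] == 0) {
          labels[j] = next_label;
          stack.push_back(j);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// Zhang-Suen thinning of a 2D binary mask [y, x] to a one-pixel-wide
// skeleton (the 2D counterpart of medial-axis thinning used for
// mitochondrial skeletons).
// [[Rcpp::export(name = ".thin_mask_cpp")]]
LogicalMatrix thin_mask_cpp(LogicalMatrix mask) {
  const int ny = mask.nrow(), nx = mask.ncol();
  LogicalMatrix img(clone(mask));

  auto at = [&](int y, int x) -> int {
    if (y < 0 || y >= ny || x < 0 || x >= nx) return 0;
    return img(y, x) ? 1 : 0;
  };

  bool changed = true;
  std::vector<std::pair<int,int>> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int x = 0; x < nx; ++x) {
        for (int y = 0; y < ny; ++y) {
          if (!img(y, x)) continue;
          // neighbours P2..P9 clockwise from north
          int p2 = at(y - 1, x),     p3 = at(y - 1, x + 1);
          int p4 = at(y, x + 1),     p5 = at(y + 1, x + 1);
          int p6 = at(y + 1, x),     p7 = at(y + 1, x - 1);
          int p8 = at(y, x - 1),     p9 = at(y - 1, x - 1);
          int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (b < 2 || b > 6) continue;
          int p[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          int a = 0;
          for (int k = 0; k < 8; ++k) if (p[k] == 0 && p[k + 1] == 1) ++a;
          if (a != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0) continue;
            if (p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0) continue;
            if (p2 * p6 * p8 != 0) continue;
          }
          kill.push_back({y, x});
        }
      }
      if (!kill.empty()) changed = true;
      for (auto &px : kill) img(px.first, px.second) = false;
    }
  }
  return img;
}
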