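#include <Rcpp.h>
using namespace Rcpp;

// Sequential (in-place) box-mode filtering of a 3D label field.
// labels: full-grid labels (column-major), 0 = unassigned.
// orders: 0-based linear indices of masked voxels, one column per sweep,
//         giving the seeded visit order. Label 0 never enters the mode
//         count; modal ties keep the smallest label.
// [[Rcpp::export]]
IntegerVector mode_filter_cpp(IntegerVector labels, IntegerVector shape,
                              LogicalVector mask, int box,
                              IntegerMatrix orders) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  const int r = box / 2;
  IntegerVector lab = clone(labels);
  int maxlab = 0;
  for (int i = 0; i < lab.size(); ++i)
    if (lab[i] > maxlab) maxlab = lab[i];
  std::vector<int> counts(maxlab + 1, 0);

  for (int s = 0; s < orders.ncol(); ++s) {
    for (int t = 0; t < orders.nrow(); ++t) {
      const int v = orders(t, s);
      const int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      std::fill(counts.begin(), counts.end(), 0);
      int best = 0, bestc = 0;
      for (int dz = -r; dz <= r; ++dz) {
        const int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -r; dy <= r; ++dy) {
          const int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          const int base = nx * (yy + ny * zz);
          for (int dx = -r; dx <= r; ++dx) {
            const int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            const int w = xx + base;
            if (!mask[w]) continue;
            const int l = lab[w];
            if (l > 0) ++counts[l];
          }
        }
      }
      for (int l = 1; l <= maxlab; ++l) {
        if (counts[l] > bestc) { bestc = counts[l]; best = l; }
      }
      if (best > 0) lab[v] = best;
    }
  }
  return lab;
}
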