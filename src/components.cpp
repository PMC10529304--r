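#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Breadth-first connected-component labelling on a 3-D logical lattice.
//
// `mask` is a logical array in R's column-major order with dimensions `dims`
// (nx, ny, nz). `offsets` is an n x 3 integer matrix of neighbour offsets
// (dx, dy, dz) defining the connectivity; it must not contain (0,0,0).
//
// Components are labelled 1..C in order of first encounter during a linear
// (column-major) scan, so label order is determined by each component's
// minimal linear index. This makes the labelling deterministic and
// independent of the traversal order inside a component.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");

  const int noff = offsets.nrow();
  std::vector<int> dx(noff), dy(noff), dz(noff);
  for (int m = 0; m < noff; ++m) {
    dx[m] = offsets(m, 0);
    dy[m] = offsets(m, 1);
    dz[m] = offsets(m, 2);
    if (dx[m] == 0 && dy[m] == 0 && dz[m] == 0)
      stop("offsets must not contain the zero offset");
  }

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> queue;
  const R_xlen_t plane = static_cast<R_xlen_t>(nx) * ny;
  int current = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++current;
    labels[start] = current;
    queue.clear();
    queue.push_back(start);
    while (!queue.empty()) {
      R_xlen_t idx = queue.back();
      queue.pop_back();
      const int k = static_cast<int>(idx / plane);
      const R_xlen_t rem = idx % plane;
      const int j = static_cast<int>(rem / nx);
      const int i = static_cast<int>(rem % nx);
      for (int m = 0; m < noff; ++m) {
        const int ii = i + dx[m];
        const int jj = j + dy[m];
        const int kk = k + dz[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        const R_xlen_t nb = static_cast<R_xlen_t>(kk) * plane +
                            static_cast<R_xlen_t>(jj) * nx + ii;
        if (mask[nb] && labels[nb] == 0) {
          labels[nb] = current;
          queue.push_back(nb);
        }
      }
    }
  }

  labels.attr("dim") = dims;
  return labels;
}
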