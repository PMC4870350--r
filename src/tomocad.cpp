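// Voxel-level kernels: separable correlation with mirror boundary,
// 3D connected-component labeling (union-find), and batched symmetric
// 3x3 eigendecomposition for Hessian fields.
#include <RcppArmadillo.h>
#include <functional>
#include <unordered_map>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Mirror (symmetric) fold of index i into [0, n): ...cba|abcd|dcb...
static inline int fold_index(int i, int n) {
  if (n == 1) return 0;
  const int p = 2 * n;
  i %= p;
  if (i < 0) i += p;
  if (i >= n) i = p - 1 - i;
  return i;
}

// Correlation (no kernel flip) along one axis of a 3D array stored in
// R column-major order (x fastest).  kernel has odd length; boundary is
// mirror-reflected.  axis: 1 = x, 2 = y, 3 = z.
// [[Rcpp::export]]
NumericVector cpp_conv1d(NumericVector arr, IntegerVector dims, int axis,
                         NumericVector kernel) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int klen = kernel.size();
  if (klen % 2 == 0) stop("kernel length must be odd");
  const int r = (klen - 1) / 2;
  NumericVector out(arr.size());

  const int n_axis = (axis == 1) ? nx : (axis == 2) ? ny : nz;
  // stride along the axis and sizes of the two orthogonal loops
  const R_xlen_t sx = 1, sy = (R_xlen_t)nx, sz = (R_xlen_t)nx * ny;
  R_xlen_t stride;
  if (axis == 1) stride = sx;
  else if (axis == 2) stride = sy;
  else stride = sz;

  std::vector<double> line(n_axis);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        if ((axis == 1 && i > 0) || (axis == 2 && j > 0) || (axis == 3 && k > 0))
          continue; // only start-of-line positions
        const R_xlen_t base = i * sx + j * sy + k * sz;
        for (int t = 0; t < n_axis; ++t) line[t] = arr[base + t * stride];
        for (int t = 0; t < n_axis; ++t) {
          double acc = 0.0;
          for (int q = -r; q <= r; ++q)
            acc += kernel[q + r] * line[fold_index(t + q, n_axis)];
          out[base + t * stride] = acc;
        }
      }
    }
  }
  return out;
}

// 3D connected-component labeling.  mask: 0/1 integers in column-major
// order; connectivity in {6, 18, 26}.  Labels are positive integers
// assigned in ascending order of each component's first (minimum)
// linear index; background stays 0.
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dims,
                          int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbor offsets strictly preceding in raster order
  std::vector<int> odx, ody, odz;
  for (int dz = -1; dz <= 0; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && (dy > 0 || (dy == 0 && dx >= 0))) continue;
        const int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        odx.push_back(dx); ody.push_back(dy); odz.push_back(dz);
      }
  const int noff = (int)odx.size();

  std::vector<R_xlen_t> parent(n);
  for (R_xlen_t i = 0; i < n; ++i) parent[i] = i;
  std::function<R_xlen_t(R_xlen_t)> find = [&](R_xlen_t i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  };

  R_xlen_t idx = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++idx) {
        if (!mask[idx]) continue;
        for (int o = 0; o < noff; ++o) {
          const int xx = x + odx[o], yy = y + ody[o], zz = z + odz[o];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny) continue;
          const R_xlen_t j = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
          if (!mask[j]) continue;
          R_xlen_t ra = find(idx), rb = find(j);
          if (ra != rb) {
            if (ra < rb) parent[rb] = ra; else parent[ra] = rb;
          }
        }
      }

  IntegerVector labels(n, 0);
  std::unordered_map<R_xlen_t, int> lab;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    R_xlen_t root = find(i);
    auto it = lab.find(root);
    if (it == lab.end()) { lab[root] = ++next; labels[i] = next; }
    else labels[i] = it->second;
  }
  return labels;
}

// Number of connected components only (cheap path for threshold search).
// [[Rcpp::export]]
int cpp_count_components(IntegerVector mask, IntegerVector dims,
                         int connectivity) {
  IntegerVector lab = cpp_label3d(mask, dims, connectivity);
  int mx = 0;
  for (R_xlen_t i = 0; i < lab.size(); ++i) if (lab[i] > mx) mx = lab[i];
  return mx;
}

// Batched eigenvalues of symmetric 3x3 matrices, returned ascending.
// Inputs are the six unique entries per voxel.
// [[Rcpp::export]]
NumericMatrix cpp_sym3eig(NumericVector a11, NumericVector a22,
                          NumericVector a33, NumericVector a12,
                          NumericVector a13, NumericVector a23) {
  const R_xlen_t n = a11.size();
  NumericMatrix out(n, 3);
  arma::mat33 H;
  arma::vec3 ev;
  for (R_xlen_t i = 0; i < n; ++i) {
    H(0, 0) = a11[i]; H(1, 1) = a22[i]; H(2, 2) = a33[i];
    H(0, 1) = H(1, 0) = a12[i];
    H(0, 2) = H(2, 0) = a13[i];
    H(1, 2) = H(2, 1) = a23[i];
    arma::eig_sym(ev, H); // ascending
    out(i, 0) = ev(0); out(i, 1) = ev(1); out(i, 2) = ev(2);
  }
  return out;
}
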