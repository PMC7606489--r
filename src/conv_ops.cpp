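// Core array primitives for the 3D dilated-convolution engine.
//
// Layout conventions (fixed across the whole package):
//  - activations are C x V matrices, V = X*Y*Z voxels in R column-major
//    order (x fastest);
//  - kernel taps are the 27 offsets delta in {-d,0,+d}^3, enumerated in
//    R column-major order over a (3,3,3) array (dx fastest);
//  - the im2col row index for (tap o, channel c) is (o-1)*C + c, matching
//    the flattened weight matrices W of dim C_out x (C_in*27).
// Out-of-volume taps are zero (zero padding equal to the dilation), which
// preserves spatial dimensions at every layer.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gather the dilated 3x3x3 neighborhood of every voxel.
// x: C x V activation matrix; returns (C*27) x V.
// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::mat& x, int X, int Y, int Z, int d) {
  const int C = x.n_rows;
  const int V = X * Y * Z;
  if ((int)x.n_cols != V)
    stop("activation matrix has %d columns, expected %d voxels", (int)x.n_cols, V);
  arma::mat out(C * 27, V, arma::fill::zeros);
  int o = 0;
  for (int kz = -1; kz <= 1; ++kz) {
    for (int ky = -1; ky <= 1; ++ky) {
      for (int kx = -1; kx <= 1; ++kx, ++o) {
        const int dx = kx * d, dy = ky * d, dz = kz * d;
        const int r0 = o * C;
        for (int z = 0; z < Z; ++z) {
          const int sz = z + dz;
          if (sz < 0 || sz >= Z) continue;
          for (int y = 0; y < Y; ++y) {
            const int sy = y + dy;
            if (sy < 0 || sy >= Y) continue;
            const int x0 = std::max(0, -dx);
            const int x1 = std::min(X, X - dx);
            if (x0 >= x1) continue;
            const int tcol = z * X * Y + y * X;
            const int scol = sz * X * Y + sy * X + dx;
            // contiguous run along the fastest axis
            out.submat(r0, tcol + x0, r0 + C - 1, tcol + x1 - 1) =
              x.cols(scol + x0, scol + x1 - 1);
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add neighborhood gradients back onto the
// voxel grid. cols: (C*27) x V; returns C x V.
// [[Rcpp::export]]
arma::mat cpp_col2im(const arma::mat& cols, int X, int Y, int Z, int d) {
  const int V = X * Y * Z;
  if ((int)cols.n_cols != V) stop("column matrix / grid mismatch");
  if (cols.n_rows % 27 != 0) stop("row count not divisible by 27");
  const int C = cols.n_rows / 27;
  arma::mat out(C, V, arma::fill::zeros);
  int o = 0;
  for (int kz = -1; kz <= 1; ++kz) {
    for (int ky = -1; ky <= 1; ++ky) {
      for (int kx = -1; kx <= 1; ++kx, ++o) {
        const int dx = kx * d, dy = ky * d, dz = kz * d;
        const int r0 = o * C;
        for (int z = 0; z < Z; ++z) {
          const int sz = z + dz;
          if (sz < 0 || sz >= Z) continue;
          for (int y = 0; y < Y; ++y) {
            const int sy = y + dy;
            if (sy < 0 || sy >= Y) continue;
            const int x0 = std::max(0, -dx);
            const int x1 = std::min(X, X - dx);
            if (x0 >= x1) continue;
            const int tcol = z * X * Y + y * X;
            const int scol = sz * X * Y + sy * X + dx;
            out.cols(scol + x0, scol + x1 - 1) +=
              cols.submat(r0, tcol + x0, r0 + C - 1, tcol + x1 - 1);
          }
        }
      }
    }
  }
  return out;
}

// Exact k-nearest-neighbour class-frequency estimate (squared Euclidean
// distance, ties broken by lower training index via stable partial sort).
// query, train: rows are points; labels: 0/1 per training row.
// Returns the positive-class frequency among the k neighbours of each query.
// [[Rcpp::export]]
NumericVector cpp_knn_freq(const arma::mat& query, const arma::mat& train,
                           const IntegerVector& labels, int k) {
  const int nq = query.n_rows, nt = train.n_rows;
  if (k <= 0) stop("k must be positive");
  if (k > nt) stop("k exceeds the number of training points");
  if (labels.size() != nt) stop("labels / training rows mismatch");
  NumericVector res(nq);
  std::vector<int> idx(nt);
  const int nd = query.n_cols;
  for (int q = 0; q < nq; ++q) {
    arma::vec d2(nt);
    for (int t = 0; t < nt; ++t) {
      // Accumulate squared differences sequentially in extended precision,
      // matching base R's column sums, so that distances that are equal
      // under the natural R computation are equal here too and the
      // documented lower-index tie rule applies deterministically.
      long double acc = 0.0L;
      for (int j = 0; j < nd; ++j) {
        const double dif = query(q, j) - train(t, j);
        acc += dif * dif;
      }
      d2[t] = static_cast<double>(acc);
    }
    for (int t = 0; t < nt; ++t) idx[t] = t;
    std::stable_sort(idx.begin(), idx.end(),
                     [&](int a, int b) { return d2[a] < d2[b]; });
    double pos = 0;
    for (int j = 0; j < k; ++j) pos += labels[idx[j]];
    res[q] = pos / k;
  }
  return res;
}
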