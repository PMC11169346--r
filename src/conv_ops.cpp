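// 3D convolution / pooling kernels for the volumetric CNN.
// Layout conventions used throughout:
//   * a batch of activations is an arma::cube of size C x nvox x n
//   * voxel linear index is Fortran order: i + d1*(j + d2*k)
//   * convolution kernels are 3x3x3 with zero padding 1 ("same"),
//     weights are Cout x (Cin*27), patch row = ci*27 + kidx with
//     kidx = (di+1) + 3*((dj+1) + 3*(dk+1)), offsets di,dj,dk in {-1,0,1}
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void im2col3d(const arma::mat& x, int d1, int d2, int d3,
                            arma::mat& P) {
  const int nvox = d1 * d2 * d3;
  const int Cin = x.n_rows;
  P.zeros(Cin * 27, nvox);
  for (int k = 0; k < d3; ++k) {
    for (int j = 0; j < d2; ++j) {
      for (int i = 0; i < d1; ++i) {
        const int col = i + d1 * (j + d2 * k);
        for (int dk = -1; dk <= 1; ++dk) {
          const int kk = k + dk;
          if (kk < 0 || kk >= d3) continue;
          for (int dj = -1; dj <= 1; ++dj) {
            const int jj = j + dj;
            if (jj < 0 || jj >= d2) continue;
            for (int di = -1; di <= 1; ++di) {
              const int ii = i + di;
              if (ii < 0 || ii >= d1) continue;
              const int src = ii + d1 * (jj + d2 * kk);
              const int kidx = (di + 1) + 3 * ((dj + 1) + 3 * (dk + 1));
              for (int c = 0; c < Cin; ++c)
                P(c * 27 + kidx, col) = x(c, src);
            }
          }
        }
      }
    }
  }
}

static inline void col2im3d(const arma::mat& dP, int d1, int d2, int d3,
                            arma::mat& dx) {
  const int Cin = dx.n_rows;
  dx.zeros();
  for (int k = 0; k < d3; ++k) {
    for (int j = 0; j < d2; ++j) {
      for (int i = 0; i < d1; ++i) {
        const int col = i + d1 * (j + d2 * k);
        for (int dk = -1; dk <= 1; ++dk) {
          const int kk = k + dk;
          if (kk < 0 || kk >= d3) continue;
          for (int dj = -1; dj <= 1; ++dj) {
            const int jj = j + dj;
            if (jj < 0 || jj >= d2) continue;
            for (int di = -1; di <= 1; ++di) {
              const int ii = i + di;
              if (ii < 0 || ii >= d1) continue;
              const int src = ii + d1 * (jj + d2 * kk);
              const int kidx = (di + 1) + 3 * ((dj + 1) + 3 * (dk + 1));
              for (int c = 0; c < Cin; ++c)
                dx(c, src) += dP(c * 27 + kidx, col);
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv3d_forward_cpp(const arma::cube& X, IntegerVector dims,
                              const arma::mat& W, const arma::vec& b) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int nvox = d1 * d2 * d3;
  const int n = X.n_slices;
  const int Cout = W.n_rows;
  arma::cube Y(Cout, nvox, n);
  arma::mat P;
  for (int s = 0; s < n; ++s) {
    im2col3d(X.slice(s), d1, d2, d3, P);
    Y.slice(s) = W * P;
    Y.slice(s).each_col() += b;
  }
  return Y;
}

// [[Rcpp::export]]
List conv3d_backward_cpp(const arma::cube& X, const arma::cube& dY,
                         IntegerVector dims, const arma::mat& W) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int n = X.n_slices;
  const int Cin = X.n_rows;
  arma::cube dX(arma::size(X));
  arma::mat dW(arma::size(W), arma::fill::zeros);
  arma::vec db(W.n_rows, arma::fill::zeros);
  arma::mat P, dP, dx(Cin, X.n_cols);
  for (int s = 0; s < n; ++s) {
    im2col3d(X.slice(s), d1, d2, d3, P);
    dW += dY.slice(s) * P.t();
    db += arma::sum(dY.slice(s), 1);
    dP = W.t() * dY.slice(s);
    col2im3d(dP, d1, d2, d3, dx);
    dX.slice(s) = dx;
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// Max pooling, window 2, stride 2, ceil mode (partial edge blocks use the
// voxels available). Returns pooled activations and the 1-based linear input
// index of each block maximum (first maximum wins on ties).
// [[Rcpp::export]]
List maxpool3d_forward_cpp(const arma::cube& X, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int o1 = (d1 + 1) / 2, o2 = (d2 + 1) / 2, o3 = (d3 + 1) / 2;
  const int nvox_out = o1 * o2 * o3;
  const int n = X.n_slices;
  const int C = X.n_rows;
  arma::cube Y(C, nvox_out, n);
  arma::cube amax(C, nvox_out, n);
  for (int s = 0; s < n; ++s) {
    const arma::mat& x = X.slice(s);
    for (int k = 0; k < o3; ++k) {
      for (int j = 0; j < o2; ++j) {
        for (int i = 0; i < o1; ++i) {
          const int col = i + o1 * (j + o2 * k);
          for (int c = 0; c < C; ++c) {
            double best = -arma::datum::inf;
            int best_ix = 0;
            for (int dk = 0; dk < 2; ++dk) {
              const int kk = 2 * k + dk;
              if (kk >= d3) continue;
              for (int dj = 0; dj < 2; ++dj) {
                const int jj = 2 * j + dj;
                if (jj >= d2) continue;
                for (int di = 0; di < 2; ++di) {
                  const int ii = 2 * i + di;
                  if (ii >= d1) continue;
                  const int src = ii + d1 * (jj + d2 * kk);
                  const double v = x(c, src);
                  if (v > best) { best = v; best_ix = src; }
                }
              }
            }
            Y(c, col, s) = best;
            amax(c, col, s) = best_ix + 1;
          }
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["argmax"] = amax,
                      _["out_dims"] = IntegerVector::create(o1, o2, o3));
}

// [[Rcpp::export]]
arma::cube maxpool3d_backward_cpp(const arma::cube& dY, const arma::cube& amax,
                                  int nvox_in) {
  const int C = dY.n_rows;
  const int nvox_out = dY.n_cols;
  const int n = dY.n_slices;
  arma::cube dX(C, nvox_in, n, arma::fill::zeros);
  for (int s = 0; s < n; ++s)
    for (int v = 0; v < nvox_out; ++v)
      for (int c = 0; c < C; ++c)
        dX(c, (int) amax(c, v, s) - 1, s) += dY(c, v, s);
  return dX;
}
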