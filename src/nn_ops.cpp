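// 3D convolution / pooling / upsampling kernels for the cascaded dose nets.
//
// Feature maps are stored as C x N matrices: one row per channel, one column
// per voxel, voxels linearised in array order over (i, j, k) with i fastest
// (matching how R linearises a d1 x d2 x d3 array). Convolutions are 3x3x3,
// stride 1, zero padding 1, computed as chunked im2col + GEMM so the large
// column matrix never holds more than `CHUNK` voxels at a time.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const int CHUNK = 8192;

// Fill `col` (27*Cin x nchunk) with the neighbourhood of voxels [v0, v0+nchunk).
// Row layout: offset-major, i.e. rows [o*Cin, (o+1)*Cin) hold channel values at
// offset o, with o = (oi+1) + 3*(oj+1) + 9*(ok+1).
static void im2col_chunk(const mat& X, int d1, int d2, int d3,
                         int v0, int nchunk, mat& col) {
  int Cin = X.n_rows;
  col.zeros();
  for (int t = 0; t < nchunk; ++t) {
    int v = v0 + t;
    int i = v % d1, j = (v / d1) % d2, k = v / (d1 * d2);
    for (int ok = -1; ok <= 1; ++ok) {
      int kk = k + ok; if (kk < 0 || kk >= d3) continue;
      for (int oj = -1; oj <= 1; ++oj) {
        int jj = j + oj; if (jj < 0 || jj >= d2) continue;
        for (int oi = -1; oi <= 1; ++oi) {
          int ii = i + oi; if (ii < 0 || ii >= d1) continue;
          int o = (oi + 1) + 3 * (oj + 1) + 9 * (ok + 1);
          int vn = ii + d1 * (jj + d2 * kk);
          std::memcpy(col.colptr(t) + o * Cin, X.colptr(vn),
                      Cin * sizeof(double));
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv3d_forward(const arma::mat& X, const arma::mat& W,
                             const arma::vec& b, int d1, int d2, int d3) {
  int N = d1 * d2 * d3, Cin = X.n_rows, Cout = W.n_rows;
  mat Y(Cout, N);
  mat col(27 * Cin, CHUNK);
  for (int v0 = 0; v0 < N; v0 += CHUNK) {
    int nchunk = std::min(CHUNK, N - v0);
    if ((int)col.n_cols != nchunk) col.set_size(27 * Cin, nchunk);
    im2col_chunk(X, d1, d2, d3, v0, nchunk, col);
    Y.cols(v0, v0 + nchunk - 1) = W * col;
  }
  Y.each_col() += b;
  return Y;
}

// Gradient w.r.t. the input: col2im of W^T * GY.
// [[Rcpp::export]]
arma::mat cpp_conv3d_bwd_input(const arma::mat& W, const arma::mat& GY,
                               int d1, int d2, int d3, int Cin) {
  int N = d1 * d2 * d3;
  mat GX(Cin, N, fill::zeros);
  mat Wt = W.t(); // (27*Cin) x Cout
  for (int v0 = 0; v0 < N; v0 += CHUNK) {
    int nchunk = std::min(CHUNK, N - v0);
    mat G = Wt * GY.cols(v0, v0 + nchunk - 1); // (27*Cin) x nchunk
    for (int t = 0; t < nchunk; ++t) {
      int v = v0 + t;
      int i = v % d1, j = (v / d1) % d2, k = v / (d1 * d2);
      for (int ok = -1; ok <= 1; ++ok) {
        int kk = k + ok; if (kk < 0 || kk >= d3) continue;
        for (int oj = -1; oj <= 1; ++oj) {
          int jj = j + oj; if (jj < 0 || jj >= d2) continue;
          for (int oi = -1; oi <= 1; ++oi) {
            int ii = i + oi; if (ii < 0 || ii >= d1) continue;
            int o = (oi + 1) + 3 * (oj + 1) + 9 * (ok + 1);
            int vn = ii + d1 * (jj + d2 * kk);
            double* dst = GX.colptr(vn);
            const double* src = G.colptr(t) + o * Cin;
            for (int c = 0; c < Cin; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  return GX;
}

// Gradients w.r.t. weights and bias.
// [[Rcpp::export]]
Rcpp::List cpp_conv3d_bwd_params(const arma::mat& X, const arma::mat& GY,
                                 int d1, int d2, int d3) {
  int N = d1 * d2 * d3, Cin = X.n_rows, Cout = GY.n_rows;
  mat GW(Cout, 27 * Cin, fill::zeros);
  mat col(27 * Cin, CHUNK);
  for (int v0 = 0; v0 < N; v0 += CHUNK) {
    int nchunk = std::min(CHUNK, N - v0);
    if ((int)col.n_cols != nchunk) col.set_size(27 * Cin, nchunk);
    im2col_chunk(X, d1, d2, d3, v0, nchunk, col);
    GW += GY.cols(v0, v0 + nchunk - 1) * col.t();
  }
  vec Gb = sum(GY, 1);
  return Rcpp::List::create(Rcpp::Named("GW") = GW, Rcpp::Named("Gb") = Gb);
}

// 2x2x2 average pooling (all dims must be even).
// [[Rcpp::export]]
arma::mat cpp_avgpool(const arma::mat& X, int d1, int d2, int d3) {
  int C = X.n_rows, e1 = d1 / 2, e2 = d2 / 2, e3 = d3 / 2;
  mat Y(C, e1 * e2 * e3, fill::zeros);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int v = i + d1 * (j + d2 * k);
        int u = (i / 2) + e1 * ((j / 2) + e2 * (k / 2));
        Y.col(u) += X.col(v);
      }
  return Y / 8.0;
}

// [[Rcpp::export]]
arma::mat cpp_avgpool_bwd(const arma::mat& GY, int d1, int d2, int d3) {
  int C = GY.n_rows, e1 = d1 / 2, e2 = d2 / 2;
  mat GX(C, d1 * d2 * d3);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int v = i + d1 * (j + d2 * k);
        int u = (i / 2) + e1 * ((j / 2) + e2 * (k / 2));
        GX.col(v) = GY.col(u) / 8.0;
      }
  return GX;
}

// Nearest-neighbour 2x upsampling; (d1, d2, d3) are the *input* dims.
// [[Rcpp::export]]
arma::mat cpp_upsample(const arma::mat& X, int d1, int d2, int d3) {
  int C = X.n_rows, e1 = 2 * d1, e2 = 2 * d2, e3 = 2 * d3;
  mat Y(C, e1 * e2 * e3);
  for (int k = 0; k < e3; ++k)
    for (int j = 0; j < e2; ++j)
      for (int i = 0; i < e1; ++i) {
        int v = i + e1 * (j + e2 * k);
        int u = (i / 2) + d1 * ((j / 2) + d2 * (k / 2));
        Y.col(v) = X.col(u);
      }
  return Y;
}

// [[Rcpp::export]]
arma::mat cpp_upsample_bwd(const arma::mat& GY, int d1, int d2, int d3) {
  int C = GY.n_rows, e1 = 2 * d1, e2 = 2 * d2, e3 = 2 * d3;
  mat GX(C, d1 * d2 * d3, fill::zeros);
  for (int k = 0; k < e3; ++k)
    for (int j = 0; j < e2; ++j)
      for (int i = 0; i < e1; ++i) {
        int v = i + e1 * (j + e2 * k);
        int u = (i / 2) + d1 * ((j / 2) + d2 * (k / 2));
        GX.col(u) += GY.col(v);
      }
  return GX;
}
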