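#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Minimal conv-net primitives used by the cascaded U-Net generator and the
// discriminator. Feature maps are cubes H x W x C; convolution weights are
// matrices (k*k*Cin) x Cout with row index ki + k*kj + k*k*ci (0-based,
// ki = kernel row, kj = kernel col, ci = input channel), so that forward
// convolution is a single GEMM on the im2col matrix.

static mat im2col(const cube& x, int k, int pad, int stride, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat cols(k * k * C, Ho * Wo, fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    const mat& xs = x.slice(ci);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int row = ki + k * kj + k * k * ci;
        for (int wo = 0; wo < Wo; ++wo) {
          const int jin = wo * stride + kj - pad;
          if (jin < 0 || jin >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int iin = ho * stride + ki - pad;
            if (iin < 0 || iin >= H) continue;
            cols(row, ho + Ho * wo) = xs(iin, jin);
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_add(cube& gx, const mat& gcols, int k, int pad, int stride,
                       int Ho, int Wo) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int ci = 0; ci < C; ++ci) {
    mat& gs = gx.slice(ci);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int row = ki + k * kj + k * k * ci;
        for (int wo = 0; wo < Wo; ++wo) {
          const int jin = wo * stride + kj - pad;
          if (jin < 0 || jin >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int iin = ho * stride + ki - pad;
            if (iin < 0 || iin >= H) continue;
            gs(iin, jin) += gcols(row, ho + Ho * wo);
          }
        }
      }
    }
  }
}

static int out_dim(int n, int k, int pad, int stride) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, int k, int pad, int stride) {
  const int Ho = out_dim(x.n_rows, k, pad, stride);
  const int Wo = out_dim(x.n_cols, k, pad, stride);
  const int Cout = w.n_cols;
  mat cols = im2col(x, k, pad, stride, Ho, Wo);
  mat y = w.t() * cols;           // Cout x (Ho*Wo)
  y.each_col() += b;
  cube out(Ho, Wo, Cout);
  for (int co = 0; co < Cout; ++co)
    out.slice(co) = reshape(y.row(co), Ho, Wo);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                          const arma::cube& gy, int k, int pad, int stride) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, Cout = gy.n_slices;
  mat G(Cout, Ho * Wo);
  for (int co = 0; co < Cout; ++co)
    G.row(co) = vectorise(gy.slice(co)).t();
  mat cols = im2col(x, k, pad, stride, Ho, Wo);
  mat gw = cols * G.t();          // (k*k*Cin) x Cout
  vec gb = sum(G, 1);
  mat gcols = w * G;              // (k*k*Cin) x (Ho*Wo)
  cube gx(x.n_rows, x.n_cols, x.n_slices, fill::zeros);
  col2im_add(gx, gcols, k, pad, stride, Ho, Wo);
  return Rcpp::List::create(Rcpp::_["gx"] = gx, Rcpp::_["gw"] = gw,
                            Rcpp::_["gb"] = gb);
}

// 2x2 average pooling (H, W must be even)
// [[Rcpp::export]]
arma::cube cpp_avgpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  cube y(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        y(i, j, c) = 0.25 * (x(2 * i, 2 * j, c) + x(2 * i + 1, 2 * j, c) +
                             x(2 * i, 2 * j + 1, c) + x(2 * i + 1, 2 * j + 1, c));
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_avgpool2_bwd(const arma::cube& gy) {
  const int H = gy.n_rows, W = gy.n_cols, C = gy.n_slices;
  cube gx(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double g = 0.25 * gy(i, j, c);
        gx(2 * i, 2 * j, c) = g;
        gx(2 * i + 1, 2 * j, c) = g;
        gx(2 * i, 2 * j + 1, c) = g;
        gx(2 * i + 1, 2 * j + 1, c) = g;
      }
  return gx;
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export]]
arma::cube cpp_upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube& gy) {
  const int H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  cube gx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        gx(i, j, c) = gy(2 * i, 2 * j, c) + gy(2 * i + 1, 2 * j, c) +
                      gy(2 * i, 2 * j + 1, c) + gy(2 * i + 1, 2 * j + 1, c);
  return gx;
}
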