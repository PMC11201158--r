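// Minimal convolutional-network primitives used by the U-Net segmenter and
// the contrastive unpaired translation generator. Feature maps are R arrays
// of dim c(H, W, C) (column-major, so they map directly onto arma::cube).
// Convolution weights are packed as a (k*k*C_in) x C_out matrix whose row
// order matches column-major flattening of an array of dim c(k, k, C_in).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col for a square kernel k, given stride and zero padding.
// Output: (Ho*Wo) x (k*k*Cin); row index runs over output pixels
// column-major (h fastest), matching R's array layout.
static mat im2col(const cube& x, int k, int stride, int pad,
                  int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(Ho * (size_t)Wo, (size_t)k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const size_t col = (size_t)c * k * k + (size_t)kx * k + ky;
        for (int j = 0; j < Wo; ++j) {
          const int xw = j * stride + kx - pad;
          if (xw < 0 || xw >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int xh = i * stride + ky - pad;
            if (xh < 0 || xh >= H) continue;
            out((size_t)j * Ho + i, col) = x(xh, xw, c);
          }
        }
      }
    }
  }
  return out;
}

// scatter-add transpose of im2col
static cube col2im(const mat& cols, int H, int W, int C, int k,
                   int stride, int pad, int Ho, int Wo) {
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const size_t col = (size_t)c * k * k + (size_t)kx * k + ky;
        for (int j = 0; j < Wo; ++j) {
          const int xw = j * stride + kx - pad;
          if (xw < 0 || xw >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int xh = i * stride + ky - pad;
            if (xh < 0 || xh >= H) continue;
            dx(xh, xw, c) += cols((size_t)j * Ho + i, col);
          }
        }
      }
    }
  }
  return dx;
}

static int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(name = ".conv2d_fw")]]
arma::cube conv2d_fw(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b, int k, int stride, int pad) {
  const int Ho = out_size(x.n_rows, k, stride, pad);
  const int Wo = out_size(x.n_cols, k, stride, pad);
  const int Cout = w.n_cols;
  mat cols = im2col(x, k, stride, pad, Ho, Wo);
  mat y = cols * w;                 // (Ho*Wo) x Cout
  y.each_row() += b.t();
  cube out(Ho, Wo, Cout);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
Rcpp::List conv2d_bw(const arma::cube& x, const arma::mat& w,
                     const arma::cube& dout, int k, int stride, int pad) {
  const int Ho = dout.n_rows, Wo = dout.n_cols, Cout = dout.n_slices;
  mat dymat(const_cast<double*>(dout.memptr()), (size_t)Ho * Wo, Cout,
            false, true);
  mat cols = im2col(x, k, stride, pad, Ho, Wo);
  mat dw = cols.t() * dymat;                    // (k*k*Cin) x Cout
  vec db = sum(dymat, 0).t();
  mat dcols = dymat * w.t();                    // (Ho*Wo) x (k*k*Cin)
  cube dx = col2im(dcols, x.n_rows, x.n_cols, x.n_slices, k, stride, pad,
                   Ho, Wo);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// 2x2 max pooling, stride 2. Returns pooled map and flat argmax indices
// (1-based into the input cube) for the backward pass.
// [[Rcpp::export(name = ".maxpool_fw")]]
Rcpp::List maxpool_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  Rcpp::IntegerVector idx((size_t)Ho * Wo * C);
  size_t p = 0;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf; int bh = 0, bw = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; bh = 2 * i + di; bw = 2 * j + dj; }
          }
        y(i, j, c) = best;
        idx[p++] = 1 + bh + bw * H + c * H * W;
      }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
arma::cube maxpool_bw(const arma::cube& dout, const Rcpp::IntegerVector& idx,
                      int H, int W, int C) {
  cube dx(H, W, C, fill::zeros);
  const double* d = dout.memptr();
  for (size_t p = 0; p < (size_t)idx.size(); ++p)
    dx.memptr()[idx[p] - 1] += d[p];
  return dx;
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export(name = ".upsample2_fw")]]
arma::cube upsample2_fw(const arma::cube& x) {
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

// [[Rcpp::export(name = ".upsample2_bw")]]
arma::cube upsample2_bw(const arma::cube& dout) {
  const int H = dout.n_rows / 2, W = dout.n_cols / 2, C = dout.n_slices;
  cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dx(i, j, c) = dout(2 * i, 2 * j, c) + dout(2 * i + 1, 2 * j, c) +
                      dout(2 * i, 2 * j + 1, c) + dout(2 * i + 1, 2 * j + 1, c);
  return dx;
}

// valid-mode single-channel cross-correlation, used by the SSIM window
// [[Rcpp::export(name = ".filter2_valid")]]
arma::mat filter2_valid(const arma::mat& x, const arma::mat& w) {
  const int k = w.n_rows;
  const int Ho = x.n_rows - k + 1, Wo = x.n_cols - k + 1;
  mat out(Ho, Wo);
  for (int j = 0; j < Wo; ++j)
    for (int i = 0; i < Ho; ++i)
      out(i, j) = accu(x.submat(i, j, i + k - 1, j + k - 1) % w);
  return out;
}
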