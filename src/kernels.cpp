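// Minimal convolutional kernels for the cGAN networks.
// Tensors are R arrays dim (H, W, C), mapped onto arma::cube without copy
// semantics changes (R arrays are column-major, matching cube(H, W, C)).
// Convolutions are stride-1, odd kernel, "same" zero padding, computed by
// im2col + GEMM so they ride on BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// column layout for im2col: row index = di + k*(dj + k*c)  (di, dj in 0..k-1)
static mat im2col(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, P = (k - 1) / 2;
  mat cols(H * W, k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = di + k * (dj + k * c);
        // output pixel (i, j) reads input (i + di - P, j + dj - P)
        const int i0 = std::max(0, P - di), i1 = std::min(H, H + P - di);
        const int j0 = std::max(0, P - dj), j1 = std::min(W, W + P - dj);
        if (i1 <= i0 || j1 <= j0) continue;
        for (int j = j0; j < j1; ++j) {
          const double* src = x.slice_colptr(c, j + dj - P);
          double* dst = cols.colptr(col) + (size_t)j * H;
          for (int i = i0; i < i1; ++i) dst[i] = src[i + di - P];
        }
      }
    }
  }
  return cols;
}

// scatter-add transpose of im2col
static cube col2im(const mat& cols, const int H, const int W, const int C,
                   const int k) {
  const int P = (k - 1) / 2;
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = di + k * (dj + k * c);
        const int i0 = std::max(0, P - di), i1 = std::min(H, H + P - di);
        const int j0 = std::max(0, P - dj), j1 = std::min(W, W + P - dj);
        if (i1 <= i0 || j1 <= j0) continue;
        for (int j = j0; j < j1; ++j) {
          double* dst = x.slice_colptr(c, j + dj - P);
          const double* src = cols.colptr(col) + (size_t)j * H;
          for (int i = i0; i < i1; ++i) dst[i + di - P] += src[i];
        }
      }
    }
  }
  return x;
}

// x: (H, W, Cin); w: (k*k*Cin, Cout); b: length Cout
// [[Rcpp::export(name = ".conv2d_forward")]]
arma::cube conv2d_forward(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, const int k) {
  const int H = x.n_rows, W = x.n_cols, Cout = w.n_cols;
  mat y = im2col(x, k) * w;          // (H*W, Cout)
  y.each_row() += b.t();
  return cube(y.memptr(), H, W, Cout);
}

// returns list(dx, dw, db)
// [[Rcpp::export(name = ".conv2d_backward")]]
Rcpp::List conv2d_backward(const arma::cube& x, const arma::mat& w,
                           const arma::cube& dy, const int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  const mat dym(const_cast<double*>(dy.memptr()), H * W, Cout, false, true);
  mat cols = im2col(x, k);
  mat dw = cols.t() * dym;
  vec db = sum(dym, 0).t();
  cube dx = col2im(dym * w.t(), H, W, Cin, k);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// forward that also hands back the im2col matrix for reuse in backward
// [[Rcpp::export(name = ".conv2d_forward_cols")]]
Rcpp::List conv2d_forward_cols(const arma::cube& x, const arma::mat& w,
                               const arma::vec& b, const int k) {
  const int H = x.n_rows, W = x.n_cols, Cout = w.n_cols;
  mat cols = im2col(x, k);
  mat y = cols * w;
  y.each_row() += b.t();
  return Rcpp::List::create(Rcpp::Named("y") = cube(y.memptr(), H, W, Cout),
                            Rcpp::Named("cols") = cols);
}

// backward reusing cached im2col columns
// [[Rcpp::export(name = ".conv2d_backward_cols")]]
Rcpp::List conv2d_backward_cols(const arma::mat& cols, const arma::mat& w,
                                const arma::cube& dy, const int Cin,
                                const int k) {
  const int H = dy.n_rows, W = dy.n_cols, Cout = dy.n_slices;
  const mat dym(const_cast<double*>(dy.memptr()), H * W, Cout, false, true);
  mat dw = cols.t() * dym;
  vec db = sum(dym, 0).t();
  cube dx = col2im(dym * w.t(), H, W, Cin, k);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// 2x2 max pool, stride 2; H, W assumed even. Returns list(y, which) where
// which holds 0-based linear indices into the input slice of each maximum.
// [[Rcpp::export(name = ".maxpool2_forward")]]
Rcpp::List maxpool2_forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int h = H / 2, w = W / 2;
  cube y(h, w, C);
  ucube idx(h, w, C);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        const int ii = 2 * i, jj = 2 * j;
        double best = xs(ii, jj);
        int bi = ii, bj = jj;
        if (xs(ii + 1, jj) > best) { best = xs(ii + 1, jj); bi = ii + 1; bj = jj; }
        if (xs(ii, jj + 1) > best) { best = xs(ii, jj + 1); bi = ii; bj = jj + 1; }
        if (xs(ii + 1, jj + 1) > best) { best = xs(ii + 1, jj + 1); bi = ii + 1; bj = jj + 1; }
        y(i, j, c) = best;
        idx(i, j, c) = (uword)(bi + H * bj);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("which") = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
arma::cube maxpool2_backward(const arma::cube& dy, const arma::ucube& which,
                             const int H, const int W) {
  const int h = dy.n_rows, w = dy.n_cols, C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* dxs = dx.slice_colptr(c, 0);
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i)
        dxs[which(i, j, c)] += dy(i, j, c);
  }
  return dx;
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export(name = ".upsample2_forward")]]
arma::cube upsample2_forward(const arma::cube& x) {
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

// [[Rcpp::export(name = ".upsample2_backward")]]
arma::cube upsample2_backward(const arma::cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}
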