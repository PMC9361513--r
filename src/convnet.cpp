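// Minimal dense conv-net kernels: 3x3 same-padding convolution and 2x2
// max-pooling, forward and backward.  Tensors are arma::cube with layout
// (H, W, C); filter banks are matrices of shape (C_out, 9 * C_in) whose
// columns follow the im2col ordering used below (channel-major, then the
// 3x3 offset in column-major di/dj order).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col3(const cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat cols(9 * C, H * W, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const uword r = c * 9 + (dj + 1) * 3 + (di + 1);
        for (uword j = 0; j < W; ++j) {
          const int js = (int)j + dj;
          if (js < 0 || js >= (int)W) continue;
          for (uword i = 0; i < H; ++i) {
            const int is = (int)i + di;
            if (is < 0 || is >= (int)H) continue;
            cols(r, j * H + i) = x(is, js, c);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".cv_conv3_fwd")]]
arma::cube cv_conv3_fwd(const arma::cube& x, const arma::mat& w,
                        const arma::vec& b) {
  const uword H = x.n_rows, W = x.n_cols;
  const uword Cout = w.n_rows;
  if (w.n_cols != 9 * x.n_slices)
    Rcpp::stop("filter bank does not match input channel count");
  mat cols = im2col3(x);
  mat y = w * cols;
  y.each_col() += b;
  cube out(H, W, Cout);
  for (uword c = 0; c < Cout; ++c)
    out.slice(c) = reshape(y.row(c).t(), H, W);
  return out;
}

// [[Rcpp::export(name = ".cv_conv3_bwd")]]
Rcpp::List cv_conv3_bwd(const arma::cube& x, const arma::mat& w,
                        const arma::cube& dy) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const uword Cout = dy.n_slices;
  mat dym(Cout, H * W);
  for (uword c = 0; c < Cout; ++c)
    dym.row(c) = vectorise(dy.slice(c)).t();
  mat cols = im2col3(x);
  mat dw = dym * cols.t();
  vec db = sum(dym, 1);
  mat dcols = w.t() * dym;  // (9C) x (HW)
  cube dx(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const uword r = c * 9 + (dj + 1) * 3 + (di + 1);
        for (uword j = 0; j < W; ++j) {
          const int js = (int)j + dj;
          if (js < 0 || js >= (int)W) continue;
          for (uword i = 0; i < H; ++i) {
            const int is = (int)i + di;
            if (is < 0 || is >= (int)H) continue;
            dx(is, js, c) += dcols(r, j * H + i);
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export(name = ".cv_maxpool2_fwd")]]
Rcpp::List cv_maxpool2_fwd(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) Rcpp::stop("max-pooling expects even spatial dims");
  const uword Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  ucube idx(Ho, Wo, C);  // linear index into the input slice
  for (uword c = 0; c < C; ++c) {
    for (uword j = 0; j < Wo; ++j) {
      for (uword i = 0; i < Ho; ++i) {
        double best = -datum::inf;
        uword bestk = 0;
        for (uword dj = 0; dj < 2; ++dj) {
          for (uword di = 0; di < 2; ++di) {
            const uword ii = 2 * i + di, jj = 2 * j + dj;
            const double v = x(ii, jj, c);
            if (v > best) { best = v; bestk = jj * H + ii; }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = bestk;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".cv_maxpool2_bwd")]]
arma::cube cv_maxpool2_bwd(const arma::ucube& idx, const arma::cube& dy,
                           int H, int W) {
  const uword C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    double* sl = dx.slice_memptr(c);
    for (uword j = 0; j < dy.n_cols; ++j)
      for (uword i = 0; i < dy.n_rows; ++i)
        sl[idx(i, j, c)] += dy(i, j, c);
  }
  return dx;
}
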