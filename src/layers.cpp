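// Compiled kernels for the network layers: im2col-based 3x3 convolution,
// 2x2 max pooling, 2x2 transposed convolution and per-channel plane
// normalization, forward and backward.  Matrix products go through the
// BLAS via Armadillo; these kernels only remove R-level copy overhead,
// the math is identical to the pure-R formulation they replaced.
//
// Layout conventions (match the R side):
//   feature map: arma::cube (H, W, C), column-major
//   3x3 weights: (9*Cin x Cout); row block (k-1)*Cin + c is offset
//                k = 3*di + dj + 1 (di, dj in 0..2), input channel c
//   2x2 transposed-conv weights: (Cin x 4*Cout); column block
//                (k-1)*Cout + co is output offset k = 2*di + dj + 1

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// The convolution GEMMs run in single precision by default: the layers
// feed through saturating nonlinearities and an optimizer with its own
// noise floor, so float32 matmuls (the deep-learning default) are ample,
// and they halve the memory traffic that dominates these kernels.  The
// R-facing interface stays double, and a double-precision path (`single =
// false`) is kept for numerical verification (finite-difference gradient
// checks need it).

template <typename eT>
static arma::Mat<eT> im2col3(const arma::Cube<eT>& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::Mat<eT> cols(H * W, 9 * C);
  // padded source coordinates: out(i,j) pulls xp(i+di, j+dj) with pad 1
  for (int di = 0; di < 3; ++di) {
    for (int dj = 0; dj < 3; ++dj) {
      const uword k = 3 * di + dj;
      for (uword c = 0; c < C; ++c) {
        eT* dst = cols.colptr(k * C + c);
        const arma::Mat<eT>& xc = x.slice(c);
        for (uword j = 0; j < W; ++j) {
          const int sj = (int)j + dj - 1;
          eT* d = dst + j * H;
          if (sj < 0 || sj >= (int)W) {
            std::memset(d, 0, H * sizeof(eT));
            continue;
          }
          const eT* s = xc.colptr(sj);
          // rows i pull source i + di - 1
          if (di == 1) {
            std::memcpy(d, s, H * sizeof(eT));
          } else if (di == 0) {
            d[0] = eT(0);
            std::memcpy(d + 1, s, (H - 1) * sizeof(eT));
          } else {
            std::memcpy(d, s + 1, (H - 1) * sizeof(eT));
            d[H - 1] = eT(0);
          }
        }
      }
    }
  }
  return cols;
}

template <typename eT>
static arma::Cube<eT> col2im3(const arma::Mat<eT>& dcols, uword H, uword W,
                              uword C) {
  arma::Cube<eT> dx(H, W, C, fill::zeros);
  for (int di = 0; di < 3; ++di) {
    for (int dj = 0; dj < 3; ++dj) {
      const uword k = 3 * di + dj;
      for (uword c = 0; c < C; ++c) {
        const eT* src = dcols.colptr(k * C + c);
        arma::Mat<eT>& xc = dx.slice(c);
        for (uword j = 0; j < W; ++j) {
          const int sj = (int)j + dj - 1;
          if (sj < 0 || sj >= (int)W) continue;
          eT* d = xc.colptr(sj);
          const eT* s = src + j * H;
          if (di == 1) {
            for (uword i = 0; i < H; ++i) d[i] += s[i];
          } else if (di == 0) {
            for (uword i = 1; i < H; ++i) d[i - 1] += s[i];
          } else {
            for (uword i = 0; i + 1 < H; ++i) d[i + 1] += s[i];
          }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube conv3_fw_cpp(const arma::cube& x, const arma::mat& W,
                        const arma::vec& b, bool single = true) {
  const uword H = x.n_rows, Wd = x.n_cols;
  if (!single) {
    mat y = im2col3<double>(x) * W;
    y.each_row() += b.t();
    return cube(y.memptr(), H, Wd, W.n_cols);
  }
  const fcube xf = conv_to<fcube>::from(x);
  fmat y = im2col3<float>(xf) * conv_to<fmat>::from(W);
  y.each_row() += conv_to<frowvec>::from(b.t());
  cube out(H, Wd, W.n_cols);
  std::copy(y.begin(), y.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv3_bw_cpp(const arma::cube& x, const arma::cube& dy,
                        const arma::mat& W, bool single = true) {
  const uword H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const uword Cout = dy.n_slices;
  if (!single) {
    const mat cols = im2col3<double>(x);
    const mat dY(const_cast<double*>(dy.memptr()), H * Wd, Cout, false);
    mat dW = cols.t() * dY;
    vec db = sum(dY, 0).t();
    cube dx = col2im3<double>(dY * W.t(), H, Wd, C);
    return Rcpp::List::create(Rcpp::Named("dx") = dx,
                              Rcpp::Named("dW") = dW,
                              Rcpp::Named("db") = db);
  }
  const fcube xf = conv_to<fcube>::from(x);
  const fcube dyf = conv_to<fcube>::from(dy);
  const fmat cols = im2col3<float>(xf);
  const fmat dY(const_cast<float*>(dyf.memptr()), H * Wd, Cout, false);
  const fmat Wf = conv_to<fmat>::from(W);
  fmat dWf = cols.t() * dY;
  vec db = conv_to<vec>::from(sum(dY, 0).t());
  fcube dxf = col2im3<float>(dY * Wf.t(), H, Wd, C);
  cube dx(H, Wd, C);
  std::copy(dxf.begin(), dxf.end(), dx.begin());
  mat dW = conv_to<mat>::from(dWf);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List pool_fw_cpp(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const uword h = H / 2, w = W / 2;
  cube y(h, w, C);
  Rcpp::IntegerVector idx(h * w * C);
  uword n = 0;
  for (uword c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    mat& yc = y.slice(c);
    for (uword j = 0; j < w; ++j) {
      for (uword i = 0; i < h; ++i) {
        // candidate order k = 2*di + dj + 1, matching (0,0),(0,1),(1,0),(1,1)
        const double v1 = xc(2 * i, 2 * j), v2 = xc(2 * i, 2 * j + 1);
        const double v3 = xc(2 * i + 1, 2 * j), v4 = xc(2 * i + 1, 2 * j + 1);
        double best = v1; int bk = 1;
        if (v2 > best) { best = v2; bk = 2; }
        if (v3 > best) { best = v3; bk = 3; }
        if (v4 > best) { best = v4; bk = 4; }
        yc(i, j) = best;
        idx[c * h * w + j * h + i] = bk;
        ++n;
      }
    }
  }
  (void)n;
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube pool_bw_cpp(const arma::cube& dy, const Rcpp::IntegerVector& idx) {
  const uword h = dy.n_rows, w = dy.n_cols, C = dy.n_slices;
  cube dx(2 * h, 2 * w, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const mat& dc = dy.slice(c);
    mat& xc = dx.slice(c);
    for (uword j = 0; j < w; ++j) {
      for (uword i = 0; i < h; ++i) {
        const int k = idx[c * h * w + j * h + i] - 1;
        xc(2 * i + k / 2, 2 * j + k % 2) = dc(i, j);
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube tconv_fw_cpp(const arma::cube& x, const arma::mat& W,
                        const arma::vec& b) {
  const uword h = x.n_rows, w = x.n_cols;
  const uword Cout = b.n_elem;
  const mat X(const_cast<double*>(x.memptr()), h * w, x.n_slices, false);
  mat M = X * W;                       // (hw x 4*Cout)
  cube y(2 * h, 2 * w, Cout);
  for (uword co = 0; co < Cout; ++co) {
    mat& yc = y.slice(co);
    for (int di = 0; di < 2; ++di) {
      for (int dj = 0; dj < 2; ++dj) {
        const uword k = 2 * di + dj;
        const double* s = M.colptr(k * Cout + co);
        for (uword j = 0; j < w; ++j)
          for (uword i = 0; i < h; ++i)
            yc(2 * i + di, 2 * j + dj) = s[j * h + i] + b[co];
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List tconv_bw_cpp(const arma::cube& x, const arma::cube& dy,
                        const arma::mat& W, int Cout_) {
  const uword h = x.n_rows, w = x.n_cols;
  const uword Cout = (uword)Cout_;
  mat dM(h * w, 4 * Cout);
  vec db(Cout, fill::zeros);
  for (uword co = 0; co < Cout; ++co) {
    const mat& dc = dy.slice(co);
    db[co] = accu(dc);
    for (int di = 0; di < 2; ++di) {
      for (int dj = 0; dj < 2; ++dj) {
        const uword k = 2 * di + dj;
        double* d = dM.colptr(k * Cout + co);
        for (uword j = 0; j < w; ++j)
          for (uword i = 0; i < h; ++i)
            d[j * h + i] = dc(2 * i + di, 2 * j + dj);
      }
    }
  }
  const mat X(const_cast<double*>(x.memptr()), h * w, x.n_slices, false);
  mat dW = X.t() * dM;
  mat dxm = dM * W.t();
  cube dx(dxm.memptr(), h, w, x.n_slices);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List norm_fw_cpp(const arma::cube& x, const arma::vec& g,
                       const arma::vec& beta, double eps) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const uword N = H * W;
  cube y(H, W, C);
  mat xhat(N, C);
  vec istd(C);
  for (uword c = 0; c < C; ++c) {
    const double* s = x.slice(c).memptr();
    double mu = 0;
    for (uword i = 0; i < N; ++i) mu += s[i];
    mu /= N;
    double v = 0;
    for (uword i = 0; i < N; ++i) { const double d = s[i] - mu; v += d * d; }
    v /= N;
    const double is = 1.0 / std::sqrt(v + eps);
    istd[c] = is;
    double* xh = xhat.colptr(c);
    double* yc = y.slice(c).memptr();
    for (uword i = 0; i < N; ++i) {
      xh[i] = (s[i] - mu) * is;
      yc[i] = g[c] * xh[i] + beta[c];
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("istd") = istd);
}

// [[Rcpp::export]]
Rcpp::List norm_bw_cpp(const arma::cube& dy, const arma::mat& xhat,
                       const arma::vec& istd, const arma::vec& g) {
  const uword H = dy.n_rows, W = dy.n_cols, C = dy.n_slices;
  const uword N = H * W;
  cube dx(H, W, C);
  vec dg(C), dbeta(C);
  for (uword c = 0; c < C; ++c) {
    const double* d = dy.slice(c).memptr();
    const double* xh = xhat.colptr(c);
    double sg = 0, sb = 0, sxh = 0;
    for (uword i = 0; i < N; ++i) {
      sg += d[i] * xh[i];
      sb += d[i];
    }
    dg[c] = sg; dbeta[c] = sb;
    const double m_dxhat = g[c] * sb / N;          // mean of dxhat
    sxh = g[c] * sg / N;                           // mean of dxhat * xhat
    double* o = dx.slice(c).memptr();
    for (uword i = 0; i < N; ++i)
      o[i] = istd[c] * (g[c] * d[i] - m_dxhat - xh[i] * sxh);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dg") = dg,
                            Rcpp::Named("dbeta") = dbeta);
}
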