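// Zero-padded stride-1 2D convolution, forward and backward, on batches
// stored as (h*w*channels) x N matrices with pixel-major rows. Each
// sample's im2col block is built transposed (hw x k^2*cin, column-major)
// so both the gemm and the output layout are contiguous; the backward
// pass rebuilds the block instead of caching it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Fill B (hw x k2*cin) with the padded patches of one sample.
static void im2col_t(const double* x, int h, int w, int cin, int k, mat& B) {
  const int r = k / 2;
  const int hw = h * w;
  B.zeros();
  int col = 0;
  for (int c = 0; c < cin; ++c) {
    const double* xc = x + (size_t)c * hw;
    for (int dj = -r; dj <= r; ++dj) {
      for (int di = -r; di <= r; ++di) {
        double* bc = B.colptr(col++);
        const int j0 = std::max(0, -dj), j1 = std::min(w, w - dj);
        const int i0 = std::max(0, -di), i1 = std::min(h, h - di);
        for (int j = j0; j < j1; ++j) {
          const double* src = xc + (size_t)(j + dj) * h + (i0 + di);
          double* dst = bc + (size_t)j * h + i0;
          std::memcpy(dst, src, sizeof(double) * (i1 - i0));
        }
      }
    }
  }
}

// Scatter-add the reverse of im2col_t: D (hw x k2*cin) into dx (one sample).
static void col2im_t(const mat& D, int h, int w, int cin, int k, double* dx) {
  const int r = k / 2;
  const int hw = h * w;
  int col = 0;
  for (int c = 0; c < cin; ++c) {
    double* xc = dx + (size_t)c * hw;
    for (int dj = -r; dj <= r; ++dj) {
      for (int di = -r; di <= r; ++di) {
        const double* bc = D.colptr(col++);
        const int j0 = std::max(0, -dj), j1 = std::min(w, w - dj);
        const int i0 = std::max(0, -di), i1 = std::min(h, h - di);
        for (int j = j0; j < j1; ++j) {
          const double* src = bc + (size_t)j * h + i0;
          double* dst = xc + (size_t)(j + dj) * h + (i0 + di);
          const int len = i1 - i0;
          for (int i = 0; i < len; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv_forward(const arma::mat& x, const arma::mat& Wt,
                           const arma::vec& b, int h, int w, int cin,
                           int k) {
  const int hw = h * w;
  const int cout = Wt.n_cols;
  const int n = x.n_cols;
  mat y(hw * cout, n);
  mat B(hw, k * k * cin);
  mat Yn(hw, cout);
  for (int s = 0; s < n; ++s) {
    im2col_t(x.colptr(s), h, w, cin, k, B);
    Yn = B * Wt;
    Yn.each_row() += b.t();
    std::memcpy(y.colptr(s), Yn.memptr(), sizeof(double) * hw * cout);
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_backward(const arma::mat& x, const arma::mat& dy,
                             const arma::mat& Wt, int h, int w, int cin,
                             int k) {
  const int hw = h * w;
  const int cout = Wt.n_cols;
  const int n = x.n_cols;
  mat dx(hw * cin, n, fill::zeros);
  mat dWt(Wt.n_rows, cout, fill::zeros);
  vec db(cout, fill::zeros);
  mat B(hw, k * k * cin);
  for (int s = 0; s < n; ++s) {
    const mat dYn(const_cast<double*>(dy.colptr(s)), hw, cout, false, true);
    im2col_t(x.colptr(s), h, w, cin, k, B);
    dWt += B.t() * dYn;
    db += sum(dYn, 0).t();
    mat D = dYn * Wt.t();          // hw x k2cin
    col2im_t(D, h, w, cin, k, dx.colptr(s));
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dWt") = dWt,
                            Rcpp::Named("db") = db);
}
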