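// Same-padding 1-D convolution kernels for the sequence models.
// Layout matches the R side: activations are (channels x positions*batch)
// matrices, columns ordered position-major within each sample.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col_same(const arma::mat& x, int L, int B, int K) {
  const int C = x.n_rows;
  const int P = (K - 1) / 2;
  arma::mat xcol(C * K, (size_t)L * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int l = 0; l < L; ++l) {
      const size_t oc = (size_t)b * L + l;
      double* dst = xcol.colptr(oc);
      for (int t = 0; t < K; ++t) {
        const int src = l + t - P;
        if (src < 0 || src >= L) continue;
        std::memcpy(dst + (size_t)t * C, x.colptr((size_t)b * L + src),
                    C * sizeof(double));
      }
    }
  }
  return xcol;
}

// [[Rcpp::export(name = ".conv1d_fwd_cpp")]]
arma::mat conv1d_fwd_cpp(const arma::mat& W, const arma::vec& b,
                         const arma::mat& x, int L, int B) {
  const int K = W.n_cols / x.n_rows;
  arma::mat out = W * im2col_same(x, L, B, K);
  out.each_col() += b;
  return out;
}

// [[Rcpp::export(name = ".conv1d_bwd_cpp")]]
List conv1d_bwd_cpp(const arma::mat& W, const arma::mat& x,
                    const arma::mat& dout, int L, int B,
                    bool need_dx) {
  const int C = x.n_rows;
  const int K = W.n_cols / C;
  const int P = (K - 1) / 2;
  arma::mat xcol = im2col_same(x, L, B, K);
  arma::mat dW = dout * xcol.t();
  arma::vec db = arma::sum(dout, 1);
  arma::mat dx;
  if (need_dx) {
    arma::mat dxcol = W.t() * dout;
    dx.zeros(C, (size_t)L * B);
    for (int b2 = 0; b2 < B; ++b2) {
      for (int l = 0; l < L; ++l) {
        const size_t oc = (size_t)b2 * L + l;
        const double* src = dxcol.colptr(oc);
        for (int t = 0; t < K; ++t) {
          const int tgt = l + t - P;
          if (tgt < 0 || tgt >= L) continue;
          double* dst = dx.colptr((size_t)b2 * L + tgt);
          const double* seg = src + (size_t)t * C;
          for (int c = 0; c < C; ++c) dst[c] += seg[c];
        }
      }
    }
  }
  return List::create(Named("dW") = dW, Named("db") = db,
                      Named("dx") = dx);
}
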