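// Multi-head self-attention kernels. Activations are (d x L*B)
// matrices (columns position-major per sample); heads split the rows.
// The attention matrices are returned through a pre-allocated R vector
// aliased as an arma::cube, avoiding a copy of the (L x L x B*H) array.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".mha_fwd_cpp")]]
List mha_fwd_cpp(const arma::mat& q, const arma::mat& k, const arma::mat& v,
                 int L, int B, int H) {
  const int d = q.n_rows;
  const int dh = d / H;
  NumericMatrix ctx_r(d, L * B);
  arma::mat ctx(ctx_r.begin(), d, (size_t)L * B, false, true);
  NumericVector A_r((R_xlen_t)L * L * B * H);
  arma::cube A(A_r.begin(), L, L, (size_t)B * H, false, true);
  arma::mat S(L, L);
  for (int b = 0; b < B; ++b) {
    const arma::uword c0 = (arma::uword)b * L;
    for (int h = 0; h < H; ++h) {
      const arma::uword r0 = (arma::uword)h * dh;
      S = q.submat(r0, c0, r0 + dh - 1, c0 + L - 1).t() *
          k.submat(r0, c0, r0 + dh - 1, c0 + L - 1);
      S /= std::sqrt((double)dh);
      arma::vec m = arma::max(S, 1);
      S.each_col() -= m;
      S.transform([](double x) { return std::exp(x); });
      arma::vec s = arma::sum(S, 1);
      S.each_col() /= s;
      A.slice((size_t)b * H + h) = S;
      ctx.submat(r0, c0, r0 + dh - 1, c0 + L - 1) =
        v.submat(r0, c0, r0 + dh - 1, c0 + L - 1) * S.t();
    }
  }
  A_r.attr("dim") = IntegerVector::create(L, L, B * H);
  return List::create(Named("ctx") = ctx_r, Named("A") = A_r);
}

// [[Rcpp::export(name = ".mha_bwd_cpp")]]
List mha_bwd_cpp(const arma::mat& q, const arma::mat& k, const arma::mat& v,
                 const NumericVector& A_r, const arma::mat& dctx,
                 int L, int B, int H) {
  const int d = q.n_rows;
  const int dh = d / H;
  const arma::cube A(const_cast<double*>(A_r.begin()), L, L,
                     (size_t)B * H, false, true);
  NumericMatrix dq_r(d, L * B), dk_r(d, L * B), dv_r(d, L * B);
  arma::mat dq(dq_r.begin(), d, (size_t)L * B, false, true);
  arma::mat dk(dk_r.begin(), d, (size_t)L * B, false, true);
  arma::mat dv(dv_r.begin(), d, (size_t)L * B, false, true);
  arma::mat dA(L, L), dS(L, L);
  for (int b = 0; b < B; ++b) {
    const arma::uword c0 = (arma::uword)b * L;
    for (int h = 0; h < H; ++h) {
      const arma::uword r0 = (arma::uword)h * dh;
      const arma::mat& Ab = A.slice((size_t)b * H + h);
      arma::mat dc = dctx.submat(r0, c0, r0 + dh - 1, c0 + L - 1);
      arma::mat Vb = v.submat(r0, c0, r0 + dh - 1, c0 + L - 1);
      dA = dc.t() * Vb;   // dA(i, j) = sum_d dc(d, i) Vb(d, j)
      dv.submat(r0, c0, r0 + dh - 1, c0 + L - 1) = dc * Ab;
      arma::vec rs = arma::sum(dA % Ab, 1);
      dS = Ab % (dA.each_col() - rs);
      dS /= std::sqrt((double)dh);
      dq.submat(r0, c0, r0 + dh - 1, c0 + L - 1) =
        k.submat(r0, c0, r0 + dh - 1, c0 + L - 1) * dS.t();
      dk.submat(r0, c0, r0 + dh - 1, c0 + L - 1) =
        q.submat(r0, c0, r0 + dh - 1, c0 + L - 1) * dS;
    }
  }
  return List::create(Named("dq") = dq_r, Named("dk") = dk_r,
                      Named("dv") = dv_r);
}
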