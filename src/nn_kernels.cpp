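// Hot kernels of the AE-AR network: dense and residual-block forward /
// backward passes.  The layer loop stays in R; these routines fuse the
// matrix products (BLAS via Armadillo) with the leaky-ReLU masks so the
// per-step R overhead and temporary allocations disappear.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// leaky-ReLU gradient factor, computed in place
static arma::mat lrelu_factor(const arma::mat& z, double slope) {
  arma::mat g(z.n_rows, z.n_cols);
  const double* zp = z.memptr();
  double* gp = g.memptr();
  const arma::uword n = z.n_elem;
  for (arma::uword i = 0; i < n; ++i) gp[i] = zp[i] > 0 ? 1.0 : slope;
  return g;
}

// [[Rcpp::export(name = ".dense_fwd")]]
arma::mat dense_fwd(const arma::mat& X, const arma::mat& W,
                    const arma::vec& b) {
  arma::mat out = X * W;
  out.each_row() += b.t();
  return out;
}

// [[Rcpp::export(name = ".dense_bwd")]]
List dense_bwd(const arma::mat& X, const arma::mat& W, const arma::mat& dOut) {
  arma::mat dW = X.t() * dOut;
  arma::rowvec db = arma::sum(dOut, 0);
  arma::mat dX = dOut * W.t();
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}

// [[Rcpp::export(name = ".resblock_fwd")]]
List resblock_fwd(const arma::mat& X, const arma::mat& W1, const arma::vec& b1,
                  const arma::mat& W2, const arma::vec& b2, double slope) {
  arma::mat Z1 = X * W1;
  Z1.each_row() += b1.t();
  arma::mat G1 = lrelu_factor(Z1, slope);
  arma::mat T1 = Z1 % G1;
  arma::mat Z2 = T1 * W2;
  Z2.each_row() += b2.t();
  arma::mat G2 = lrelu_factor(Z2, slope);
  arma::mat out = X + Z2 % G2;
  return List::create(_["out"] = out, _["G1"] = G1, _["T1"] = T1,
                      _["G2"] = G2);
}

// [[Rcpp::export(name = ".resblock_bwd")]]
List resblock_bwd(const arma::mat& X, const arma::mat& G1, const arma::mat& T1,
                  const arma::mat& G2, const arma::mat& W1,
                  const arma::mat& W2, const arma::mat& dOut) {
  arma::mat dZ2 = dOut % G2;
  arma::mat dW2 = T1.t() * dZ2;
  arma::rowvec db2 = arma::sum(dZ2, 0);
  arma::mat dZ1 = (dZ2 * W2.t()) % G1;
  arma::mat dW1 = X.t() * dZ1;
  arma::rowvec db1 = arma::sum(dZ1, 0);
  arma::mat dX = dOut + dZ1 * W1.t();
  return List::create(_["dW1"] = dW1, _["db1"] = db1, _["dW2"] = dW2,
                      _["db2"] = db2, _["dX"] = dX);
}
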