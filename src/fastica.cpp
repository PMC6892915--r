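// Symmetric (parallel) FastICA updates with the logcosh contrast.
// Operates on pre-whitened data Z (components x observations, Z Z^T / n = I);
// whitening is done once in R and shared across random restarts.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// symmetric decorrelation: W <- (W W^T)^{-1/2} W
static mat sym_decorrelate(const mat& w) {
  vec eigval;
  mat eigvec;
  eig_sym(eigval, eigvec, w * w.t());
  eigval = clamp(eigval, 1e-300, datum::inf);
  return eigvec * diagmat(1.0 / sqrt(eigval)) * eigvec.t() * w;
}

// [[Rcpp::export]]
Rcpp::List fastica_sym_core(const arma::mat& z, const arma::mat& w0,
                            double tol, int max_iter, double alpha) {
  const double n = static_cast<double>(z.n_cols);
  const mat zt = z.t();
  mat w = sym_decorrelate(w0);
  double lim = datum::inf;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    mat gwx = tanh(alpha * (w * z));
    vec gprime_mean = alpha * (1.0 - mean(square(gwx), 1));
    mat w1 = (gwx * zt) / n - diagmat(gprime_mean) * w;
    w1 = sym_decorrelate(w1);
    lim = abs(abs(diagvec(w1 * w.t())) - 1.0).max();
    w = w1;
    if (lim < tol) { ++iter; break; }
  }
  return Rcpp::List::create(Rcpp::Named("W") = w,
                            Rcpp::Named("iter") = iter,
                            Rcpp::Named("converged") = lim < tol,
                            Rcpp::Named("lim") = lim);
}
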