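#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Multiplicative updates minimizing ||V - W S H||_F^2 with W, H >= 0 and S
// (the nonsmooth mixing matrix) held fixed. The standard Lee-Seung Frobenius
// updates are applied with W*S taken as the basis when updating H and S*H as
// the coefficient matrix when updating W, so each half-step is non-increasing
// in the objective. eps guards the denominators only; numerators are exact so
// a zero entry stays zero (the sparsity nsNMF is after).
// [[Rcpp::export]]
Rcpp::List nsnmf_update_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                            const arma::mat& S, int max_iter, double tol) {
  const double eps = 1e-12;
  std::vector<double> trace;
  trace.reserve(64);
  double rss = datum::inf;
  int it;
  for (it = 0; it < max_iter; ++it) {
    mat A = W * S;                                   // p x k
    H %= (A.t() * V) / (A.t() * A * H + eps);        // k x n
    mat B = S * H;                                   // k x n
    W %= (V * B.t()) / (W * (B * B.t()) + eps);      // p x k
    double rss_new = accu(square(V - W * S * H));
    trace.push_back(rss_new);
    if (it > 0 && std::fabs(rss - rss_new) <= tol * std::max(rss, eps)) {
      rss = rss_new;
      ++it;
      break;
    }
    rss = rss_new;
  }
  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("H") = H,
                            Rcpp::Named("rss") = rss,
                            Rcpp::Named("rss_trace") = trace,
                            Rcpp::Named("iterations") = it);
}

// Nonnegative least-squares projection of columns of Vnew onto the fixed
// basis A (= W*S): multiplicative updates on H only.
// [[Rcpp::export]]
arma::mat nnls_project_cpp(const arma::mat& A, const arma::mat& Vnew,
                           int max_iter, double tol) {
  const double eps = 1e-12;
  mat H(A.n_cols, Vnew.n_cols, fill::ones);
  mat AtA = A.t() * A;
  mat AtV = A.t() * Vnew;
  double obj = datum::inf;
  for (int it = 0; it < max_iter; ++it) {
    H %= AtV / (AtA * H + eps);
    double obj_new = accu(square(Vnew - A * H));
    if (it > 0 && std::fabs(obj - obj_new) <= tol * std::max(obj, eps)) break;
    obj = obj_new;
  }
  return H;
}
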