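// Lawson-Hanson active-set non-negative least squares.
// Minimizes ||A x - b||_2 subject to x >= 0.  This is the only constraint
// used by the distribution inversion (besides the analysis-range box that
// is enforced at candidate-drawing time): no smoothness regularization.

#include <RcppArmadillo.h>

// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
Rcpp::List nnls_cpp(const arma::mat& A, const arma::vec& b,
                    int max_iter = -1) {
  const arma::uword m = A.n_rows, n = A.n_cols;
  if (b.n_elem != m) Rcpp::stop("dimension mismatch between A and b");
  if (max_iter < 0) max_iter = 3 * static_cast<int>(n) + 30;

  arma::vec x(n, arma::fill::zeros);
  std::vector<bool> passive(n, false);
  arma::vec resid = b;
  // Gradient tolerance scaled to the problem.
  const double tol = 10.0 * std::numeric_limits<double>::epsilon() *
                     arma::norm(A, 1) * static_cast<double>(m);

  auto passive_idx = [&]() {
    std::vector<arma::uword> idx;
    for (arma::uword j = 0; j < n; ++j) if (passive[j]) idx.push_back(j);
    return arma::uvec(idx);
  };

  int outer = 0;
  while (outer++ < max_iter) {
    arma::vec w = A.t() * resid;
    // Most negative-gradient free variable.
    double wmax = tol;
    int jstar = -1;
    for (arma::uword j = 0; j < n; ++j) {
      if (!passive[j] && w(j) > wmax) { wmax = w(j); jstar = static_cast<int>(j); }
    }
    if (jstar < 0) break;
    passive[static_cast<arma::uword>(jstar)] = true;

    int inner = 0;
    while (inner++ < max_iter) {
      arma::uvec P = passive_idx();
      arma::vec z;
      bool ok = arma::solve(z, A.cols(P), b,
                            arma::solve_opts::fast + arma::solve_opts::no_approx);
      if (!ok) {
        // Fall back to a least-squares (minimum-norm) solution.
        z = arma::pinv(A.cols(P)) * b;
      }
      if (z.min() > 0) {
        x.zeros();
        x.elem(P) = z;
        break;
      }
      // Step back along the segment x -> z until a variable hits zero.
      double alpha = arma::datum::inf;
      for (arma::uword k = 0; k < P.n_elem; ++k) {
        if (z(k) <= 0) {
          double xk = x(P(k));
          double a = xk / (xk - z(k));
          if (a < alpha) alpha = a;
        }
      }
      for (arma::uword k = 0; k < P.n_elem; ++k) {
        double xnew = x(P(k)) + alpha * (z(k) - x(P(k)));
        x(P(k)) = xnew;
      }
      for (arma::uword k = 0; k < P.n_elem; ++k) {
        if (x(P(k)) <= tol) { x(P(k)) = 0.0; passive[P(k)] = false; }
      }
    }
    resid = b - A * x;
  }

  return Rcpp::List::create(
    Rcpp::Named("x") = x,
    Rcpp::Named("rnorm") = arma::norm(b - A * x, 2));
}
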