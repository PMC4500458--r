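#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Dual of the constrained entropy maximization: given features T (S x m),
// constraint vector b and prior q, maximize
//   g(lambda) = b'lambda - log( sum_i q_i exp(t_i'lambda) )
// whose stationary point gives p_i = q_i exp(t_i'lambda) / Z with T'p = b.
// Damped Newton with backtracking line search; convergence is declared when
// the largest change in any single predicted relative abundance between two
// iterations falls below `tol` (the criterion used for iterative scaling in
// the CATS literature), so that boundary-constraint problems -- where the
// dual optimum is at infinity but p converges -- terminate cleanly.

static arma::vec softmax_p(const arma::mat& T, const arma::vec& lambda,
                           const arma::vec& logq) {
  arma::vec eta = logq + T * lambda;
  eta -= eta.max();
  arma::vec p = arma::exp(eta);
  return p / arma::accu(p);
}

static double dual_obj(const arma::mat& T, const arma::vec& lambda,
                       const arma::vec& logq, const arma::vec& b) {
  arma::vec eta = logq + T * lambda;
  double mx = eta.max();
  return arma::dot(b, lambda) - (mx + std::log(arma::accu(arma::exp(eta - mx))));
}

// [[Rcpp::export(name = ".maxent_dual_cpp")]]
List maxent_dual_cpp(const arma::mat& T, const arma::vec& b, const arma::vec& q,
                     double tol = 1e-7, int max_iter = 100000,
                     double lambda_cap = 1e3) {
  const int m = T.n_cols;
  arma::vec logq = arma::log(q);
  arma::vec lambda(m, arma::fill::zeros);
  arma::vec p = softmax_p(T, lambda, logq);

  bool converged = (m == 0);
  double max_step = 0.0;
  int it = 0;
  bool capped = false;

  for (it = 0; it < max_iter && m > 0; ++it) {
    arma::vec mu = T.t() * p;            // achieved constraints
    arma::vec grad = b - mu;
    // Hessian of -g: covariance of features under p
    arma::mat H = T.t() * (T.each_col() % p) - mu * mu.t();
    H.diag() += 1e-12 + 1e-10 * arma::trace(H) / m;
    arma::vec step;
    bool ok = arma::solve(step, H, grad, arma::solve_opts::likely_sympd +
                                          arma::solve_opts::no_approx);
    if (!ok || !step.is_finite()) step = grad;  // gradient ascent fallback

    // backtracking line search on the dual objective
    double g0 = dual_obj(T, lambda, logq, b);
    double alpha = 1.0;
    arma::vec lam_new = lambda + step;
    for (int ls = 0; ls < 60; ++ls) {
      lam_new = lambda + alpha * step;
      if (lam_new.is_finite() &&
          dual_obj(T, lam_new, logq, b) >= g0 - 1e-14) break;
      alpha *= 0.5;
    }
    // cap multipliers to keep boundary problems finite
    capped = false;
    for (int j = 0; j < m; ++j) {
      if (lam_new(j) > lambda_cap)  { lam_new(j) = lambda_cap;  capped = true; }
      if (lam_new(j) < -lambda_cap) { lam_new(j) = -lambda_cap; capped = true; }
    }
    arma::vec p_new = softmax_p(T, lam_new, logq);
    max_step = arma::abs(p_new - p).max();
    lambda = lam_new;
    p = p_new;
    if (max_step < tol) {
      converged = !capped;
      ++it;
      break;
    }
    if (capped) { converged = false; }
  }

  arma::vec resid = (m > 0) ? arma::vec(T.t() * p - b) : arma::vec();
  return List::create(_["p_hat"] = p, _["lambda"] = lambda,
                      _["iterations"] = it, _["converged"] = converged,
                      _["max_step"] = max_step,
                      _["constraint_residual"] = resid);
}

// Solve one maxent problem per row of B (plots x m), shared features/prior.
// [[Rcpp::export(name = ".maxent_dual_batch_cpp")]]
List maxent_dual_batch_cpp(const arma::mat& T, const arma::mat& B,
                           const arma::vec& q, double tol = 1e-7,
                           int max_iter = 100000, double lambda_cap = 1e3) {
  const int P = B.n_rows;
  arma::mat Phat(P, T.n_rows), Lam(P, T.n_cols);
  IntegerVector iters(P);
  LogicalVector conv(P);
  NumericVector steps(P);
  for (int k = 0; k < P; ++k) {
    List r = maxent_dual_cpp(T, B.row(k).t(), q, tol, max_iter, lambda_cap);
    Phat.row(k) = as<arma::vec>(r["p_hat"]).t();
    Lam.row(k) = as<arma::vec>(r["lambda"]).t();
    iters[k] = r["iterations"];
    conv[k] = r["converged"];
    steps[k] = r["max_step"];
  }
  return List::create(_["p_hat"] = Phat, _["lambda"] = Lam,
                      _["iterations"] = iters, _["converged"] = conv,
                      _["max_step"] = steps);
}
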