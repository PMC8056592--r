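#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Observed-data Gaussian log-likelihood of the factor model
// Sigma = W W' + diag(psi), evaluated through the Woodbury identity so the
// p x p covariance is never formed (q is small, p can be large).
static double obs_loglik(const arma::mat& X, const arma::mat& W,
                         const arma::vec& psi) {
  const double n = (double) X.n_cols;
  const double p = (double) X.n_rows;
  const arma::uword q = W.n_cols;

  arma::mat Wp = W;
  Wp.each_col() /= psi;                                  // Psi^{-1} W
  arma::mat M = arma::eye(q, q) + W.t() * Wp;            // I + W'Psi^{-1}W
  arma::mat Minv = arma::inv_sympd(M);
  arma::mat U = Wp.t() * X;                              // q x n

  arma::mat X2 = arma::square(X);
  X2.each_col() /= psi;
  double quad = arma::accu(X2) - arma::accu(U % (Minv * U));

  double ldetM, sign;
  arma::log_det(ldetM, sign, M);
  double logdet_sigma = arma::accu(arma::log(psi)) + ldetM;

  return -0.5 * (n * p * std::log(2.0 * M_PI) + n * logdet_sigma + quad);
}

static arma::mat soft_threshold_mat(const arma::mat& W, double lambda) {
  arma::mat sh = arma::abs(W) - lambda;
  sh.elem(arma::find(sh < 0.0)).zeros();
  return arma::sign(W) % sh;
}

// EM for X = W Z + eps, Z ~ N(0, I_q), eps ~ N(0, diag(psi)).
// After each M-step the loadings are soft-thresholded elementwise by lambda.
// Convergence: lambda == 0 -> relative log-likelihood change < tol (trace is
// the log-likelihood); lambda > 0 -> max |delta W| < tol (trace is that max,
// since thresholding breaks likelihood monotonicity).
// [[Rcpp::export]]
List em_loop_cpp(const arma::mat& X, arma::mat W, arma::vec psi,
                 double lambda, int max_iter, double tol, double psi_floor) {
  const double n = (double) X.n_cols;
  const arma::uword q = W.n_cols;

  arma::vec s2 = arma::mean(arma::square(X), 1);   // per-feature 2nd moment
  std::vector<double> trace;
  trace.reserve(max_iter > 0 ? max_iter : 1);
  bool converged = false;
  double prev_ll = 0.0;
  int done = 0;

  arma::mat EZ, VarZ;

  for (int iter = 1; iter <= max_iter; ++iter) {
    // E-step
    arma::mat Wp = W;
    Wp.each_col() /= psi;
    arma::mat M = arma::eye(q, q) + W.t() * Wp;
    VarZ = arma::inv_sympd(M);
    EZ = VarZ * (Wp.t() * X);                       // q x n

    // M-step
    arma::mat A = n * VarZ + EZ * EZ.t();           // q x q, SPD
    arma::mat XEZt = X * EZ.t();                    // p x q
    arma::mat Wnew = arma::solve(A, XEZt.t(),
                                 arma::solve_opts::likely_sympd).t();
    arma::vec psin = s2 - arma::sum(Wnew % XEZt, 1) / n;
    psin = arma::clamp(psin, psi_floor, arma::datum::inf);

    if (lambda > 0.0) Wnew = soft_threshold_mat(Wnew, lambda);

    double delta_w = arma::abs(Wnew - W).max();
    W = Wnew;
    psi = psin;
    done = iter;

    if (lambda > 0.0) {
      trace.push_back(delta_w);
      if (delta_w < tol) { converged = true; break; }
    } else {
      double ll = obs_loglik(X, W, psi);
      trace.push_back(ll);
      if (iter > 1 &&
          std::abs(ll - prev_ll) < tol * (std::abs(prev_ll) + 1e-8)) {
        converged = true;
        prev_ll = ll;
        break;
      }
      prev_ll = ll;
    }
  }

  // posterior at the final parameter values (used for cluster assignment)
  {
    arma::mat Wp = W;
    Wp.each_col() /= psi;
    arma::mat M = arma::eye(q, q) + W.t() * Wp;
    VarZ = arma::inv_sympd(M);
    EZ = VarZ * (Wp.t() * X);
  }

  return List::create(_["W"] = W, _["psi"] = psi, _["EZ"] = EZ,
                      _["VarZ"] = VarZ, _["trace"] = trace,
                      _["converged"] = converged, _["n_iter"] = done);
}
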