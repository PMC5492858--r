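// EM inner loop for full-covariance Gaussian mixtures.
// The outer convergence logic, initialization and all user-facing
// validation live in R (R/gmm.R); this file only carries the per-iteration
// E-step / M-step arithmetic, which dominates training time.
//
// Both steps are organised as two large matrix products per iteration
// (X * [rooti_1 .. rooti_M] and X' * [r_1 % X .. r_M % X]) instead of M
// small per-component products, which keeps the BLAS efficient at d = 13.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Log densities of all rows of X under each of M Gaussian components.
// means: M x d; covs: d x d x M. Returns R x M matrix of log N(x; mu_k, S_k).
// [[Rcpp::export(name = ".gmm_logdens_cpp")]]
arma::mat gmm_logdens_cpp(const arma::mat& X, const arma::mat& means,
                          const arma::cube& covs) {
  const arma::uword R = X.n_rows, d = X.n_cols, M = means.n_rows;
  const double cst = -0.5 * d * std::log(2.0 * M_PI);
  arma::mat L(R, M);
  for (arma::uword k = 0; k < M; ++k) {
    arma::mat ch;
    if (!arma::chol(ch, covs.slice(k)))
      stop("covariance of component %d is not positive definite", (int)(k + 1));
    const double logdet = 2.0 * arma::accu(arma::log(ch.diag()));
    const arma::mat rooti = arma::inv(arma::trimatu(ch));
    arma::mat Z = X.each_row() - means.row(k);
    Z = Z * rooti;
    L.col(k) = cst - 0.5 * (logdet + arma::sum(Z % Z, 1));
  }
  return L;
}

// One full EM run iterated until convergence. Returns final parameters and
// the log-likelihood recorded at every E-step (before the matching M-step),
// which is the sequence the EM ascent guarantee applies to.
// [[Rcpp::export(name = ".gmm_em_cpp")]]
List gmm_em_cpp(const arma::mat& X, arma::mat means, arma::cube covs,
                arma::vec weights, const double tol, const int max_iter,
                const double reg) {
  const arma::uword R = X.n_rows, d = X.n_cols, M = means.n_rows;
  const double cst = -0.5 * d * std::log(2.0 * M_PI);
  const arma::mat regI = reg * arma::eye<arma::mat>(d, d);
  std::vector<double> trace;
  trace.reserve(max_iter);
  double ll_old = -arma::datum::inf;
  bool converged = false;

  arma::mat rooti_all(d, d * M);   // horizontally stacked inverse roots
  arma::rowvec offs(M);            // log w_k + cst - logdet_k / 2
  arma::mat mu_z(M, d);            // mu_k * rooti_k, row per component
  arma::mat ZX(R, d * M), L(R, M), Y(R, d * M);

  for (int it = 0; it < max_iter; ++it) {
    // Factorize every covariance once per iteration.
    for (arma::uword k = 0; k < M; ++k) {
      arma::mat ch;
      if (!arma::chol(ch, covs.slice(k)))
        stop("covariance collapse in component %d during EM", (int)(k + 1));
      rooti_all.cols(k * d, k * d + d - 1) = arma::inv(arma::trimatu(ch));
      offs(k) = std::log(weights(k)) + cst - arma::accu(arma::log(ch.diag()));
      mu_z.row(k) = means.row(k) * rooti_all.cols(k * d, k * d + d - 1);
    }
    // E-step: (x - mu)' S^-1 (x - mu) = || x rooti - mu rooti ||^2, expanded
    // so the stacked product X * rooti_all is computed once per iteration.
    ZX = X * rooti_all;
    for (arma::uword k = 0; k < M; ++k) {
      const auto Zk = ZX.cols(k * d, k * d + d - 1);
      L.col(k) = (offs(k) - 0.5 * arma::dot(mu_z.row(k), mu_z.row(k))) -
        0.5 * arma::sum(Zk % Zk, 1) + Zk * mu_z.row(k).t();
    }
    const arma::vec mx = arma::max(L, 1);
    const arma::vec lse = mx + arma::log(arma::sum(arma::exp(L.each_col() - mx), 1));
    const double ll = arma::accu(lse);
    trace.push_back(ll);
    if (std::isfinite(ll_old) && (ll - ll_old) < tol * std::abs(ll_old)) {
      converged = true;
      break;
    }
    ll_old = ll;

    arma::mat resp = arma::exp(L.each_col() - lse);
    arma::rowvec Nk = arma::sum(resp, 0);
    // Components starved of responsibility are reseeded at the point the
    // current mixture explains worst, mirroring the k-means empty-cluster rule.
    for (arma::uword k = 0; k < M; ++k) {
      if (Nk(k) < 1e-8 * R) {
        arma::uword far = lse.index_min();
        resp.row(far).zeros();
        resp(far, k) = 1.0;
        Nk = arma::sum(resp, 0);
      }
    }
    // M-step via non-centered sufficient statistics:
    // S_k = X' diag(r_k) X / N_k - mu_k' mu_k, batched as one product.
    weights = (Nk / (double)R).t();
    means = resp.t() * X;
    means.each_col() /= Nk.t();
    for (arma::uword k = 0; k < M; ++k)
      Y.cols(k * d, k * d + d - 1) = X.each_col() % resp.col(k);
    const arma::mat G = X.t() * Y;               // d x dM, one product
    for (arma::uword k = 0; k < M; ++k)
      covs.slice(k) = G.cols(k * d, k * d + d - 1) / Nk(k) -
        means.row(k).t() * means.row(k) + regI;
  }

  return List::create(
    _["weights"] = weights, _["means"] = means, _["covs"] = covs,
    _["loglik_trace"] = trace, _["n_iter"] = (int)trace.size(),
    _["converged"] = converged);
}
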