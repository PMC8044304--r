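// EM for a full-covariance Gaussian mixture. The E-step works in log
// space (log-sum-exp) for numerical stability; each M-step adds `reg` to
// the covariance diagonals, which also guards against component collapse.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// log N(x | mu, Sigma) for all rows of X, via Cholesky
static vec dmvnorm_log(const mat& X, const rowvec& mu, const mat& Sigma) {
  const uword d = X.n_cols;
  mat L;
  mat S = Sigma;
  double jitter = 0.0;
  while (!chol(L, S, "lower")) {
    jitter = (jitter == 0.0) ? 1e-10 : jitter * 10.0;
    S = Sigma + jitter * eye(d, d);
    if (jitter > 1e2) Rcpp::stop("covariance not factorizable");
  }
  double logdet = 2.0 * sum(log(L.diag()));
  mat diff = X.each_row() - mu;           // n x d
  mat sol = solve(trimatl(L), diff.t());  // d x n
  vec quad = sum(square(sol), 0).t();
  return -0.5 * (d * std::log(2.0 * M_PI) + logdet + quad);
}

// resp0: n x K initial responsibilities (e.g. one-hot from a k-means
// partition); the algorithm starts with an M-step on them.
// [[Rcpp::export(name = ".gmm_em_cpp")]]
Rcpp::List gmm_em_cpp(const arma::mat& X, const arma::mat& resp0,
                      double tol, double reg, int max_iter) {
  const uword n = X.n_rows, d = X.n_cols, K = resp0.n_cols;

  rowvec w(K);
  mat means(K, d);
  cube covs(d, d, K);
  mat logp(n, K);
  mat resp = resp0;
  std::vector<double> ll_trace;
  double ll_old = -datum::inf, ll = -datum::inf;
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    // M-step (first pass uses the initial responsibilities)
    rowvec nk = sum(resp, 0);
    nk = clamp(nk, 1e-10, datum::inf);
    w = nk / n;
    for (uword k = 0; k < K; ++k) {
      rowvec mu = (resp.col(k).t() * X) / nk(k);
      means.row(k) = mu;
      mat diff = X.each_row() - mu;
      mat wd = diff.each_col() % resp.col(k);
      mat S = (wd.t() * diff) / nk(k);
      S.diag() += reg;
      covs.slice(k) = 0.5 * (S + S.t());
    }

    // E-step
    for (uword k = 0; k < K; ++k) {
      logp.col(k) = dmvnorm_log(X, means.row(k), covs.slice(k)) +
                    std::log(std::max(w(k), 1e-300));
    }
    vec m = max(logp, 1);
    mat shifted = exp(logp.each_col() - m);
    vec rowsum = sum(shifted, 1);
    resp = shifted.each_col() / rowsum;
    ll = accu(m + log(rowsum));
    if (!std::isfinite(ll)) Rcpp::stop("non-finite log-likelihood at iteration %d", iter + 1);
    ll_trace.push_back(ll);
    if (iter > 0) {
      double rel = std::fabs(ll - ll_old) /
                   std::max(std::fabs(ll_old), 1e-12);
      if (rel < tol) { converged = true; break; }
    }
    ll_old = ll;
  }

  return Rcpp::List::create(
    Rcpp::Named("weights") = w.t(),
    Rcpp::Named("means") = means,
    Rcpp::Named("covariances") = covs,
    Rcpp::Named("log_likelihood") = ll,
    Rcpp::Named("responsibilities") = resp,
    Rcpp::Named("ll_trace") = ll_trace,
    Rcpp::Named("n_iter") = iter + 1,
    Rcpp::Named("converged") = converged);
}
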