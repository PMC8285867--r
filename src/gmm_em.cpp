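// EM for finite Gaussian mixtures under six covariance constraints.
// The R wrapper (fit_gmm) owns initialization, restarts and the user
// interface; this routine is the numerical core.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// model codes: 0 EII, 1 VII, 2 EEI, 3 VVI, 4 EEE, 5 VVV

static void mstep(const mat& X, const mat& resp, int model,
                  double floor_eig, vec& pi, mat& mu, cube& sigma,
                  vec& nk) {
  const uword n = X.n_rows, d = X.n_cols, K = resp.n_cols;
  nk = sum(resp, 0).t();
  nk = clamp(nk, 1e-300, datum::inf);
  pi = nk / (double) n;
  mu = resp.t() * X;
  mu.each_col() /= nk;

  if (model >= 4) { // full covariance
    cube W(d, d, K);
    for (uword k = 0; k < K; ++k) {
      mat Xc = X;
      Xc.each_row() -= mu.row(k);
      W.slice(k) = Xc.t() * (Xc.each_col() % resp.col(k));
    }
    if (model == 4) { // EEE: pooled
      mat S(d, d, fill::zeros);
      for (uword k = 0; k < K; ++k) S += W.slice(k);
      S /= (double) n;
      S.diag() += floor_eig;
      for (uword k = 0; k < K; ++k) sigma.slice(k) = S;
    } else { // VVV
      for (uword k = 0; k < K; ++k) {
        mat S = W.slice(k) / nk(k);
        S.diag() += floor_eig;
        sigma.slice(k) = S;
      }
    }
  } else { // diagonal / spherical
    mat Wd(K, d);
    for (uword k = 0; k < K; ++k) {
      mat Xc = X;
      Xc.each_row() -= mu.row(k);
      mat sq = square(Xc);
      sq.each_col() %= resp.col(k);
      Wd.row(k) = sum(sq, 0);
    }
    mat lam(K, d);
    if (model == 0) {        // EII
      lam.fill(accu(Wd) / (double)(n * d));
    } else if (model == 1) { // VII
      vec v = sum(Wd, 1) / (nk * (double) d);
      for (uword k = 0; k < K; ++k) lam.row(k).fill(v(k));
    } else if (model == 2) { // EEI
      rowvec v = sum(Wd, 0) / (double) n;
      lam.each_row() = v;
    } else {                 // VVI
      lam = Wd.each_col() / nk;
    }
    lam = clamp(lam, floor_eig, datum::inf);
    for (uword k = 0; k < K; ++k) {
      sigma.slice(k) = diagmat(lam.row(k));
    }
  }
}

// log densities + responsibilities; returns loglik
static double estep(const mat& X, const vec& pi, const mat& mu,
                    const cube& sigma, mat& resp) {
  const uword n = X.n_rows, d = X.n_cols, K = pi.n_elem;
  mat logdens(n, K);
  const double c0 = d * std::log(2.0 * datum::pi);
  for (uword k = 0; k < K; ++k) {
    mat R;
    bool ok = chol(R, sigma.slice(k));
    if (!ok) {
      mat S = sigma.slice(k);
      S.diag() += 1e-8 * trace(S) / d + 1e-12;
      R = chol(S);
    }
    double logdet = 2.0 * accu(log(R.diag()));
    mat Xc = X;
    Xc.each_row() -= mu.row(k);
    mat Z = solve(trimatl(R.t()), Xc.t());
    rowvec quad = sum(square(Z), 0);
    logdens.col(k) = -0.5 * (c0 + logdet + quad.t()) + std::log(pi(k));
  }
  vec mx = max(logdens, 1);
  logdens.each_col() -= mx;
  vec se = sum(exp(logdens), 1);
  resp = exp(logdens);
  resp.each_col() /= se;
  return accu(mx + log(se));
}

// [[Rcpp::export(name = ".em_fit_cpp")]]
Rcpp::List em_fit_cpp(const arma::mat& X, const arma::mat& resp0,
                      int model, double tol, int max_iter,
                      double floor_eig) {
  const uword n = X.n_rows, K = resp0.n_cols, d = X.n_cols;
  mat resp = resp0;
  vec pi(K), nk(K);
  mat mu(K, d);
  cube sigma(d, d, K);
  std::vector<double> trace_ll;
  double ll_old = -datum::inf;
  bool converged = false, collapsed = false;
  int iter = 0;
  const double collapse_thresh = 1.0 / (10.0 * n);
  for (iter = 1; iter <= max_iter; ++iter) {
    mstep(X, resp, model, floor_eig, pi, mu, sigma, nk);
    if (pi.min() < collapse_thresh) { collapsed = true; break; }
    double ll = estep(X, pi, mu, sigma, resp);
    trace_ll.push_back(ll);
    if (std::isfinite(ll_old) &&
        std::abs(ll - ll_old) < tol * (1.0 + std::abs(ll))) {
      converged = true;
      ll_old = ll;
      break;
    }
    ll_old = ll;
  }
  if (trace_ll.empty()) { // collapsed on the first M-step
    trace_ll.push_back(-datum::inf);
    ll_old = -datum::inf;
  }
  return Rcpp::List::create(
    Rcpp::Named("pi") = pi, Rcpp::Named("mu") = mu,
    Rcpp::Named("sigma") = sigma,
    Rcpp::Named("loglik") = ll_old,
    Rcpp::Named("loglik_trace") = trace_ll,
    Rcpp::Named("resp") = resp,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("collapsed") = collapsed,
    Rcpp::Named("n_iter") = iter);
}
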