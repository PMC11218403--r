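// Blocked Gibbs sampler for the spatiotemporally varying coefficients model
//   log y[i,t] = sum_k (beta_k + mu[i,k] + gamma[t,k]) X[i,t,k] + eps[i,t]
// with intrinsic-CAR priors on the space-coefficient fields mu[,k] (sum-to-
// zero), RW2 priors on the time-coefficient paths gamma[,k] (sum-to-zero,
// slope free), flat priors on the global coefficients beta, and conjugate
// inverse-gamma priors on the variance components.
//
// Each mu/gamma full conditional is sampled jointly via a precomputed
// spectral decomposition: with A the (fixed, diagonal) likelihood precision
// pattern and Q the structure matrix, B = A^{-1/2} Q A^{-1/2} = V L V', so
// the posterior precision  Q/s2q + A/s2e = A^{1/2} V (L/s2q + I/s2e) V' A^{1/2}
// is diagonalized once; every draw then costs a few dense mat-vecs. The
// sum-to-zero constraint is imposed exactly by conditioning-by-kriging.
//
// Uses R's RNG throughout so results are reproducible via set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static vec rnorm_vec(int n) {
  vec z(n);
  for (int i = 0; i < n; ++i) z[i] = R::norm_rand();
  return z;
}

// draw from N(m, P^{-1}) with P = Q/s2q + A/s2e, constrained to sum(x) = 0,
// using the spectral pieces described above. b is the likelihood linear term.
static vec sample_block(const vec& b, const mat& V, const vec& lam,
                        const vec& ainv_sqrt, const vec& w,
                        double s2q, double s2e) {
  vec d = lam / s2q + 1.0 / s2e;          // posterior spectrum
  vec bt = V.t() * (ainv_sqrt % b);       // transform linear term
  vec m = bt / d;
  vec x = ainv_sqrt % (V * (m + rnorm_vec(b.n_elem) / sqrt(d)));
  // conditioning by kriging onto the sum-to-zero subspace
  vec c = ainv_sqrt % (V * (w / d));      // P^{-1} 1
  double denom = dot(w, w / d);           // 1' P^{-1} 1
  x -= c * (accu(x) / denom);
  return x;
}

// [[Rcpp::export]]
Rcpp::List stvc_gibbs_chain(
    const arma::mat& z, const arma::cube& X,
    const arma::cube& Vs, const arma::mat& lam_s, const arma::mat& ainv_s,
    const arma::mat& w_s,
    const arma::cube& Vt, const arma::mat& lam_t, const arma::mat& ainv_t,
    const arma::mat& w_t,
    const arma::mat& Qs, const arma::mat& Rt,
    int rank_s, int rank_t,
    double prior_a, double prior_b,
    bool include_global,
    int n_iter, int burn_in, int thin,
    const arma::vec& beta_init, const arma::vec& s_mu_init,
    const arma::vec& s_ga_init,
    double s_eps_init, bool fix_variances) {

  const int N = z.n_rows, T = z.n_cols, K = X.n_slices;
  const int NT = N * T;

  vec beta = beta_init;
  mat mu(N, K, fill::zeros);
  mat ga(T, K, fill::zeros);
  vec s2_mu = square(s_mu_init);
  vec s2_ga = square(s_ga_init);
  double s2_eps = s_eps_init * s_eps_init;

  // residual r = z - eta under current state (mu, ga start at zero)
  mat r = z;
  for (int k = 0; k < K; ++k) r -= beta[k] * X.slice(k);

  // fixed K x K cross-product for the beta block
  mat XtX(K, K, fill::zeros);
  for (int k = 0; k < K; ++k)
    for (int l = k; l < K; ++l) {
      XtX(k, l) = accu(X.slice(k) % X.slice(l));
      XtX(l, k) = XtX(k, l);
    }

  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  mat beta_draws(n_keep, K, fill::zeros);
  cube mu_draws(N, K, n_keep);
  cube ga_draws(T, K, n_keep);
  mat s_mu_draws(n_keep, K);
  mat s_ga_draws(n_keep, K);
  vec s_eps_draws(n_keep);
  mat eta_mean(N, T, fill::zeros);

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    // --- space-coefficient fields ---
    for (int k = 0; k < K; ++k) {
      r += X.slice(k).each_col() % mu.col(k);       // add block back
      vec b = (X.slice(k) % r) * ones<vec>(T) / s2_eps;
      mu.col(k) = sample_block(b, Vs.slice(k), lam_s.col(k), ainv_s.col(k),
                               w_s.col(k), s2_mu[k], s2_eps);
      r -= X.slice(k).each_col() % mu.col(k);
    }
    // --- time-coefficient paths ---
    for (int k = 0; k < K; ++k) {
      r += X.slice(k).each_row() % ga.col(k).t();
      vec b = (X.slice(k) % r).t() * ones<vec>(N) / s2_eps;
      ga.col(k) = sample_block(b, Vt.slice(k), lam_t.col(k), ainv_t.col(k),
                               w_t.col(k), s2_ga[k], s2_eps);
      r -= X.slice(k).each_row() % ga.col(k).t();
    }
    // --- global coefficients (flat prior) ---
    if (include_global) {
      for (int k = 0; k < K; ++k) r += beta[k] * X.slice(k);
      vec bb(K);
      for (int k = 0; k < K; ++k) bb[k] = accu(X.slice(k) % r);
      mat P = XtX / s2_eps;
      mat L = chol(P, "lower");
      vec m = solve(trimatu(L.t()), solve(trimatl(L), bb / s2_eps));
      beta = m + solve(trimatu(L.t()), rnorm_vec(K));
      for (int k = 0; k < K; ++k) r -= beta[k] * X.slice(k);
    }
    // --- variance components (conjugate inverse gamma) ---
    if (!fix_variances) {
      for (int k = 0; k < K; ++k) {
        double qf = as_scalar(mu.col(k).t() * Qs * mu.col(k));
        s2_mu[k] = 1.0 / R::rgamma(prior_a + 0.5 * rank_s,
                                   1.0 / (prior_b + 0.5 * qf));
        double qg = as_scalar(ga.col(k).t() * Rt * ga.col(k));
        s2_ga[k] = 1.0 / R::rgamma(prior_a + 0.5 * rank_t,
                                   1.0 / (prior_b + 0.5 * qg));
      }
      s2_eps = 1.0 / R::rgamma(prior_a + 0.5 * NT,
                               1.0 / (prior_b + 0.5 * accu(r % r)));
    }
    // --- store ---
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      beta_draws.row(kept) = beta.t();
      mu_draws.slice(kept) = mu;
      ga_draws.slice(kept) = ga;
      s_mu_draws.row(kept) = sqrt(s2_mu).t();
      s_ga_draws.row(kept) = sqrt(s2_ga).t();
      s_eps_draws[kept] = std::sqrt(s2_eps);
      eta_mean += z - r;
      ++kept;
    }
  }
  eta_mean /= std::max(kept, 1);

  return Rcpp::List::create(
    Rcpp::Named("beta") = beta_draws,
    Rcpp::Named("mu") = mu_draws,
    Rcpp::Named("gamma") = ga_draws,
    Rcpp::Named("sd_mu") = s_mu_draws,
    Rcpp::Named("sd_gamma") = s_ga_draws,
    Rcpp::Named("sd_eps") = s_eps_draws,
    Rcpp::Named("eta_mean") = eta_mean,
    Rcpp::Named("n_keep") = kept);
}
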