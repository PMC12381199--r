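// Single-tree lambda-scaled PGLS sampler.
//
// Model: y ~ N(X beta, sigma2 * V(lambda)), V(lambda) = lambda * V with the
// diagonal of V restored. Priors: beta_j ~ N(0, prior_beta_sd^2) iid,
// lambda ~ U(0,1), sigma ~ half-Cauchy(sigma_prior_scale).
//
// Updates per iteration: Gibbs draw of beta from its conditional normal;
// random-walk Metropolis on log sigma2; random-walk Metropolis on lambda
// reflected at [0,1]. Proposal scales adapt during burn-in only. All
// randomness comes from R's RNG so set.seed() fixes the draw sequence.

#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::depends(RcppArmadillo)]]

namespace {

struct LamState {
  arma::mat Xt;    // L^{-1} X
  arma::vec yt;    // L^{-1} y
  double logdet;   // log |V(lambda)|
};

bool build_state(const arma::mat& V, const arma::vec& vdiag, double lam,
                 const arma::mat& X, const arma::vec& y, LamState& s) {
  arma::mat Vl = lam * V;
  Vl.diag() = vdiag;
  arma::mat L;
  if (!arma::chol(L, Vl, "lower")) return false;
  s.Xt = arma::solve(arma::trimatl(L), X);
  s.yt = arma::solve(arma::trimatl(L), y);
  s.logdet = 2.0 * arma::accu(arma::log(L.diag()));
  return true;
}

double loglik(const LamState& s, const arma::vec& beta, double sigma2, int n) {
  arma::vec r = s.yt - s.Xt * beta;
  return -0.5 * (n * std::log(2.0 * M_PI * sigma2) + s.logdet +
                 arma::dot(r, r) / sigma2);
}

// half-Cauchy prior on sigma expressed on u = log sigma2 (includes Jacobian)
double log_prior_u(double u, double scale) {
  return -std::log1p(std::exp(u) / (scale * scale)) + 0.5 * u;
}

arma::vec rnorm_vec(int p) {
  arma::vec z(p);
  for (int j = 0; j < p; ++j) z[j] = R::norm_rand();
  return z;
}

double reflect01(double x) {
  // reflect into [0, 1]
  while (x < 0.0 || x > 1.0) {
    if (x < 0.0) x = -x;
    if (x > 1.0) x = 2.0 - x;
  }
  return x;
}

} // namespace

// [[Rcpp::export(name = ".pgls_mcmc_chain")]]
List pgls_mcmc_chain(const arma::vec& y, const arma::mat& X, const arma::mat& V,
                     int iterations, int burn_in, int thinning,
                     double prior_beta_sd, double sigma_prior_scale,
                     double prop_lambda, double prop_log_sigma2,
                     bool lambda_is_fixed, double lambda_value,
                     bool sigma2_is_fixed, double sigma2_value) {
  const int n = y.n_elem, p = X.n_cols;
  const arma::vec vdiag = V.diag();
  const double prior_prec = 1.0 / (prior_beta_sd * prior_beta_sd);

  double lam = lambda_is_fixed ? lambda_value : 0.5;
  LamState st;
  if (!build_state(V, vdiag, lam, X, y, st)) {
    stop("phylogenetic covariance matrix is numerically singular; add jitter to "
         "branch lengths or check for duplicated tips");
  }

  // initialise beta at the ridge GLS estimate, sigma2 at the residual scale
  arma::mat A0 = st.Xt.t() * st.Xt + 1e-8 * arma::eye(p, p);
  arma::vec beta = arma::solve(A0, st.Xt.t() * st.yt);
  arma::vec r0 = st.yt - st.Xt * beta;
  double sigma2 = sigma2_is_fixed ? sigma2_value
                                  : std::max(arma::dot(r0, r0) / std::max(n - p, 1), 1e-10);
  double ll = loglik(st, beta, sigma2, n);
  if (!std::isfinite(ll)) {
    stop("non-finite likelihood at initialization");
  }

  const int n_keep = iterations / thinning;
  arma::mat beta_draws(n_keep, p);
  arma::vec sigma2_draws(n_keep), lambda_draws(n_keep);

  double s_lam = prop_lambda, s_sig = prop_log_sigma2;
  int acc_lam = 0, try_lam = 0, acc_sig = 0, try_sig = 0;       // post burn-in
  int win_acc_lam = 0, win_try_lam = 0, win_acc_sig = 0, win_try_sig = 0;
  const int adapt_window = 50;
  int kept = 0;

  const int total = burn_in + iterations;
  for (int it = 1; it <= total; ++it) {
    const bool adapting = it <= burn_in;

    // --- beta | sigma2, lambda: conjugate normal ---------------------------
    arma::mat A = st.Xt.t() * st.Xt / sigma2 + prior_prec * arma::eye(p, p);
    arma::vec b = st.Xt.t() * st.yt / sigma2;
    arma::mat Ra = arma::chol(A);              // upper
    arma::vec m = arma::solve(A, b);
    beta = m + arma::solve(arma::trimatu(Ra), rnorm_vec(p));
    ll = loglik(st, beta, sigma2, n);

    // --- sigma2: random-walk MH on log sigma2 ------------------------------
    if (!sigma2_is_fixed) {
      double u = std::log(sigma2);
      double u_new = u + s_sig * R::norm_rand();
      double s2_new = std::exp(u_new);
      double ll_new = loglik(st, beta, s2_new, n);
      double lr = (ll_new + log_prior_u(u_new, sigma_prior_scale)) -
                  (ll + log_prior_u(u, sigma_prior_scale));
      bool acc = std::isfinite(ll_new) && std::log(R::unif_rand()) < lr;
      if (acc) { sigma2 = s2_new; ll = ll_new; }
      if (adapting) {
        ++win_try_sig; win_acc_sig += acc;
        if (win_try_sig == adapt_window) {
          double rate = (double)win_acc_sig / win_try_sig;
          s_sig = std::min(10.0, std::max(1e-3, s_sig * std::exp(rate - 0.3)));
          win_try_sig = win_acc_sig = 0;
        }
      } else { ++try_sig; acc_sig += acc; }
    }

    // --- lambda: reflected random-walk MH ----------------------------------
    if (!lambda_is_fixed) {
      double lam_new = reflect01(lam + s_lam * R::norm_rand());
      LamState st_new;
      bool ok = build_state(V, vdiag, lam_new, X, y, st_new);
      bool acc = false;
      if (ok) {
        double ll_new = loglik(st_new, beta, sigma2, n);
        acc = std::isfinite(ll_new) && std::log(R::unif_rand()) < (ll_new - ll);
        if (acc) { lam = lam_new; st = st_new; ll = ll_new; }
      }
      if (adapting) {
        ++win_try_lam; win_acc_lam += acc;
        if (win_try_lam == adapt_window) {
          double rate = (double)win_acc_lam / win_try_lam;
          s_lam = std::min(2.0, std::max(1e-4, s_lam * std::exp(rate - 0.3)));
          win_try_lam = win_acc_lam = 0;
        }
      } else { ++try_lam; acc_lam += acc; }
    }

    if (!adapting && (it - burn_in) % thinning == 0) {
      beta_draws.row(kept) = beta.t();
      sigma2_draws[kept] = sigma2;
      lambda_draws[kept] = lam;
      ++kept;
    }
    if (it % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["beta"] = beta_draws,
    _["sigma2"] = sigma2_draws,
    _["lambda"] = lambda_draws,
    _["accept_lambda"] = try_lam > 0 ? (double)acc_lam / try_lam : NA_REAL,
    _["accept_sigma2"] = try_sig > 0 ? (double)acc_sig / try_sig : NA_REAL,
    _["proposal_lambda"] = s_lam,
    _["proposal_log_sigma2"] = s_sig
  );
}
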