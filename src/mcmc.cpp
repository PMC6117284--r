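// Adaptive random-walk Metropolis sampler for the per-node mixing model.
//
// Parameterisation: source proportions per factor level live on the
// K-simplex and are sampled in isometric log-ratio (ILR) coordinates
// (K-1 unconstrained reals per level); residual SDs tau_j are sampled on
// the log scale. Source means/SDs are refreshed each iteration from their
// closed-form normal/scaled-inverse-chi^2 posteriors given the source
// samples alone, which propagates source uncertainty without joint
// updating. Step size adapts only during burn-in.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Orthonormal (Helmert-type) basis of the hyperplane orthogonal to 1_K.
static arma::mat ilr_basis(int K) {
  arma::mat V(K, K - 1, arma::fill::zeros);
  for (int i = 0; i < K - 1; ++i) {
    double a = 1.0 / std::sqrt((double)(i + 1) * (i + 2));
    for (int r = 0; r <= i; ++r) V(r, i) = a;
    V(i + 1, i) = -(i + 1) * a;
  }
  return V;
}

// Inverse ILR: closure of exp(V z).
static arma::vec ilr_inv(const arma::mat& V, const arma::vec& z) {
  arma::vec u = V * z;
  u -= u.max();
  arma::vec p = arma::exp(u);
  return p / arma::accu(p);
}

// Log target density over (z, log tau). Includes the ILR Jacobian
// sum_k log p_k (so a Dirichlet(alpha) prior on p contributes
// sum_k alpha_k log p_k) and the log-tau Jacobian for the uniform tau prior.
static double log_post(const arma::mat& Y, const arma::ivec& lev, int L,
                       const arma::mat& mu, const arma::mat& sig,
                       const arma::mat& conc, const arma::vec& alpha,
                       bool residual, const arma::vec& tau_max,
                       const arma::mat& Z, const arma::vec& log_tau,
                       const arma::mat& V) {
  const int K = mu.n_rows, J = mu.n_cols, N = Y.n_rows;
  double lp = 0.0;
  arma::mat m(L, J), s2(L, J, arma::fill::zeros);
  for (int l = 0; l < L; ++l) {
    arma::vec p = ilr_inv(V, Z.row(l).t());
    // Dirichlet prior + Jacobian
    for (int k = 0; k < K; ++k) {
      if (p(k) <= 0) return -INFINITY;
      lp += alpha(k) * std::log(p(k));
    }
    for (int j = 0; j < J; ++j) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) tot += p(k) * conc(k, j);
      double mj = 0.0, vj = 0.0;
      for (int k = 0; k < K; ++k) {
        double pk = p(k) * conc(k, j) / tot;
        mj += pk * mu(k, j);
        vj += pk * pk * sig(k, j) * sig(k, j);
      }
      m(l, j) = mj;
      s2(l, j) = vj;
    }
  }
  arma::vec tau(J, arma::fill::zeros);
  if (residual) {
    for (int j = 0; j < J; ++j) {
      tau(j) = std::exp(log_tau(j));
      if (tau(j) >= tau_max(j)) return -INFINITY;
      lp += log_tau(j);  // Jacobian of log transform, uniform prior on tau
    }
  }
  static const double LOG2PI = std::log(2.0 * M_PI);
  for (int i = 0; i < N; ++i) {
    const int l = lev(i);
    for (int j = 0; j < J; ++j) {
      double sd2 = residual ? tau(j) * tau(j) : s2(l, j);
      if (sd2 <= 0) return -INFINITY;
      double r = Y(i, j) - m(l, j);
      lp += -0.5 * (LOG2PI + std::log(sd2) + r * r / sd2);
    }
  }
  return lp;
}

// Draw source (mu, sigma) from the standard noninformative posterior given
// per-group summaries: sigma^2 ~ (n-1) s^2 / chisq(n-1), mu ~ N(xbar,
// sigma^2/n). Zero-SD tracers stay at the plug-in values.
static void draw_source_params(const arma::mat& xbar, const arma::mat& s,
                               const arma::vec& n, arma::mat& mu,
                               arma::mat& sig) {
  const int K = xbar.n_rows, J = xbar.n_cols;
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < J; ++j) {
      if (s(k, j) <= 0) {
        sig(k, j) = s(k, j);
        mu(k, j) = xbar(k, j);
      } else {
        double df = n(k) - 1.0;
        double s2 = df * s(k, j) * s(k, j) / R::rchisq(df);
        sig(k, j) = std::sqrt(s2);
        mu(k, j) = R::rnorm(xbar(k, j), std::sqrt(s2 / n(k)));
      }
    }
  }
}

// [[Rcpp::export]]
List run_chain_cpp(const arma::mat& Y, const arma::ivec& lev, int L,
                   const arma::mat& src_mean, const arma::mat& src_sd,
                   const arma::vec& src_n, bool draw_sources,
                   const arma::mat& conc, const arma::vec& alpha,
                   bool residual, const arma::vec& tau_max,
                   int n_iter, int burn, int thin, double init_step) {
  const int K = src_mean.n_rows, J = src_mean.n_cols;
  const arma::mat V = ilr_basis(K);
  const int n_keep = (n_iter - burn) / thin;
  const int n_z = L * (K - 1);
  const int n_par = n_z + (residual ? J : 0);

  // dispersed initial state: z near the prior mean composition, tau uniform
  arma::vec p0 = alpha / arma::accu(alpha);
  arma::vec z0 = V.t() * arma::log(p0);
  arma::mat Z(L, K - 1);
  for (int l = 0; l < L; ++l)
    for (int d = 0; d < K - 1; ++d) Z(l, d) = z0(d) + R::rnorm(0.0, 0.5);
  arma::vec log_tau(std::max(J, 1), arma::fill::zeros);
  if (residual)
    for (int j = 0; j < J; ++j)
      log_tau(j) = std::log(tau_max(j) * R::runif(0.2, 0.8));

  arma::mat mu = src_mean, sig = src_sd;
  double step = init_step;
  int acc = 0, win_acc = 0, win_n = 0;

  arma::cube p_keep(n_keep, K, L);
  arma::mat tau_keep(n_keep, residual ? J : 0);
  int kept = 0;

  for (int t = 1; t <= n_iter; ++t) {
    if (draw_sources) draw_source_params(src_mean, src_sd, src_n, mu, sig);
    double lp_cur = log_post(Y, lev, L, mu, sig, conc, alpha, residual,
                             tau_max, Z, log_tau, V);
    arma::mat Zp = Z;
    arma::vec ltp = log_tau;
    for (int l = 0; l < L; ++l)
      for (int d = 0; d < K - 1; ++d) Zp(l, d) += R::rnorm(0.0, step);
    if (residual)
      for (int j = 0; j < J; ++j) ltp(j) += R::rnorm(0.0, step);
    double lp_prop = log_post(Y, lev, L, mu, sig, conc, alpha, residual,
                              tau_max, Zp, ltp, V);
    if (std::log(R::runif(0.0, 1.0)) < lp_prop - lp_cur) {
      Z = Zp;
      log_tau = ltp;
      ++acc;
      ++win_acc;
    }
    ++win_n;
    if (t <= burn && win_n == 50) {  // adapt only during burn-in
      double rate = (double)win_acc / win_n;
      step *= std::exp(0.6 * (rate - 0.28));
      step = std::min(std::max(step, 1e-4), 10.0);
      win_acc = 0;
      win_n = 0;
    }
    if (t > burn && (t - burn) % thin == 0 && kept < n_keep) {
      for (int l = 0; l < L; ++l) {
        arma::vec p = ilr_inv(V, Z.row(l).t());
        for (int k = 0; k < K; ++k) p_keep(kept, k, l) = p(k);
      }
      if (residual)
        for (int j = 0; j < J; ++j) tau_keep(kept, j) = std::exp(log_tau(j));
      ++kept;
    }
  }
  return List::create(_["p"] = p_keep, _["tau"] = tau_keep,
                      _["accept_rate"] = (double)acc / n_iter,
                      _["step"] = step, _["n_par"] = n_par);
}
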