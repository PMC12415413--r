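#include <Rcpp.h>
using namespace Rcpp;

// Adaptive Metropolis-within-Gibbs sampler for the two-tracer Bayesian
// mixing model.  Contributions p live on the simplex and are sampled on the
// softmax scale z (J-1 free coordinates, last fixed at 0); the Jacobian of
// the transform contributes sum(log p_j) to the log target.  The observation
// model for tracer k is
//   x_k ~ Normal( sum_j p_j mu_jk , xi * sum_j p_j^2 s2_jk + tau_k^2 )
// (process error scaled by xi, plus an additive residual variance), with
//   p ~ Dirichlet(alpha), log xi ~ N(0, 1), log tau_k ~ N(log tau0_k, 0.25)
// (the residual scale is anchored at the known analytical uncertainty).
// xi and tau can be fixed, in which case only z is updated.

static double log_target(const NumericVector& z,
                         double log_xi,
                         const NumericVector& log_tau,
                         const NumericMatrix& x,
                         const NumericMatrix& mu,
                         const NumericMatrix& s2,
                         const NumericVector& alpha,
                         const NumericVector& log_tau0,
                         bool fix_errors,
                         std::vector<double>& p_out) {
  const int J = mu.nrow(), K = mu.ncol(), n_obs = x.nrow();
  // softmax with z_J = 0
  double zmax = 0.0;
  for (int j = 0; j < J - 1; ++j) if (z[j] > zmax) zmax = z[j];
  double denom = std::exp(-zmax);
  for (int j = 0; j < J - 1; ++j) denom += std::exp(z[j] - zmax);
  double lp = 0.0;
  for (int j = 0; j < J; ++j) {
    double zj = (j < J - 1) ? z[j] : 0.0;
    p_out[j] = std::exp(zj - zmax) / denom;
  }
  // Dirichlet prior + softmax Jacobian: sum_j alpha_j * log p_j
  for (int j = 0; j < J; ++j) {
    double pj = std::max(p_out[j], 1e-300);
    lp += alpha[j] * std::log(pj);
  }
  double xi = std::exp(log_xi);
  for (int k = 0; k < K; ++k) {
    double m = 0.0, vproc = 0.0;
    for (int j = 0; j < J; ++j) {
      m += p_out[j] * mu(j, k);
      vproc += p_out[j] * p_out[j] * s2(j, k);
    }
    double tau = std::exp(log_tau[k]);
    double v = xi * vproc + tau * tau;
    if (v <= 0) return -INFINITY;
    for (int i = 0; i < n_obs; ++i) {
      double r = x(i, k) - m;
      lp += -0.5 * std::log(2.0 * M_PI * v) - 0.5 * r * r / v;
    }
  }
  if (!fix_errors) {
    lp += -0.5 * log_xi * log_xi;  // log xi ~ N(0, 1)
    for (int k = 0; k < K; ++k) {
      double d = (log_tau[k] - log_tau0[k]) / 0.25;
      lp += -0.5 * d * d;          // log tau_k ~ N(log tau0_k, 0.25)
    }
  }
  return lp;
}

// [[Rcpp::export]]
List mix_sampler_cpp(NumericMatrix x,        // n_obs x K
                     NumericMatrix mu,       // J x K
                     NumericMatrix s2,       // J x K source variances
                     NumericVector alpha,    // J Dirichlet parameters
                     NumericVector tau0,     // K residual-sd prior medians
                     bool fix_errors,
                     double xi_fixed,
                     NumericVector tau_fixed,
                     int n_chains, int n_iter, int n_warmup, int thin) {
  const int J = mu.nrow(), K = mu.ncol();
  const int n_free = J - 1;
  const int n_save = (n_iter - n_warmup) / thin;
  NumericVector log_tau0(K);
  for (int k = 0; k < K; ++k) log_tau0[k] = std::log(tau0[k]);

  // saved draws: [n_save, J, n_chains] etc., filled chain-major
  NumericVector p_draws(static_cast<R_xlen_t>(n_save) * J * n_chains);
  NumericVector xi_draws(static_cast<R_xlen_t>(n_save) * n_chains);
  NumericVector tau_draws(static_cast<R_xlen_t>(n_save) * K * n_chains);
  NumericVector lp_draws(static_cast<R_xlen_t>(n_save) * n_chains);
  NumericVector accept(n_chains);

  std::vector<double> p_cur(J), p_prop(J);

  for (int c = 0; c < n_chains; ++c) {
    // init: z at the normalized-prior mean (jittered per chain), errors at prior medians
    NumericVector z(n_free);
    double asum = 0.0;
    for (int j = 0; j < J; ++j) asum += alpha[j];
    for (int j = 0; j < n_free; ++j) {
      double pj = std::max(alpha[j] / asum, 1e-6);
      double pJ = std::max(alpha[J - 1] / asum, 1e-6);
      z[j] = std::log(pj / pJ) + 0.3 * R::rnorm(0.0, 1.0);
    }
    double log_xi = fix_errors ? std::log(xi_fixed) : 0.0;
    NumericVector log_tau(K);
    for (int k = 0; k < K; ++k)
      log_tau[k] = fix_errors ? std::log(tau_fixed[k]) : log_tau0[k];

    std::vector<double> scale_z(n_free, 0.5);
    double scale_xi = 0.5;
    double scale_joint = 0.2;
    std::vector<double> scale_tau(K, 0.5);
    NumericVector z_prop(n_free);

    double lp_cur = log_target(z, log_xi, log_tau, x, mu, s2, alpha, log_tau0,
                               fix_errors, p_cur);
    long n_acc = 0, n_try = 0;
    int save_idx = 0;

    for (int it = 0; it < n_iter; ++it) {
      double ad = std::min(0.1, 1.0 / std::sqrt(static_cast<double>(it + 1)));
      for (int j = 0; j < n_free; ++j) {
        double zj_old = z[j];
        z[j] = zj_old + scale_z[j] * R::rnorm(0.0, 1.0);
        double lp_new = log_target(z, log_xi, log_tau, x, mu, s2, alpha,
                                   log_tau0, fix_errors, p_prop);
        bool acc = std::log(R::runif(0.0, 1.0)) < lp_new - lp_cur;
        if (acc) { lp_cur = lp_new; p_cur = p_prop; ++n_acc; }
        else z[j] = zj_old;
        ++n_try;
        if (it < n_warmup)
          scale_z[j] *= std::exp(ad * ((acc ? 1.0 : 0.0) - 0.44));
      }
      if (n_free > 1) {
        // joint kick across all coordinates helps when the target is a
        // narrow ridge the coordinate-wise sweep walks slowly along
        for (int j = 0; j < n_free; ++j)
          z_prop[j] = z[j] + scale_joint * R::rnorm(0.0, 1.0);
        double lp_new = log_target(z_prop, log_xi, log_tau, x, mu, s2, alpha,
                                   log_tau0, fix_errors, p_prop);
        bool acc = std::log(R::runif(0.0, 1.0)) < lp_new - lp_cur;
        if (acc) {
          for (int j = 0; j < n_free; ++j) z[j] = z_prop[j];
          lp_cur = lp_new; p_cur = p_prop;
        }
        if (it < n_warmup)
          scale_joint *= std::exp(ad * ((acc ? 1.0 : 0.0) - 0.23));
      }
      if (!fix_errors) {
        double old = log_xi;
        log_xi = old + scale_xi * R::rnorm(0.0, 1.0);
        double lp_new = log_target(z, log_xi, log_tau, x, mu, s2, alpha,
                                   log_tau0, fix_errors, p_prop);
        bool acc = std::log(R::runif(0.0, 1.0)) < lp_new - lp_cur;
        if (acc) { lp_cur = lp_new; p_cur = p_prop; }
        else log_xi = old;
        if (it < n_warmup)
          scale_xi *= std::exp(ad * ((acc ? 1.0 : 0.0) - 0.44));
        for (int k = 0; k < K; ++k) {
          double oldt = log_tau[k];
          log_tau[k] = oldt + scale_tau[k] * R::rnorm(0.0, 1.0);
          lp_new = log_target(z, log_xi, log_tau, x, mu, s2, alpha,
                              log_tau0, fix_errors, p_prop);
          acc = std::log(R::runif(0.0, 1.0)) < lp_new - lp_cur;
          if (acc) { lp_cur = lp_new; p_cur = p_prop; }
          else log_tau[k] = oldt;
          if (it < n_warmup)
            scale_tau[k] *= std::exp(ad * ((acc ? 1.0 : 0.0) - 0.44));
        }
      }
      if (it >= n_warmup && (it - n_warmup) % thin == 0 && save_idx < n_save) {
        for (int j = 0; j < J; ++j)
          p_draws[static_cast<R_xlen_t>(c) * n_save * J + j * n_save + save_idx] = p_cur[j];
        xi_draws[static_cast<R_xlen_t>(c) * n_save + save_idx] = std::exp(log_xi);
        for (int k = 0; k < K; ++k)
          tau_draws[static_cast<R_xlen_t>(c) * n_save * K + k * n_save + save_idx] = std::exp(log_tau[k]);
        lp_draws[static_cast<R_xlen_t>(c) * n_save + save_idx] = lp_cur;
        ++save_idx;
      }
    }
    accept[c] = n_try > 0 ? static_cast<double>(n_acc) / n_try : NA_REAL;
  }

  p_draws.attr("dim") = IntegerVector::create(n_save, J, n_chains);
  tau_draws.attr("dim") = IntegerVector::create(n_save, K, n_chains);
  xi_draws.attr("dim") = IntegerVector::create(n_save, n_chains);
  lp_draws.attr("dim") = IntegerVector::create(n_save, n_chains);
  return List::create(_["p"] = p_draws, _["xi"] = xi_draws,
                      _["tau"] = tau_draws, _["lp"] = lp_draws,
                      _["accept"] = accept);
}
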