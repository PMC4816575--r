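#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the zero-inflated binomial occupancy
// model: z_i ~ Bern(logit^-1(x_i' beta)), y_i ~ Binom(n_i, z_i * delta),
// delta = logit^-1(gamma). z is drawn from its exact full conditional;
// beta and gamma move by componentwise random-walk Metropolis with proposal
// scales adapted during burn-in only (frozen afterwards to keep the chain
// Markovian). Uses R's RNG so set.seed() in R gives determinism.

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// log p(z | beta) + log-prior for beta given current eta = X beta
static double beta_logpost(const NumericVector& eta, const IntegerVector& z,
                           const NumericVector& beta,
                           const NumericVector& pr_mean, double pr_var) {
  double lp = 0.0;
  const int n = eta.size();
  // log Bernoulli(z | logistic(eta)) with a stable log(1 + exp(eta))
  for (int i = 0; i < n; ++i) {
    double e = eta[i];
    double lse = (e > 0) ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
    lp += (z[i] == 1 ? e : 0.0) - lse;
  }
  for (int j = 0; j < beta.size(); ++j) {
    double d = beta[j] - pr_mean[j];
    lp += -0.5 * d * d / pr_var;
  }
  return lp;
}

// log p(y | z, gamma) + log-prior for gamma
static double gamma_logpost(double gamma, const IntegerVector& y,
                            const IntegerVector& n, const IntegerVector& z,
                            double pr_mean, double pr_var) {
  double lp = 0.0;
  double ldelta, l1mdelta;
  if (gamma > 0) {
    ldelta = -std::log1p(std::exp(-gamma));
    l1mdelta = -gamma - std::log1p(std::exp(-gamma));
  } else {
    ldelta = gamma - std::log1p(std::exp(gamma));
    l1mdelta = -std::log1p(std::exp(gamma));
  }
  for (int i = 0; i < y.size(); ++i) {
    if (z[i] == 1) lp += y[i] * ldelta + (n[i] - y[i]) * l1mdelta;
  }
  double d = gamma - pr_mean;
  lp += -0.5 * d * d / pr_var;
  return lp;
}

// deviance of the z-marginalized likelihood
// L_i = theta_i Binom(y_i | n_i, delta) + (1 - theta_i) 1[y_i = 0]
static double marginal_deviance(const NumericVector& eta, double gamma,
                                const IntegerVector& y,
                                const IntegerVector& n) {
  double ll = 0.0;
  double delta = logistic(gamma);
  for (int i = 0; i < y.size(); ++i) {
    double theta = logistic(eta[i]);
    double binom = R::dbinom(y[i], n[i], delta, 0);
    double L = theta * binom + (y[i] == 0 ? (1.0 - theta) : 0.0);
    ll += std::log(std::max(L, 1e-300));
  }
  return -2.0 * ll;
}

// [[Rcpp::export(name = ".zib_chain")]]
List zib_chain(IntegerVector y, IntegerVector n, NumericMatrix X,
               NumericVector beta_init, double gamma_init,
               NumericVector prior_mean, double prior_var,
               int burnin, int iters, int thin,
               double init_scale, bool adapt) {
  const int nc = y.size(), p = X.ncol();
  NumericVector beta = clone(beta_init);
  double gamma = gamma_init;
  IntegerVector z(nc);
  NumericVector eta(nc);

  for (int i = 0; i < nc; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    eta[i] = e;
    z[i] = (y[i] > 0) ? 1 : (unif_rand() < 0.5 ? 1 : 0);
  }

  NumericVector scale(p + 1, init_scale);
  IntegerVector acc(p + 1), tries(p + 1);
  IntegerVector acc_win(p + 1), tries_win(p + 1);

  const int kept = iters / thin;
  NumericMatrix draws(kept, p + 1);
  NumericVector deviance(kept);
  NumericVector z_mean(nc);
  int stored = 0;
  const int total = burnin + iters;

  for (int it = 0; it < total; ++it) {
    // --- z | beta, gamma, y (exact full conditional)
    double delta = logistic(gamma);
    for (int i = 0; i < nc; ++i) {
      if (y[i] > 0) { z[i] = 1; continue; }
      double theta = logistic(eta[i]);
      double a = theta * std::pow(1.0 - delta, (double)n[i]);
      double pz = a / (a + (1.0 - theta));
      z[i] = (unif_rand() < pz) ? 1 : 0;
    }

    // --- beta | z (componentwise RW-MH)
    double lp_cur = beta_logpost(eta, z, beta, prior_mean, prior_var);
    for (int j = 0; j < p; ++j) {
      double prop = beta[j] + norm_rand() * scale[j];
      double diff = prop - beta[j];
      NumericVector eta_prop(nc);
      for (int i = 0; i < nc; ++i) eta_prop[i] = eta[i] + X(i, j) * diff;
      NumericVector beta_prop = clone(beta);
      beta_prop[j] = prop;
      double lp_prop = beta_logpost(eta_prop, z, beta_prop, prior_mean,
                                    prior_var);
      ++tries[j]; ++tries_win[j];
      if (std::log(unif_rand()) < lp_prop - lp_cur) {
        beta[j] = prop; eta = eta_prop; lp_cur = lp_prop;
        ++acc[j]; ++acc_win[j];
      }
    }

    // --- gamma | z, y (RW-MH)
    {
      double prop = gamma + norm_rand() * scale[p];
      double lp0 = gamma_logpost(gamma, y, n, z, prior_mean[p], prior_var);
      double lp1 = gamma_logpost(prop, y, n, z, prior_mean[p], prior_var);
      ++tries[p]; ++tries_win[p];
      if (std::log(unif_rand()) < lp1 - lp0) {
        gamma = prop; ++acc[p]; ++acc_win[p];
      }
    }

    // --- proposal adaptation, burn-in only, every 50 iterations
    if (adapt && it < burnin && (it + 1) % 50 == 0) {
      for (int j = 0; j <= p; ++j) {
        if (tries_win[j] > 0) {
          double rate = (double)acc_win[j] / tries_win[j];
          if (rate > 0.45) scale[j] *= 1.2;
          else if (rate < 0.20) scale[j] /= 1.2;
        }
        acc_win[j] = 0; tries_win[j] = 0;
      }
    }

    if (it >= burnin && ((it - burnin + 1) % thin == 0) && stored < kept) {
      for (int j = 0; j < p; ++j) draws(stored, j) = beta[j];
      draws(stored, p) = gamma;
      deviance[stored] = marginal_deviance(eta, gamma, y, n);
      for (int i = 0; i < nc; ++i) z_mean[i] += z[i];
      ++stored;
    }
  }

  NumericVector acc_rate(p + 1);
  for (int j = 0; j <= p; ++j) {
    acc_rate[j] = tries[j] > 0 ? (double)acc[j] / tries[j] : NA_REAL;
  }
  if (stored > 0) {
    for (int i = 0; i < nc; ++i) z_mean[i] /= stored;
  }
  return List::create(_["draws"] = draws, _["deviance"] = deviance,
                      _["acceptance"] = acc_rate, _["scale"] = scale,
                      _["z_mean"] = z_mean);
}
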