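// Single-site Gibbs samplers for the five Bayesian whole-genome regression
// models: BRR (Gaussian prior, one common marker variance), BayesA
// (per-marker scaled-inverse-chi-square variances), BayesB (point mass at
// zero with probability pi + per-marker variances), BayesC (point mass +
// one common variance), and the Bayesian LASSO (Laplace prior via the
// normal-exponential scale mixture with per-marker latent variances).
//
// All randomness comes from R's RNG, so set.seed() in the calling R code
// makes chains exactly reproducible.

#include <Rcpp.h>
using namespace Rcpp;

// scaled-inverse-chi-square draw: nu * S / chisq_nu
static inline double rscinvchisq(double nu, double sumsq_plus_nuS) {
  return sumsq_plus_nuS / R::rchisq(nu);
}

// inverse-Gaussian draw (Michael, Schucany & Haas)
static inline double rinvgauss(double mu, double lambda) {
  double nu = R::norm_rand();
  double y = nu * nu;
  double x = mu + mu * mu * y / (2.0 * lambda) -
    mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  double z = R::unif_rand();
  return (z <= mu / (mu + x)) ? x : mu * mu / x;
}

// model codes: 0 = BRR, 1 = BayesA, 2 = BayesB, 3 = BayesC, 4 = BL
// [[Rcpp::export]]
List gibbs_wgr_cpp(const NumericMatrix& X, const NumericVector& y, int model,
                   int niter, int burn, int thin,
                   double nu_beta, double S_beta, double nu_e, double S_e,
                   double pi0, bool estimate_pi, double pi_a, double pi_b,
                   double lambda_shape, double lambda_rate,
                   bool fix_var, double fixed_sb2, double fixed_se2,
                   bool sample_mu) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector b(p, 0.0), sb2j(p, S_beta), tau2(p, 1.0), d(p, 1.0);
  double sb2 = fix_var ? fixed_sb2 : S_beta;
  double se2 = fix_var ? fixed_se2 : S_e;
  double pi = pi0;                      // probability of a NULL effect
  double lambda2 = lambda_shape / lambda_rate;
  double mu = 0.0;

  NumericVector e = clone(y);           // residual: y - mu - X b
  NumericVector xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }

  const int nkeep = (niter - burn) / thin;
  NumericVector b_sum(p, 0.0), b_sumsq(p, 0.0), d_sum(p, 0.0);
  NumericVector chain_se2(nkeep), chain_sb2(nkeep), chain_lambda2(nkeep),
    chain_pi(nkeep);
  double mu_sum = 0.0;
  int kept = 0;

  const bool mixture = (model == 2 || model == 3);

  for (int it = 1; it <= niter; ++it) {
    if (sample_mu) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += e[i] + mu;
      double mu_new = R::rnorm(s / n, std::sqrt(se2 / n));
      for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
      mu = mu_new;
    }

    int m_in = 0;
    double sum_b2_in = 0.0;
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0.0) { b[j] = 0.0; continue; }
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      rhs += xtx[j] * b[j];

      double vj;                        // prior slab variance of b_j
      switch (model) {
        case 0: vj = sb2; break;
        case 1: case 2: vj = sb2j[j]; break;
        case 3: vj = sb2; break;
        default: vj = tau2[j] * se2; break;  // BL scale mixture
      }

      double b_new;
      if (mixture) {
        double den = vj * xtx[j] + se2;
        double log_odds = std::log((1.0 - pi) / pi) +
          0.5 * std::log(se2 / den) + rhs * rhs * vj / (2.0 * se2 * den);
        double p_in = 1.0 / (1.0 + std::exp(-log_odds));
        if (R::unif_rand() < p_in) {
          double c = xtx[j] + se2 / vj;
          b_new = R::rnorm(rhs / c, std::sqrt(se2 / c));
          d[j] = 1.0;
        } else {
          b_new = 0.0;
          d[j] = 0.0;
        }
      } else {
        double c = xtx[j] + se2 / vj;
        b_new = R::rnorm(rhs / c, std::sqrt(se2 / c));
      }
      if (b_new != b[j]) {
        double diff = b[j] - b_new;
        for (int i = 0; i < n; ++i) e[i] += X(i, j) * diff;
        b[j] = b_new;
      }
      if (!mixture || d[j] > 0.5) { ++m_in; sum_b2_in += b[j] * b[j]; }
    }

    // marker-variance updates
    if (!fix_var) {
      if (model == 0) {
        double ssb = 0.0;
        for (int j = 0; j < p; ++j) ssb += b[j] * b[j];
        sb2 = rscinvchisq(nu_beta + p, ssb + nu_beta * S_beta);
      } else if (model == 1) {
        for (int j = 0; j < p; ++j)
          sb2j[j] = rscinvchisq(nu_beta + 1.0, b[j] * b[j] + nu_beta * S_beta);
      } else if (model == 2) {
        for (int j = 0; j < p; ++j) {
          if (d[j] > 0.5)
            sb2j[j] = rscinvchisq(nu_beta + 1.0, b[j] * b[j] + nu_beta * S_beta);
          else
            sb2j[j] = rscinvchisq(nu_beta, nu_beta * S_beta);  // prior draw
        }
      } else if (model == 3) {
        sb2 = rscinvchisq(nu_beta + m_in, sum_b2_in + nu_beta * S_beta);
      }
    }

    if (model == 4) {                   // BL latent scales and lambda^2
      for (int j = 0; j < p; ++j) {
        double bj2 = b[j] * b[j];
        if (bj2 < 1e-12) bj2 = 1e-12;
        double inv_tau2 = rinvgauss(std::sqrt(lambda2 * se2 / bj2), lambda2);
        tau2[j] = 1.0 / std::max(inv_tau2, 1e-12);
      }
      double sum_tau2 = 0.0;
      for (int j = 0; j < p; ++j) sum_tau2 += tau2[j];
      lambda2 = R::rgamma(lambda_shape + p, 1.0 / (lambda_rate + sum_tau2 / 2.0));
    }

    if (mixture && estimate_pi) {
      int m_null = p - m_in;
      pi = R::rbeta(pi_a + m_null, pi_b + m_in);
      if (pi < 1e-8) pi = 1e-8;
      if (pi > 1.0 - 1e-8) pi = 1.0 - 1e-8;
    }

    if (!fix_var) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      se2 = rscinvchisq(nu_e + n, sse + nu_e * S_e);
    }

    if (!R_finite(se2) || se2 <= 0.0 || !R_finite(b[0]))
      stop("sampler diverged (non-finite state) at iteration %d", it);

    if (it > burn && ((it - burn) % thin == 0) && kept < nkeep) {
      for (int j = 0; j < p; ++j) {
        b_sum[j] += b[j];
        b_sumsq[j] += b[j] * b[j];
        d_sum[j] += d[j];
      }
      mu_sum += mu;
      chain_se2[kept] = se2;
      if (model == 1 || model == 2) {
        double m = 0.0;
        for (int j = 0; j < p; ++j) m += sb2j[j];
        chain_sb2[kept] = m / p;
      } else chain_sb2[kept] = sb2;
      chain_lambda2[kept] = lambda2;
      chain_pi[kept] = pi;
      ++kept;
    }
  }

  NumericVector b_mean(p), b_sd(p), incl(p);
  for (int j = 0; j < p; ++j) {
    b_mean[j] = b_sum[j] / kept;
    double v = b_sumsq[j] / kept - b_mean[j] * b_mean[j];
    b_sd[j] = std::sqrt(std::max(v, 0.0));
    incl[j] = mixture ? d_sum[j] / kept : 1.0;
  }
  return List::create(
    _["effect_mean"] = b_mean, _["effect_sd"] = b_sd,
    _["inclusion_prob"] = incl, _["mu_mean"] = mu_sum / std::max(kept, 1),
    _["chain_se2"] = chain_se2, _["chain_sb2"] = chain_sb2,
    _["chain_lambda2"] = chain_lambda2, _["chain_pi"] = chain_pi,
    _["n_samples"] = kept);
}
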