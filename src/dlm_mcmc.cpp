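// Random-walk Metropolis-within-Gibbs sampler for the two-dose probit
// dynamic linear model.  Serves as the seeded stochastic cross-check of the
// deterministic quadrature backend.
//
// Parameterization: (mu1, mu2, v) with the borrowing scale
// s2 = xi + tau * tan(pi v / 2), v ~ Uniform(0, 1), so the half-Cauchy
// prior on s2 is exact and the sampler works on a bounded coordinate.

#include <Rcpp.h>
using namespace Rcpp;

static inline double binom_loglik(int y, int n, double mu) {
  if (n == 0) return 0.0;
  double p = R::pnorm(mu, 0.0, 1.0, 1, 0);
  if (p <= 0.0) return (y == 0) ? 0.0 : R_NegInf;
  if (p >= 1.0) return (y == n) ? 0.0 : R_NegInf;
  return y * std::log(p) + (n - y) * std::log1p(-p);
}

// [[Rcpp::export]]
List dlm_mcmc_cpp(int y1, int n1, int y2, int n2,
                  double theta, double sigma1, double xi, double tau,
                  double p0, double delta1,
                  double niter, double nburn) {
  RNGScope scope;
  const double z0 = R::qnorm(p0, 0.0, 1.0, 1, 0);
  const long NI = (long)niter, NB = (long)nburn;

  double mu1 = theta, mu2 = theta, v = 0.5;
  double s2 = xi + tau * std::tan(M_PI * v / 2.0);
  double ll1 = binom_loglik(y1, n1, mu1), ll2 = binom_loglik(y2, n2, mu2);
  double step1 = 1.0, step2 = 1.0, stepv = 0.2;
  long acc1 = 0, acc2 = 0, accv = 0, tries = 0;

  // streaming sums and batch means for MCSE
  const int NS = 5;
  double sums[NS] = {0, 0, 0, 0, 0};
  const int NBATCH = 1000;
  std::vector<double> bsum(NS * NBATCH, 0.0);
  long per_batch = NI / NBATCH + 1;

  for (long it = -NB; it < NI; ++it) {
    // mu1 update
    {
      double prop = mu1 + step1 * norm_rand();
      double llp = binom_loglik(y1, n1, prop);
      double lr = llp - ll1
        + R::dnorm(prop, theta, sigma1, 1) - R::dnorm(mu1, theta, sigma1, 1)
        + R::dnorm(mu2, prop, s2, 1) - R::dnorm(mu2, mu1, s2, 1);
      if (std::log(unif_rand()) < lr) { mu1 = prop; ll1 = llp; ++acc1; }
    }
    // mu2 update
    {
      double prop = mu2 + step2 * norm_rand();
      double llp = binom_loglik(y2, n2, prop);
      double lr = llp - ll2
        + R::dnorm(prop, mu1, s2, 1) - R::dnorm(mu2, mu1, s2, 1);
      if (std::log(unif_rand()) < lr) { mu2 = prop; ll2 = llp; ++acc2; }
    }
    // v update (reflected at the boundaries; uniform prior cancels)
    {
      double prop = v + stepv * norm_rand();
      while (prop < 0.0 || prop > 1.0)
        prop = (prop < 0.0) ? -prop : 2.0 - prop;
      double pc = std::min(std::max(prop, 1e-12), 1.0 - 1e-12);
      double s2p = xi + tau * std::tan(M_PI * pc / 2.0);
      double lr = R::dnorm(mu2, mu1, s2p, 1) - R::dnorm(mu2, mu1, s2, 1);
      if (std::log(unif_rand()) < lr) { v = pc; s2 = s2p; ++accv; }
    }
    ++tries;

    if (it < 0) {                      // step-size adaptation during burn-in
      if (tries == 500) {
        if (acc1 < 150) step1 *= 0.7; else if (acc1 > 300) step1 *= 1.4;
        if (acc2 < 150) step2 *= 0.7; else if (acc2 > 300) step2 *= 1.4;
        if (accv < 150) stepv *= 0.7; else if (accv > 300) stepv *= 1.4;
        acc1 = acc2 = accv = 0; tries = 0;
      }
      continue;
    }
    if (it == 0) { acc1 = acc2 = accv = 0; tries = 0; }

    double p1 = R::pnorm(mu1, 0.0, 1.0, 1, 0);
    double p2 = R::pnorm(mu2, 0.0, 1.0, 1, 0);
    double val[NS] = {
      (mu1 > z0) ? 1.0 : 0.0,
      (mu2 > z0) ? 1.0 : 0.0,
      (p2 - p1 < delta1) ? 1.0 : 0.0,
      p1, p2
    };
    int b = (int)(it / per_batch);
    if (b >= NBATCH) b = NBATCH - 1;
    for (int s = 0; s < NS; ++s) {
      sums[s] += val[s];
      bsum[s * NBATCH + b] += val[s];
    }
  }

  NumericVector est(NS), mcse(NS);
  for (int s = 0; s < NS; ++s) est[s] = sums[s] / (double)NI;
  // batch-means MCSE
  for (int s = 0; s < NS; ++s) {
    double bs = 0.0, bss = 0.0;
    int nb = 0;
    for (int b = 0; b < NBATCH; ++b) {
      long lo = (long)b * per_batch;
      if (lo >= NI) break;
      long hi = std::min<long>(NI, lo + per_batch);
      double mb = bsum[s * NBATCH + b] / (double)(hi - lo);
      bs += mb; bss += mb * mb; ++nb;
    }
    double varb = (bss - bs * bs / nb) / (nb - 1.0);
    mcse[s] = std::sqrt(std::max(varb, 0.0) / nb);
  }

  return List::create(
    _["est"] = est, _["mcse"] = mcse,
    _["accept"] = NumericVector::create(
      acc1 / (double)tries, acc2 / (double)tries, accv / (double)tries));
}
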