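#include <Rcpp.h>
using namespace Rcpp;

// Multi-species functional response MCMC core.
//
// Adaptive random-walk Metropolis on log attack rates (the reference
// species is pinned at 1; one joint proposal per iteration) and on the
// log Dirichlet concentration, with prey availability redrawn from a
// left-truncated normal at every iteration (plug-in propagation of
// availability uncertainty, not joint inference). Uses R's RNG so runs
// are reproducible under set.seed().

// left-truncated-at-zero normal draw; sd == 0 returns the mean.
// Rejection sampling is cheap here because availability means are >= 0,
// so the acceptance probability is always >= 1/2.
static double rtnorm0(double mean, double sd) {
  if (sd <= 0.0) return mean < 0.0 ? 0.0 : mean;
  for (int k = 0; k < 100; ++k) {
    double x = mean + sd * R::norm_rand();
    if (x >= 0.0) return x;
  }
  double plo = R::pnorm(0.0, mean, sd, 1, 0);
  double u = R::runif(plo, 1.0);
  if (u >= 1.0) u = 1.0 - 1e-16;
  return R::qnorm(u, mean, sd, 1, 0);
}

static inline double pow_m(double x, double m) {
  if (m == 1.0) return x;
  if (m == 1.5) return x * std::sqrt(x);
  if (m == 2.0) return x * x;
  return std::pow(x, m);
}

// Dirichlet(tau * p_pred) log-likelihood given precomputed B^m and
// log(obs); p_pred floored at eps and renormalised per row.
static double loglik_Bm(const NumericMatrix& logobs,
                        const NumericMatrix& Bm,
                        const std::vector<double>& a,
                        double tau, double eps) {
  int n = logobs.nrow(), S = logobs.ncol();
  double ll = n * R::lgammafn(tau);
  std::vector<double> p(S);
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (int j = 0; j < S; ++j) {
      p[j] = a[j] * Bm(i, j);
      tot += p[j];
    }
    double tot2 = 0.0;
    for (int j = 0; j < S; ++j) {
      p[j] = (tot > 0.0) ? p[j] / tot : 1.0 / S;
      if (p[j] < eps) p[j] = eps;
      tot2 += p[j];
    }
    for (int j = 0; j < S; ++j) {
      double alpha = tau * p[j] / tot2;
      ll += (alpha - 1.0) * logobs(i, j) - R::lgammafn(alpha);
    }
  }
  return ll;
}

// [[Rcpp::export(name = ".msfr_loglik_cpp")]]
double msfr_loglik_cpp(NumericMatrix obs, NumericMatrix B, NumericVector a,
                       double m, double tau, double eps) {
  int n = obs.nrow(), S = obs.ncol();
  NumericMatrix logobs(n, S), Bm(n, S);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < S; ++j) {
      logobs(i, j) = std::log(obs(i, j));
      Bm(i, j) = pow_m(B(i, j), m);
    }
  std::vector<double> av(a.begin(), a.end());
  return loglik_Bm(logobs, Bm, av, tau, eps);
}

// [[Rcpp::export(name = ".msfr_mcmc_cpp")]]
List msfr_mcmc_cpp(NumericMatrix obs, NumericMatrix avail_mean,
                   NumericMatrix avail_sd, double m, int ref_idx,
                   int iter, int burn, NumericVector init_a,
                   double init_tau, double prior_max, double tau_lo,
                   double tau_hi, double eps) {
  RNGScope scope;
  int n = obs.nrow(), S = obs.ncol();
  if (avail_mean.nrow() != n || avail_mean.ncol() != S)
    stop("availability matrix does not match observations");
  int ref = ref_idx - 1;  // 1-based from R

  NumericMatrix logobs(n, S);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < S; ++j) logobs(i, j) = std::log(obs(i, j));

  bool any_sd = false;
  for (int i = 0; i < n && !any_sd; ++i)
    for (int j = 0; j < S; ++j)
      if (avail_sd(i, j) > 0.0) { any_sd = true; break; }

  std::vector<double> la(S), a(S);
  for (int j = 0; j < S; ++j) {
    a[j] = init_a[j];
    la[j] = std::log(init_a[j]);
  }
  double ltau = std::log(init_tau);
  double ltau_lo = std::log(tau_lo), ltau_hi = std::log(tau_hi);

  // proposal scales, adapted during burn-in (joint update for the
  // attack-rate block, so the target acceptance is the multivariate 0.23)
  double prop_sd_a = 0.1, prop_sd_tau = 0.15;
  int acc_a = 0, tries_a = 0, acc_tau = 0, tries_tau = 0;
  const int adapt_every = 50;
  const double target_a = 0.23, target_tau = 0.44;

  NumericMatrix Bm(n, S);
  int total = burn + iter;
  NumericMatrix draws_a(iter, S);
  NumericVector draws_tau(iter), deviance(iter);
  double acc_post_a = 0.0, acc_post_tau = 0.0;

  // availability fixed at its means when all SDs are zero
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < S; ++j)
      Bm(i, j) = pow_m(avail_mean(i, j) < 0 ? 0 : avail_mean(i, j), m);

  std::vector<double> la_new(S), a_new(S);
  for (int it = 0; it < total; ++it) {
    // redraw availability, recompute current likelihood under it
    if (any_sd) {
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < S; ++j)
          Bm(i, j) = pow_m(rtnorm0(avail_mean(i, j), avail_sd(i, j)), m);
    }
    double tau = std::exp(ltau);
    double ll = loglik_Bm(logobs, Bm, a, tau, eps);

    // attack-rate block (log scale; the uniform(0, prior_max) prior on a
    // contributes la via the Jacobian)
    {
      bool ok = true;
      double dlp = 0.0;
      for (int j = 0; j < S; ++j) {
        if (j == ref) { la_new[j] = la[j]; a_new[j] = a[j]; continue; }
        la_new[j] = la[j] + R::norm_rand() * prop_sd_a;
        a_new[j] = std::exp(la_new[j]);
        if (a_new[j] >= prior_max) ok = false;
        dlp += la_new[j] - la[j];
      }
      tries_a++;
      if (ok) {
        double ll_new = loglik_Bm(logobs, Bm, a_new, tau, eps);
        if (std::log(R::unif_rand()) < ll_new - ll + dlp) {
          la = la_new; a = a_new; ll = ll_new;
          acc_a++;
          if (it >= burn) acc_post_a += 1.0;
        }
      }
    }

    // concentration (log-uniform prior on [tau_lo, tau_hi])
    {
      double lt_new = ltau + R::norm_rand() * prop_sd_tau;
      tries_tau++;
      if (lt_new > ltau_lo && lt_new < ltau_hi) {
        double ll_new = loglik_Bm(logobs, Bm, a, std::exp(lt_new), eps);
        if (std::log(R::unif_rand()) < ll_new - ll) {
          ltau = lt_new; ll = ll_new;
          acc_tau++;
          if (it >= burn) acc_post_tau += 1.0;
        }
      }
    }

    // adapt proposal scales during burn-in
    if (it < burn && (it + 1) % adapt_every == 0) {
      double ra = tries_a > 0 ? (double)acc_a / tries_a : target_a;
      prop_sd_a *= std::exp(ra - target_a);
      prop_sd_a = std::min(std::max(prop_sd_a, 1e-3), 5.0);
      acc_a = 0; tries_a = 0;
      double rt = tries_tau > 0 ? (double)acc_tau / tries_tau : target_tau;
      prop_sd_tau *= std::exp(rt - target_tau);
      prop_sd_tau = std::min(std::max(prop_sd_tau, 1e-3), 5.0);
      acc_tau = 0; tries_tau = 0;
    }

    if (it >= burn) {
      int r = it - burn;
      for (int j = 0; j < S; ++j) draws_a(r, j) = a[j];
      draws_tau[r] = std::exp(ltau);
      deviance[r] = -2.0 * ll;
    }
  }

  NumericVector acc_rates(S);
  for (int j = 0; j < S; ++j)
    acc_rates[j] = (j == ref) ? NA_REAL : acc_post_a / iter;

  return List::create(
    _["a"] = draws_a, _["tau"] = draws_tau, _["deviance"] = deviance,
    _["accept_a"] = acc_rates, _["accept_tau"] = acc_post_tau / iter);
}
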