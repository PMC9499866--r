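#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for one exposure's spike-and-slab classification.
//
// Model (per exposure, d diseases): p ~ Beta(alpha, beta);
// label_j in {null, slab+, slab-} with P(null) = 1 - p and each slab sign
// carrying p/2; observed beta_hat_j ~ N(0, se_j^2) under null and
// N(+/-mu, sigma^2 + se_j^2) under the slabs (true effect integrated out).
// Alternates label draws given p with a conjugate Beta draw of p given the
// non-null count. Uses R's RNG so results are reproducible via set.seed().
//
// Returns per-disease posterior probabilities of each label over the
// post-burn-in draws plus the posterior mean of p.
// [[Rcpp::export(name = ".gibbs_one_exposure")]]
List gibbs_one_exposure(NumericVector beta_hat, NumericVector se,
                        double alpha, double beta, double mu, double sigma,
                        int n_iter, int burn_in) {
  const int d = beta_hat.size();
  if (se.size() != d) stop("beta_hat and se lengths differ");
  for (int j = 0; j < d; ++j)
    if (!(se[j] > 0)) stop("all standard errors must be positive");
  if (n_iter <= burn_in || burn_in < 0) stop("need n_iter > burn_in >= 0");

  // log-likelihood of each component, offset so the null term is 0
  std::vector<double> dp(d), dm(d);
  const double slab_var = sigma * sigma;
  for (int j = 0; j < d; ++j) {
    double v0 = se[j] * se[j];
    double ll0 = R::dnorm(beta_hat[j], 0.0, std::sqrt(v0), 1);
    double vs  = std::sqrt(slab_var + v0);
    dp[j] = R::dnorm(beta_hat[j],  mu, vs, 1) - ll0;
    dm[j] = R::dnorm(beta_hat[j], -mu, vs, 1) - ll0;
  }

  std::vector<int> label(d);
  double p = alpha / (alpha + beta);
  // initial labels from the prior at the prior-mean inclusion proportion
  for (int j = 0; j < d; ++j) {
    double u = unif_rand();
    label[j] = (u < 1.0 - p) ? 0 : (unif_rand() < 0.5 ? 1 : 2);
  }

  std::vector<double> n_null(d, 0.0), n_plus(d, 0.0), n_minus(d, 0.0);
  double p_sum = 0.0;
  const int kept = n_iter - burn_in;

  for (int it = 0; it < n_iter; ++it) {
    const double l0 = std::log1p(-p);       // log(1 - p)
    const double ls = std::log(p / 2.0);    // log(p) + log(1/2)
    int k = 0;
    for (int j = 0; j < d; ++j) {
      double w0 = l0, wp = ls + dp[j], wm = ls + dm[j];
      double m = std::max(w0, std::max(wp, wm));
      double e0 = std::exp(w0 - m), ep = std::exp(wp - m), em = std::exp(wm - m);
      double u = unif_rand() * (e0 + ep + em);
      int lab = (u < e0) ? 0 : ((u < e0 + ep) ? 1 : 2);
      label[j] = lab;
      if (lab != 0) ++k;
      if (it >= burn_in) {
        if (lab == 0) n_null[j] += 1.0;
        else if (lab == 1) n_plus[j] += 1.0;
        else n_minus[j] += 1.0;
      }
    }
    p = R::rbeta(alpha + k, beta + d - k);
    if (it >= burn_in) p_sum += p;
  }

  NumericVector pn(d), pp(d), pm(d);
  for (int j = 0; j < d; ++j) {
    pn[j] = n_null[j] / kept;
    pp[j] = n_plus[j] / kept;
    pm[j] = n_minus[j] / kept;
  }
  return List::create(_["null_prob"] = pn, _["slab_plus_prob"] = pp,
                      _["slab_minus_prob"] = pm,
                      _["p_mean"] = p_sum / kept);
}
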