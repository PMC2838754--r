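// BayesB Gibbs / Metropolis-Hastings sampler with reliability-weighted
// residuals.  Model: y_i = alpha + sum_k x_ik beta_k delta_k + e_i,
// Var(e_i) = sigma2e / w_i.  Per locus, (delta_k, sigma2_beta_k) is
// updated by a Metropolis-Hastings step proposing from the prior with
// beta_k integrated out of the likelihood; included effects are then
// drawn by a Gibbs step, as are alpha (flat prior) and sigma2e
// (scaled-inverse-chi-square).  Uses R's RNG so set.seed() on the R
// side makes runs bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double rsichisq(double nu, double s2) {
  // scaled inverse chi-square draw: nu * s2 / chisq(nu)
  return nu * s2 / R::rchisq(nu);
}

// marginal log-likelihood gain of fitting the locus with effect
// variance v, relative to delta = 0, with beta integrated out:
//   a = x' W x,  b = x' W r  (W = diag(w), unscaled by sigma2e)
static inline double dloglik(double v, double a, double b, double s2e) {
  return -0.5 * std::log(1.0 + v * a / s2e) +
         0.5 * v * b * b / (s2e * (s2e + v * a));
}

// [[Rcpp::export(name = ".bayesb_mcmc")]]
List bayesb_mcmc(const arma::mat& X, const arma::vec& y,
                 const arma::vec& w, double pi_prior,
                 double nuE, double s2E, double nuB, double s2B,
                 bool fixVar, double fixedVar,
                 int chain, int burnin, int thin) {
  const int n = X.n_rows, K = X.n_cols;
  RNGScope scope;

  // weighted design columns and their weighted sums of squares
  arma::mat WX = X;
  WX.each_col() %= w;
  arma::vec a(K);
  for (int k = 0; k < K; ++k) a(k) = arma::dot(WX.col(k), X.col(k));
  const double sw = arma::accu(w);

  arma::vec beta(K, arma::fill::zeros);
  arma::ivec delta(K, arma::fill::zeros);
  arma::vec varb(K);
  const double priorMeanVar = fixVar ? fixedVar : nuB * s2B / (nuB - 2.0);
  varb.fill(priorMeanVar);
  double alpha = arma::dot(w, y) / sw;
  double s2e = s2E;
  arma::vec r = y - alpha;

  arma::vec sumBeta(K, arma::fill::zeros);
  arma::vec sumDelta(K, arma::fill::zeros);
  double sumAlpha = 0.0, sumS2e = 0.0;
  const int nkeep = (chain - burnin) / thin;
  arma::mat trace(nkeep > 0 ? nkeep : 0, 3);
  int kept = 0, nPost = 0;

  for (int it = 0; it < chain; ++it) {
    // locus sweep
    for (int k = 0; k < K; ++k) {
      if (delta(k)) r += X.col(k) * beta(k);      // remove current effect
      const double b = arma::dot(WX.col(k), r);
      const double llCur = delta(k) ? dloglik(varb(k), a(k), b, s2e) : 0.0;
      const int deltaProp = (unif_rand() < pi_prior) ? 1 : 0;
      const double vProp = fixVar ? fixedVar : rsichisq(nuB, s2B);
      const double llProp = deltaProp ? dloglik(vProp, a(k), b, s2e) : 0.0;
      if (std::log(unif_rand()) < llProp - llCur) {
        delta(k) = deltaProp;
        varb(k) = vProp;
      }
      if (delta(k)) {
        const double C = a(k) / s2e + 1.0 / varb(k);
        const double mean = (b / s2e) / C;
        beta(k) = mean + norm_rand() / std::sqrt(C);
        r -= X.col(k) * beta(k);
      } else {
        beta(k) = 0.0;
      }
    }
    // intercept, flat prior
    r += alpha;
    alpha = arma::dot(w, r) / sw + norm_rand() * std::sqrt(s2e / sw);
    r -= alpha;
    // residual variance, scaled-inverse-chi-square posterior
    const double ssr = arma::dot(w, arma::square(r));
    s2e = (ssr + nuE * s2E) / R::rchisq(nuE + n);

    if (it >= burnin) {
      ++nPost;
      sumAlpha += alpha;
      sumS2e += s2e;
      for (int k = 0; k < K; ++k) {
        if (delta(k)) {
          sumBeta(k) += beta(k);
          sumDelta(k) += 1.0;
        }
      }
      if ((it - burnin) % thin == 0 && kept < nkeep) {
        trace(kept, 0) = alpha;
        trace(kept, 1) = s2e;
        trace(kept, 2) = arma::accu(delta);
        ++kept;
      }
    }
  }

  return List::create(
    _["alpha"] = sumAlpha / nPost,
    _["beta"] = sumBeta / nPost,          // posterior mean of beta*delta
    _["inclusion"] = sumDelta / nPost,
    _["sigma2e"] = sumS2e / nPost,
    _["trace"] = trace);
}
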