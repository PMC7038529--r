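// Single-site Gibbs sampler for the mixture-prior marker-effect model
// ("Bayes B"): each marker effect is null with prior probability pi, or
// normal with its own variance s2b_j ~ scaled-inv-chi2(nu, s2) otherwise
// (marginally a scaled-t prior). The indicator is updated from the
// marginal likelihood ratio with the effect integrated out, so no
// Metropolis step is needed. Uses R's RNG: seed with set.seed() in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double rinvchisq(double df, double scale) {
  // scaled-inverse-chi-square draw: df * scale / chi2_df
  return df * scale / R::rchisq(df);
}

// [[Rcpp::export(name = ".bayesbGibbs")]]
List bayesb_gibbs(const arma::vec& y, const arma::mat& X, double pi0,
                  double nu, double s2, int n_iter, int burn_in, int thin,
                  double nu_e, double s2_e0, bool update_pi) {
  const int n = X.n_rows, m = X.n_cols;
  arma::vec xtx(m);
  for (int j = 0; j < m; ++j) xtx(j) = arma::dot(X.col(j), X.col(j));

  const double vy = arma::var(y);
  double mu = arma::mean(y);
  double s2e = s2_e0;
  arma::vec b(m, arma::fill::zeros);
  arma::vec s2b(m);
  for (int j = 0; j < m; ++j) s2b(j) = rinvchisq(nu, s2);
  arma::ivec delta(m, arma::fill::zeros);
  arma::vec e = y - mu;              // current residual (b = 0)

  arma::vec bSum(m, arma::fill::zeros), bSumSq(m, arma::fill::zeros);
  arma::vec inclSum(m, arma::fill::zeros);
  double muSum = 0.0, s2eSum = 0.0, piSum = 0.0;
  int kept = 0;
  bool divergent = false;
  double logPriorOdds = std::log(1.0 - pi0) - std::log(pi0);
  const bool allIn = (pi0 <= 0.0);

  for (int it = 1; it <= n_iter; ++it) {
    // intercept
    e += mu;
    mu = R::rnorm(arma::mean(e), std::sqrt(s2e / n));
    e -= mu;

    // marker effects
    for (int j = 0; j < m; ++j) {
      if (delta(j) == 1) { e += X.col(j) * b(j); }
      const double rhs = arma::dot(X.col(j), e);
      const double c = xtx(j) * s2b(j) + s2e;
      bool incl;
      if (allIn) {
        incl = true;
      } else {
        // log Bayes factor of inclusion vs null, b_j integrated out
        const double logBF = 0.5 * (std::log(s2e / c)
                                    + rhs * rhs * s2b(j) / (s2e * c));
        const double lo = logPriorOdds + logBF;
        const double pIncl = 1.0 / (1.0 + std::exp(-lo));
        incl = (R::unif_rand() < pIncl);
      }
      if (incl) {
        const double postVar = s2b(j) * s2e / c;
        const double postMean = rhs * s2b(j) / c;
        b(j) = R::rnorm(postMean, std::sqrt(postVar));
        e -= X.col(j) * b(j);
        delta(j) = 1;
        s2b(j) = rinvchisq(nu + 1.0, (nu * s2 + b(j) * b(j)) / (nu + 1.0));
      } else {
        b(j) = 0.0;
        delta(j) = 0;
        s2b(j) = rinvchisq(nu, s2);   // refresh from the prior
      }
    }

    // mixture weight: Beta posterior under a uniform prior
    if (update_pi && !allIn) {
      const int k = arma::accu(delta);
      pi0 = R::rbeta(m - k + 1.0, k + 1.0);
      pi0 = std::min(std::max(pi0, 1e-6), 1.0 - 1e-6);
      logPriorOdds = std::log(1.0 - pi0) - std::log(pi0);
    }

    // residual variance
    s2e = rinvchisq(n + nu_e, (arma::dot(e, e) + nu_e * s2_e0) / (n + nu_e));
    if (s2e > 10.0 * vy) divergent = true;

    if (it > burn_in && (it - burn_in) % thin == 0) {
      ++kept;
      muSum += mu;
      s2eSum += s2e;
      bSum += b;
      bSumSq += arma::square(b);
      piSum += pi0;
      for (int j = 0; j < m; ++j) inclSum(j) += delta(j);
    }
  }

  arma::vec bMean = bSum / kept;
  arma::vec bSD = arma::sqrt(arma::clamp(bSumSq / kept - arma::square(bMean),
                                         0.0, arma::datum::inf));
  return List::create(_["mu"] = muSum / kept,
                      _["beta"] = bMean,
                      _["betaSD"] = bSD,
                      _["inclusion"] = inclSum / kept,
                      _["sigma2e"] = s2eSum / kept,
                      _["pi"] = piSum / kept,
                      _["retained"] = kept,
                      _["divergent"] = divergent);
}
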