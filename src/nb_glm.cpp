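// Negative-binomial GLM machinery for the Wald differential-abundance
// test: per-taxon IRLS fits with log link and size-factor offsets,
// profile-likelihood dispersion estimation, and posterior-mode dispersion
// shrinkage toward a fitted trend.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static const double MU_FLOOR = 1e-10;

// NB log likelihood with dispersion alpha (size = 1/alpha); Poisson limit
// for very small alpha.
static double nb_loglik(const arma::vec& y, const arma::vec& mu, double alpha) {
  double ll = 0.0;
  if (alpha < 1e-12) {
    for (arma::uword i = 0; i < y.n_elem; ++i)
      ll += R::dpois(y[i], std::max(mu[i], MU_FLOOR), 1);
  } else {
    double size = 1.0 / alpha;
    for (arma::uword i = 0; i < y.n_elem; ++i)
      ll += R::dnbinom_mu(y[i], size, std::max(mu[i], MU_FLOOR), 1);
  }
  return ll;
}

// Same up to terms constant in (beta, alpha); used inside optimisation.
static double nb_loglik_kernel(const arma::vec& y, const arma::vec& mu,
                               double alpha) {
  double size = 1.0 / std::max(alpha, 1e-12);
  double lgs = std::lgamma(size);
  double ll = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    double m = std::max(mu[i], MU_FLOOR);
    ll += std::lgamma(y[i] + size) - lgs + size * std::log(size / (size + m)) +
      y[i] * std::log(m / (size + m));
  }
  return ll;
}

// IRLS for an NB GLM with log link, fixed dispersion, offset = log size
// factors. beta is used as warm start when finite. Returns convergence flag.
static bool nb_irls(const arma::vec& y, const arma::mat& X,
                    const arma::vec& offset, double alpha, arma::vec& beta,
                    int maxit = 50, double tol = 1e-10) {
  const arma::uword p = X.n_cols;
  if (beta.n_elem != p || !beta.is_finite()) {
    // init from a rough log-linear regression
    arma::vec z0 = arma::log(y + 0.5) - offset;
    beta = arma::solve(X.t() * X + 1e-8 * arma::eye(p, p), X.t() * z0);
  }
  bool converged = false;
  for (int it = 0; it < maxit; ++it) {
    arma::vec eta = X * beta + offset;
    eta = arma::clamp(eta, -30.0, 30.0);
    arma::vec mu = arma::exp(eta);
    mu.transform([](double v) { return std::max(v, MU_FLOOR); });
    arma::vec w = mu / (1.0 + alpha * mu);
    arma::vec z = (eta - offset) + (y - mu) / mu;
    arma::mat Xw = X.each_col() % w;
    arma::mat A = X.t() * Xw;
    arma::vec b = Xw.t() * z;
    arma::vec beta_new;
    bool ok = arma::solve(beta_new, A + 1e-10 * arma::eye(p, p), b);
    if (!ok || !beta_new.is_finite()) return false;
    double step = arma::abs(beta_new - beta).max();
    beta = beta_new;
    if (step < tol * (1.0 + arma::abs(beta).max())) {
      converged = true;
      break;
    }
  }
  return converged;
}

static double profile_ll(const arma::vec& y, const arma::mat& X,
                         const arma::vec& offset, double log_alpha,
                         arma::vec& beta) {
  double alpha = std::exp(log_alpha);
  nb_irls(y, X, offset, alpha, beta, 25, 1e-7);
  arma::vec mu = arma::exp(arma::clamp(X * beta + offset, -30.0, 30.0));
  return nb_loglik_kernel(y, mu, alpha);
}

// Golden-section maximisation of f over [lo, hi] (log-alpha scale).
template <typename F>
static double golden_max(F f, double lo, double hi, double tol = 5e-3) {
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double a = lo, b = hi;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = f(x1), f2 = f(x2);
  while (b - a > tol) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a); f2 = f(x2);
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a); f1 = f(x1);
    }
  }
  return 0.5 * (a + b);
}

// [[Rcpp::export]]
List nb_glm_fit_cpp(const arma::vec& y, const arma::mat& X,
                    const arma::vec& offset, double alpha) {
  arma::vec beta;
  bool conv = nb_irls(y, X, offset, alpha, beta);
  arma::vec eta = arma::clamp(X * beta + offset, -30.0, 30.0);
  arma::vec mu = arma::exp(eta);
  arma::vec w = mu / (1.0 + alpha * mu);
  arma::mat info = X.t() * (X.each_col() % w);
  arma::mat vcov;
  bool ok = arma::inv_sympd(vcov, info + 1e-12 * arma::eye(X.n_cols, X.n_cols));
  arma::vec se(X.n_cols);
  se.fill(NA_REAL);
  if (ok) se = arma::sqrt(vcov.diag());
  return List::create(_["beta"] = beta, _["se"] = se, _["mu"] = mu,
                      _["loglik"] = nb_loglik(y, mu, alpha),
                      _["converged"] = conv);
}

// Taxon-wise maximum-likelihood dispersions (profile likelihood in beta),
// counts: samples x taxa.
// [[Rcpp::export]]
arma::vec nb_ml_dispersions_cpp(const arma::mat& counts, const arma::mat& X,
                                const arma::vec& offset,
                                double log_alpha_lo, double log_alpha_hi) {
  arma::uword m = counts.n_cols;
  arma::vec out(m);
  for (arma::uword j = 0; j < m; ++j) {
    arma::vec y = counts.col(j);
    if (arma::accu(y) <= 0) { out[j] = NA_REAL; continue; }
    arma::vec beta;
    auto f = [&](double la) { return profile_ll(y, X, offset, la, beta); };
    out[j] = golden_max(f, log_alpha_lo, log_alpha_hi);
  }
  return out;
}

// Posterior-mode dispersions: maximise profile loglik minus a squared
// log-scale penalty toward the trend value.
// [[Rcpp::export]]
arma::vec nb_map_dispersions_cpp(const arma::mat& counts, const arma::mat& X,
                                 const arma::vec& offset,
                                 const arma::vec& log_alpha_trend,
                                 double prior_var,
                                 double log_alpha_lo, double log_alpha_hi) {
  arma::uword m = counts.n_cols;
  arma::vec out(m);
  for (arma::uword j = 0; j < m; ++j) {
    arma::vec y = counts.col(j);
    if (arma::accu(y) <= 0) { out[j] = NA_REAL; continue; }
    double lat = log_alpha_trend[j];
    arma::vec beta;
    auto f = [&](double la) {
      double pen = (la - lat) * (la - lat) / (2.0 * prior_var);
      return profile_ll(y, X, offset, la, beta) - pen;
    };
    out[j] = golden_max(f, log_alpha_lo, log_alpha_hi);
  }
  return out;
}

// Final Wald fits for all taxa at fixed per-taxon dispersions.
// Returns p x m coefficient and SE matrices plus convergence flags.
// [[Rcpp::export]]
List nb_wald_fits_cpp(const arma::mat& counts, const arma::mat& X,
                      const arma::vec& offset, const arma::vec& alpha) {
  arma::uword m = counts.n_cols, p = X.n_cols;
  arma::mat beta_mat(p, m), se_mat(p, m);
  beta_mat.fill(NA_REAL);
  se_mat.fill(NA_REAL);
  LogicalVector conv(m);
  for (arma::uword j = 0; j < m; ++j) {
    arma::vec y = counts.col(j);
    if (arma::accu(y) <= 0 || !std::isfinite(alpha[j])) {
      conv[j] = false;
      continue;
    }
    arma::vec beta;
    bool ok = nb_irls(y, X, offset, alpha[j], beta);
    arma::vec mu = arma::exp(arma::clamp(X * beta + offset, -30.0, 30.0));
    arma::vec w = mu / (1.0 + alpha[j] * mu);
    arma::mat info = X.t() * (X.each_col() % w);
    arma::mat vcov;
    bool inv_ok = arma::inv_sympd(vcov,
                                  info + 1e-12 * arma::eye(p, p));
    if (ok && inv_ok && beta.is_finite() && arma::abs(beta).max() < 30.0) {
      beta_mat.col(j) = beta;
      se_mat.col(j) = arma::sqrt(vcov.diag());
      conv[j] = true;
    } else {
      conv[j] = false;
    }
  }
  return List::create(_["beta"] = beta_mat, _["se"] = se_mat,
                      _["converged"] = conv);
}
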