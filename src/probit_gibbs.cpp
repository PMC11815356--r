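// Gibbs sampler for Bayesian probit regression with a site random intercept
// and optional spike-and-slab selection on designated columns.
//
// Latent-variable augmentation: z_i | y_i ~ N(x_i'beta + a_{s(i)}, 1)
// truncated to (0, inf) if y_i = 1, (-inf, 0] otherwise. Conjugate normal
// updates for beta and the site effects; inverse-gamma for the site variance.
// Selection columns carry an exact point-mass-at-zero spike: gamma_k is
// updated from the marginal slab-vs-spike odds with beta_k integrated out,
// then the active coefficients are redrawn jointly.
//
// Uses R's RNG so results are reproducible via set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// N(mu, 1) truncated to (0, inf) when pos, (-inf, 0] otherwise,
// via inverse-CDF with clamped tail probabilities
static double rtruncnorm01(double mu, bool pos) {
  double u = unif_rand();
  double p;
  if (pos) {
    double lo = R::pnorm(-mu, 0.0, 1.0, 1, 0);
    p = lo + u * (1.0 - lo);
  } else {
    double hi = R::pnorm(-mu, 0.0, 1.0, 1, 0);
    p = u * hi;
  }
  if (p < 1e-15) p = 1e-15;
  if (p > 1.0 - 1e-15) p = 1.0 - 1e-15;
  return mu + R::qnorm(p, 0.0, 1.0, 1, 0);
}

// [[Rcpp::export(name = ".probit_gibbs_cpp")]]
List probit_gibbs_cpp(const arma::mat& X, const arma::ivec& y,
                      const arma::ivec& site, int n_sites,
                      const arma::vec& slab_var, const arma::uvec& select,
                      double incl_pi, double ig_shape, double ig_scale,
                      double sigma2_fixed, // < 0 means: sample sigma2
                      int n_warmup, int n_samples, int thin) {
  const int n = X.n_rows, p = X.n_cols;
  const int n_iter = n_warmup + n_samples * thin;

  arma::vec beta(p, arma::fill::zeros);
  arma::uvec gamma(p, arma::fill::ones); // inactive only possible if select
  arma::vec a(n_sites, arma::fill::zeros);
  double sigma2 = (sigma2_fixed >= 0.0) ? sigma2_fixed : 1.0;
  arma::vec z(n, arma::fill::zeros);

  arma::mat beta_out(n_samples, p), a_out(n_samples, n_sites);
  arma::imat gamma_out(n_samples, p);
  arma::vec sigma2_out(n_samples);

  // per-site row indices
  std::vector<std::vector<arma::uword>> site_rows(n_sites);
  for (int i = 0; i < n; ++i) site_rows[site[i]].push_back(i);

  arma::vec xss(p); // column sums of squares
  for (int j = 0; j < p; ++j) xss[j] = arma::dot(X.col(j), X.col(j));

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    // 1. latent z
    arma::vec eta = X * beta;
    for (int i = 0; i < n; ++i) {
      eta[i] += a[site[i]];
      z[i] = rtruncnorm01(eta[i], y[i] == 1);
    }

    arma::vec resid_site = z; // z minus site effects
    for (int i = 0; i < n; ++i) resid_site[i] -= a[site[i]];

    // 2. spike-and-slab indicators (marginalized over beta_k)
    arma::vec res = resid_site - X * beta;
    for (int j = 0; j < p; ++j) {
      if (!select[j]) continue;
      arma::vec rj = res + X.col(j) * beta[j];
      double s = xss[j], v = slab_var[j];
      double m = arma::dot(X.col(j), rj);
      double log_odds = std::log(incl_pi / (1.0 - incl_pi))
        - 0.5 * std::log1p(v * s) + 0.5 * v * m * m / (1.0 + v * s);
      double pr = 1.0 / (1.0 + std::exp(-log_odds));
      bool on = unif_rand() < pr;
      gamma[j] = on ? 1 : 0;
      if (on) {
        double post_var = 1.0 / (s + 1.0 / v);
        beta[j] = R::rnorm(m * post_var, std::sqrt(post_var));
      } else {
        beta[j] = 0.0;
      }
      res = rj - X.col(j) * beta[j];
    }

    // 3. joint draw of active beta
    arma::uvec act = arma::find(gamma == 1);
    if (act.n_elem > 0) {
      arma::mat Xa = X.cols(act);
      arma::mat prec = Xa.t() * Xa;
      for (arma::uword k = 0; k < act.n_elem; ++k)
        prec(k, k) += 1.0 / slab_var[act[k]];
      arma::mat L = arma::chol(prec, "lower");
      arma::vec mu = arma::solve(arma::trimatu(L.t()),
                     arma::solve(arma::trimatl(L), Xa.t() * resid_site));
      arma::vec zdraw(act.n_elem);
      for (arma::uword k = 0; k < act.n_elem; ++k) zdraw[k] = norm_rand();
      arma::vec ba = mu + arma::solve(arma::trimatu(L.t()), zdraw);
      beta.zeros();
      for (arma::uword k = 0; k < act.n_elem; ++k) beta[act[k]] = ba[k];
    } else {
      beta.zeros();
    }

    // 4. site effects
    arma::vec res2 = z - X * beta;
    if (sigma2_fixed == 0.0) {
      a.zeros();
    } else {
      for (int s = 0; s < n_sites; ++s) {
        double ns = (double)site_rows[s].size();
        double sum = 0.0;
        for (arma::uword idx : site_rows[s]) sum += res2[idx];
        double prec = ns + 1.0 / sigma2;
        a[s] = R::rnorm(sum / prec, std::sqrt(1.0 / prec));
      }
    }

    // 5. site variance
    if (sigma2_fixed < 0.0) {
      double ssa = arma::dot(a, a);
      double shape = ig_shape + 0.5 * n_sites;
      double rate = ig_scale + 0.5 * ssa;
      sigma2 = rate / R::rgamma(shape, 1.0);
    }

    if (it >= n_warmup && (it - n_warmup) % thin == 0) {
      beta_out.row(kept) = beta.t();
      for (int j = 0; j < p; ++j) gamma_out(kept, j) = gamma[j];
      a_out.row(kept) = a.t();
      sigma2_out[kept] = sigma2;
      ++kept;
      if (kept == n_samples) break;
    }
  }

  return List::create(_["beta"] = beta_out, _["gamma"] = gamma_out,
                      _["a"] = a_out, _["sigma2"] = sigma2_out);
}
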