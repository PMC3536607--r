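#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for weighted BayesC.
//
// Model: y_i = mu + sum_j z_ij u_j + e_i,  Var(e_i) = sigma2_e / w_i,
// u_j = 0 with probability pi, u_j ~ N(0, sigma2_u) otherwise (common
// variance).  Variances get scaled-inverse-chi-square full conditionals
// unless fixed_variances is set.  Uses R's RNG, so set.seed() upstream
// makes the whole chain reproducible.
//
// [[Rcpp::export(name = ".bayesc_gibbs")]]
List bayesc_gibbs(NumericVector y, NumericMatrix Z, NumericVector w,
                  double pi, int chain_length, int burn_in,
                  double nu_u, double nu_e,
                  double scale_u, double scale_e,
                  bool fixed_variances) {
  const int n = y.size();
  const int k = Z.ncol();
  if (Z.nrow() != n || w.size() != n)
    stop("dimension mismatch between y, Z and w");
  if (burn_in >= chain_length)
    stop("config error: burn_in must be smaller than chain_length");

  std::vector<double> u(k, 0.0), wz2(k);
  std::vector<int> incl(k, 0);
  NumericVector r = clone(y); // residual y - mu - Z u (mu starts at 0)
  double mu = 0.0;
  double s2u = scale_u, s2e = scale_e;
  double sw = 0.0;
  for (int i = 0; i < n; ++i) {
    if (w[i] <= 0) stop("input error: non-positive weight");
    sw += w[i];
  }
  const double *zbase = Z.begin();
  const double *wp = w.begin();
  for (int j = 0; j < k; ++j) {
    const double *z = zbase + (size_t)j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += wp[i] * z[i] * z[i];
    wz2[j] = s;
  }
  const double log_prior_odds =
      (pi <= 0.0) ? R_PosInf : std::log((1.0 - pi) / pi);

  std::vector<double> u_mean(k, 0.0), incl_freq(k, 0.0);
  double mu_mean = 0.0, s2u_mean = 0.0, s2e_mean = 0.0;
  int kept = 0;

  for (int it = 0; it < chain_length; ++it) {
    double *rp = r.begin();

    // intercept
    double rhs_mu = 0.0;
    for (int i = 0; i < n; ++i) rhs_mu += wp[i] * (rp[i] + mu);
    double mu_new = R::rnorm(rhs_mu / sw, std::sqrt(s2e / sw));
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) rp[i] -= dmu;
    mu = mu_new;

    // marker effects
    int m_in = 0;
    double ssq_u = 0.0;
    for (int j = 0; j < k; ++j) {
      const double *z = zbase + (size_t)j * n;
      const double uj_old = u[j];
      double rhs = 0.0;
      if (uj_old != 0.0) {
        rhs = uj_old * wz2[j];
        for (int i = 0; i < n; ++i) rhs += wp[i] * z[i] * rp[i];
      } else {
        for (int i = 0; i < n; ++i) rhs += wp[i] * z[i] * rp[i];
      }
      const double c = wz2[j] / s2e;      // information (precision units)
      const double b = rhs / s2e;         // z' R^-1 (r + z u_old)
      // marginal log-likelihood ratio, u_j integrated out
      const double q = 1.0 + c * s2u;
      const double log_lr = -0.5 * std::log(q) + 0.5 * b * b * s2u / q;
      double p_in;
      if (!R_FINITE(log_prior_odds)) {
        p_in = 1.0;
      } else {
        const double lo = log_prior_odds + log_lr;
        p_in = 1.0 / (1.0 + std::exp(-lo));
      }
      double uj_new = 0.0;
      int dj = 0;
      if (unif_rand() < p_in) {
        const double prec = c + 1.0 / s2u;
        uj_new = R::rnorm(b / prec, std::sqrt(1.0 / prec));
        dj = 1;
      }
      if (uj_new != uj_old) {
        const double du = uj_new - uj_old;
        for (int i = 0; i < n; ++i) rp[i] -= z[i] * du;
      }
      u[j] = uj_new;
      incl[j] = dj;
      if (dj) { ++m_in; ssq_u += uj_new * uj_new; }
    }

    // variance components
    if (!fixed_variances) {
      s2u = (ssq_u + nu_u * scale_u) / R::rchisq(nu_u + m_in);
      double ssq_e = 0.0;
      for (int i = 0; i < n; ++i) ssq_e += wp[i] * rp[i] * rp[i];
      s2e = (ssq_e + nu_e * scale_e) / R::rchisq(nu_e + n);
    }

    if (it >= burn_in) {
      ++kept;
      mu_mean += mu; s2u_mean += s2u; s2e_mean += s2e;
      for (int j = 0; j < k; ++j) {
        u_mean[j] += u[j];
        incl_freq[j] += incl[j];
      }
    }
  }

  NumericVector eff(k), freq(k);
  for (int j = 0; j < k; ++j) {
    eff[j] = u_mean[j] / kept;
    freq[j] = incl_freq[j] / kept;
  }
  return List::create(_["mu"] = mu_mean / kept,
                      _["effect"] = eff,
                      _["inclusion_freq"] = freq,
                      _["sigma2_u"] = s2u_mean / kept,
                      _["sigma2_e"] = s2e_mean / kept,
                      _["n_kept"] = kept);
}
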