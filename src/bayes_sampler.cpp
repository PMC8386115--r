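#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for spike-slab whole-genome regression:
//   y = X b + sum_j m_j beta_j delta_j + e
// with delta_j ~ Bernoulli(1 - pi), beta_j | delta_j=1 ~ N(0, sigma2_beta_j),
// flat priors on b, scaled-inverse-chi-square priors on the variances.
// common_variance = true gives a single marker variance (BayesC),
// false gives per-locus variances (BayesB).
// Uses R's RNG so set.seed() makes chains bit-reproducible.
//
// M must be column-centered (mean-imputed) beforehand; zero-variance columns
// are permanently excluded from the model.

// four-accumulator dot product: keeps FP association explicit so the
// compiler can use SIMD without -ffast-math
static inline double dot4(const double* a, const double* b, int n) {
  double s0 = 0, s1 = 0, s2 = 0, s3 = 0;
  int i = 0;
  for (; i + 4 <= n; i += 4) {
    s0 += a[i] * b[i];
    s1 += a[i + 1] * b[i + 1];
    s2 += a[i + 2] * b[i + 2];
    s3 += a[i + 3] * b[i + 3];
  }
  for (; i < n; ++i) s0 += a[i] * b[i];
  return (s0 + s1) + (s2 + s3);
}

static inline void axpy(double c, const double* a, double* y, int n) {
  for (int i = 0; i < n; ++i) y[i] += c * a[i];
}

// [[Rcpp::export(name = ".bayes_mixture_mcmc")]]
List bayes_mixture_mcmc(NumericVector y, NumericMatrix X, NumericMatrix M,
                        double pi, int n_iter, int burn_in, int thin,
                        double nu_beta, double s2_beta,
                        double nu_e, double s2_e,
                        bool common_variance,
                        bool fix_marker_var, bool fix_resid_var) {
  const int n = y.size();
  const int p = X.ncol();
  const int k = M.ncol();
  if (X.nrow() != n || M.nrow() != n) stop("design dimensions do not match y");
  if (burn_in >= n_iter) stop("burn_in must be < n_iter");

  std::vector<double> b(p, 0.0), beta(k, 0.0);
  std::vector<int> delta(k, 0);
  std::vector<double> sigma2_b(k, s2_beta);
  double sigma2_b_common = s2_beta;
  double sigma2_e = (fix_resid_var && s2_e > 0) ? s2_e : 1.0;
  {
    double m = mean(y), ss = 0.0;
    for (int i = 0; i < n; ++i) ss += (y[i] - m) * (y[i] - m);
    if (!fix_resid_var) sigma2_e = (n > 1) ? 0.5 * ss / (n - 1) : 1.0;
    if (!R_finite(sigma2_e) || sigma2_e <= 0) sigma2_e = 1.0;
  }

  std::vector<double> xpx(p), mpm(k);
  for (int j = 0; j < p; ++j) {
    double s = 0.0; const double* xc = &X(0, j);
    for (int i = 0; i < n; ++i) s += xc[i] * xc[i];
    xpx[j] = s;
  }
  for (int j = 0; j < k; ++j) {
    double s = 0.0; const double* mc = &M(0, j);
    for (int i = 0; i < n; ++i) s += mc[i] * mc[i];
    mpm[j] = s;
  }

  std::vector<double> e(n), xb(n, 0.0);
  for (int i = 0; i < n; ++i) e[i] = y[i];

  const int n_kept = n_iter - burn_in;
  const int n_thin = n_kept / thin;
  NumericMatrix window_draws(n_thin, k);
  NumericVector genvar_draws(n_kept), resvar_draws(n_kept);
  std::vector<double> sum_beta(k, 0.0), sum_beta2(k, 0.0), sum_delta(k, 0.0),
      sum_b(p, 0.0);
  const double log_prior_odds = std::log((1.0 - pi)) - std::log(pi > 0 ? pi : 1e-300);

  for (int iter = 0; iter < n_iter; ++iter) {
    // fixed effects, flat prior, one column at a time
    for (int j = 0; j < p; ++j) {
      if (xpx[j] <= 0) continue;
      const double* xc = &X(0, j);
      double rhs = dot4(xc, e.data(), n) + xpx[j] * b[j];
      double bnew = R::rnorm(rhs / xpx[j], std::sqrt(sigma2_e / xpx[j]));
      double d = b[j] - bnew;
      axpy(d, xc, e.data(), n);
      axpy(-d, xc, xb.data(), n);
      b[j] = bnew;
    }

    // markers in map order: joint (delta_j, beta_j) with beta marginalized
    // out of the inclusion update
    for (int j = 0; j < k; ++j) {
      if (mpm[j] <= 0) { beta[j] = 0.0; delta[j] = 0; continue; }
      double s2bj = common_variance ? sigma2_b_common : sigma2_b[j];
      const double* mc = &M(0, j);
      double rhs = dot4(mc, e.data(), n) + mpm[j] * beta[j];

      const double v0 = mpm[j] * sigma2_e;
      const double v1 = v0 + mpm[j] * mpm[j] * s2bj;
      double log_bf = 0.5 * (std::log(v0 / v1) + rhs * rhs * (1.0 / v0 - 1.0 / v1));
      double log_odds = log_prior_odds + log_bf;
      double p1 = (pi <= 0.0) ? 1.0 : 1.0 / (1.0 + std::exp(-log_odds));

      double bnew = 0.0;
      int dnew = (R::unif_rand() < p1) ? 1 : 0;
      if (dnew == 1) {
        double C = mpm[j] + sigma2_e / s2bj;
        bnew = R::rnorm(rhs / C, std::sqrt(sigma2_e / C));
      }
      if (bnew != beta[j]) axpy(beta[j] - bnew, mc, e.data(), n);
      beta[j] = bnew;
      delta[j] = dnew;
    }

    // marker effect variances: scaled-inverse-chi-square full conditionals;
    // excluded loci (BayesB) refresh from the prior
    if (!fix_marker_var) {
      if (common_variance) {
        double ssb = 0.0; int nin = 0;
        for (int j = 0; j < k; ++j) if (delta[j]) { ssb += beta[j] * beta[j]; ++nin; }
        sigma2_b_common = (nu_beta * s2_beta + ssb) / R::rchisq(nu_beta + nin);
      } else {
        for (int j = 0; j < k; ++j) {
          if (mpm[j] <= 0) continue;
          double ss = nu_beta * s2_beta + (delta[j] ? beta[j] * beta[j] : 0.0);
          sigma2_b[j] = ss / R::rchisq(nu_beta + delta[j]);
        }
      }
    }

    if (!fix_resid_var) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      sigma2_e = (sse + nu_e * s2_e) / R::rchisq((double)n + nu_e);
      if (!R_finite(sigma2_e) || sigma2_e <= 0)
        stop("residual variance diverged (non-finite) at iteration %d", iter + 1);
    }

    if (iter >= burn_in) {
      int kept = iter - burn_in;  // 0-based index among kept draws
      double gsum = 0.0, gss = 0.0;
      for (int i = 0; i < n; ++i) {
        double g = y[i] - xb[i] - e[i];  // = (M beta)_i
        gsum += g; gss += g * g;
      }
      double gvar = (n > 1) ? (gss - gsum * gsum / n) / (n - 1) : 0.0;
      genvar_draws[kept] = gvar;
      resvar_draws[kept] = sigma2_e;
      for (int j = 0; j < k; ++j) {
        sum_beta[j] += beta[j];
        sum_beta2[j] += beta[j] * beta[j];
        sum_delta[j] += delta[j];
      }
      for (int j = 0; j < p; ++j) sum_b[j] += b[j];
      if ((kept + 1) % thin == 0) {
        int row = (kept + 1) / thin - 1;
        if (row < n_thin)
          for (int j = 0; j < k; ++j) window_draws(row, j) = beta[j];
      }
    }
  }

  NumericVector beta_mean(k), beta_sd(k), model_freq(k), b_mean(p);
  for (int j = 0; j < k; ++j) {
    beta_mean[j] = sum_beta[j] / n_kept;
    double v = sum_beta2[j] / n_kept - beta_mean[j] * beta_mean[j];
    beta_sd[j] = v > 0 ? std::sqrt(v) : 0.0;
    model_freq[j] = sum_delta[j] / n_kept;
  }
  for (int j = 0; j < p; ++j) b_mean[j] = sum_b[j] / n_kept;

  return List::create(
    _["beta_mean"] = beta_mean, _["beta_sd"] = beta_sd,
    _["model_freq"] = model_freq, _["b_mean"] = b_mean,
    _["genetic_var_draws"] = genvar_draws, _["residual_var_draws"] = resvar_draws,
    _["window_draws"] = window_draws);
}
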