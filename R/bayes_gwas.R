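# Bayesian whole-genome regression for window-based GWAS. BayesC (common
# marker variance) estimates genetic and residual variances that then serve
# as priors for BayesB (per-locus marker variances), whose thinned effect
# draws feed the window variance decomposition.

#' Configuration for the Bayesian GWAS samplers
#'
#' Defaults mirror the analysis this package implements: prior exclusion
#' probability pi = 0.9970, 41,000 MCMC samples with the first 1,000
#' discarded, and every 100th post-burn-in effect vector retained for the
#' window variance decomposition. Marker-effect and residual variances take
#' scaled-inverse-chi-square priors with `nu_beta` and `nu_e` degrees of
#' freedom. Setting `nu_beta = Inf` (or `nu_e = Inf`) pins the corresponding
#' variance at its prior scale instead of sampling it, which turns the
#' pi = 0 model into Bayesian ridge regression with a known variance ratio.
#'
#' @param pi Prior probability that a marker is excluded from the model.
#' @param n_iter Total MCMC iterations.
#' @param burn_in Discarded initial iterations.
#' @param thin_for_windows Keep every `thin`-th post-burn-in effect vector.
#' @param nu_beta,nu_e Prior degrees of freedom for the marker-effect and
#'   residual variances.
#' @return A validated list of class `gwas_config`.
#' @export
gwas_config <- function(pi = 0.9970, n_iter = 41000, burn_in = 1000,
                        thin_for_windows = 100, nu_beta = 4, nu_e = 4) {
  stopifnot(pi >= 0, pi < 1, burn_in >= 0, burn_in < n_iter, thin_for_windows >= 1,
            nu_beta > 2 || is.infinite(nu_beta), nu_e > 0 || is.infinite(nu_e))
  structure(list(pi = pi, n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin_for_windows = as.integer(thin_for_windows),
                 nu_beta = nu_beta, nu_e = nu_e),
            class = "gwas_config")
}

#' Mean-impute and center a dosage matrix
#'
#' Missing dosages are replaced by the marker's mean dosage (2p) and each
#' column is centered on that mean, the coding the genomic model expects.
#'
#' @param genotypes Animals x markers dosage matrix (`NA` missing).
#' @return Numeric matrix of centered dosages.
#' @export
center_dosage <- function(genotypes) {
  M <- apply(genotypes, 2, function(col) {
    mu <- mean(col, na.rm = TRUE)
    if (is.nan(mu)) mu <- 0
    col[is.na(col)] <- mu
    col - mu
  })
  matrix(as.numeric(M), nrow = nrow(genotypes), dimnames = dimnames(genotypes))
}

# Sum over markers of 2 p_j (1 - p_j), the heterozygosity normalizer that
# converts a total genetic variance into a per-locus effect variance.
sum_2pq <- function(genotypes) {
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  s <- sum(2 * p * (1 - p), na.rm = TRUE)
  if (s <= 0) stop("all markers are monomorphic; cannot scale marker variance")
  s
}

# Per-locus prior scale from a total genetic variance under the mixture prior:
# S2_beta = V_g (nu-2)/nu / ((1-pi) sum_j 2 p_j q_j).
marker_prior_scale <- function(genetic_variance, genotypes, pi, nu_beta) {
  dffac <- if (is.infinite(nu_beta)) 1 else (nu_beta - 2) / nu_beta
  genetic_variance * dffac / ((1 - pi) * sum_2pq(genotypes))
}

#' Low-level spike-slab sampler with explicit variance scales
#'
#' Direct access to the Gibbs sampler behind [fit_bayes_c()] and
#' [fit_bayes_b()], with the marker-effect and residual variance prior scales
#' supplied explicitly. With `config` built using `nu_beta = Inf` /
#' `nu_e = Inf` the corresponding variance is pinned at its scale rather than
#' sampled; combined with `pi = 0` this yields Bayesian ridge regression with
#' a known variance ratio, a useful closed-form cross-check.
#'
#' @inheritParams fit_bayes_c
#' @param s2_beta,s2_e Prior scale of the marker-effect and residual
#'   variances.
#' @param common_variance One shared marker variance (BayesC-style) instead
#'   of per-locus variances.
#' @return Raw sampler output: `beta_mean`, `beta_sd`, `model_freq`,
#'   `b_mean`, `genetic_var_draws`, `residual_var_draws`, `window_draws`.
#' @export
bayes_mixture <- function(y, X, genotypes, config, s2_beta, s2_e,
                          common_variance = FALSE) {
  run_mixture(y, X, genotypes, config, s2_beta, s2_e, common_variance)
}

run_mixture <- function(y, X, genotypes, config, s2_beta, s2_e, common_variance,
                        fix_marker_var = is.infinite(config$nu_beta),
                        fix_resid_var = is.infinite(config$nu_e)) {
  if (any(!is.finite(y))) stop("y contains non-finite values; drop missing records upstream")
  M <- center_dosage(genotypes)
  X <- as.matrix(X)
  .bayes_mixture_mcmc(as.numeric(y), X, M, config$pi, config$n_iter,
                      config$burn_in, config$thin_for_windows,
                      if (is.infinite(config$nu_beta)) 0 else config$nu_beta, s2_beta,
                      if (is.infinite(config$nu_e)) 0 else config$nu_e, s2_e,
                      common_variance, fix_marker_var, fix_resid_var)
}

#' BayesC: genetic and residual variance estimation
#'
#' Single-site Gibbs sampling of the spike-slab model with a common marker
#' variance. The genetic variance of a draw is the variance across animals of
#' the sampled genomic values; posterior means of the genetic and residual
#' variance draws are returned, to be used as priors for [fit_bayes_b()].
#'
#' @param y Numeric trait vector (no missing values).
#' @param X Fixed-effect design matrix (including intercept; see
#'   [trait_design()]).
#' @param genotypes Animals x markers dosage matrix.
#' @param config A [gwas_config()]; `pi` defaults to the same mixture
#'   probability as BayesB.
#' @return List of class `variance_estimates`: `genetic_variance`,
#'   `residual_variance`.
#' @export
fit_bayes_c <- function(y, X, genotypes, config = gwas_config()) {
  vy <- var(y)
  s2_beta <- marker_prior_scale(0.5 * vy, genotypes, config$pi, config$nu_beta)
  s2_e <- 0.5 * vy * resid_scale_factor(config$nu_e)
  fit <- run_mixture(y, X, genotypes, config, s2_beta, s2_e, common_variance = TRUE)
  structure(list(genetic_variance = mean(fit$genetic_var_draws),
                 residual_variance = mean(fit$residual_var_draws)),
            class = "variance_estimates")
}

# Prior scale giving a scaled-inv-chi-square distribution whose mean equals
# the supplied estimate (mean = nu S2 / (nu - 2)); with nu <= 2 or Inf the
# estimate is used directly.
resid_scale_factor <- function(nu) if (is.finite(nu) && nu > 2) (nu - 2) / nu else 1

#' BayesB: marker-effect estimation with per-locus variances
#'
#' Single-site Gibbs sampling of the spike-slab model in which each included
#' marker carries its own scaled-inverse-chi-square effect variance. The
#' joint (inclusion, effect) update marginalizes the effect out of the
#' inclusion probability. Variance priors are derived from BayesC estimates:
#' the per-locus scale spreads the genetic variance over the expected
#' `(1-pi) k` included loci weighted by heterozygosity.
#'
#' @inheritParams fit_bayes_c
#' @param priors A `variance_estimates` object from [fit_bayes_c()].
#' @return List of class `chain_summary`: posterior mean and sd of each
#'   marker effect, per-marker model frequency, fixed-effect posterior means,
#'   genetic/residual variance draws, and `window_draws` (thinned draws x
#'   markers effect matrix for the window decomposition).
#' @export
fit_bayes_b <- function(y, X, genotypes, config = gwas_config(), priors) {
  stopifnot(inherits(priors, "variance_estimates"))
  stopifnot(priors$genetic_variance > 0, priors$residual_variance > 0)
  s2_beta <- marker_prior_scale(priors$genetic_variance, genotypes,
                                config$pi, config$nu_beta)
  s2_e <- priors$residual_variance * resid_scale_factor(config$nu_e)
  fit <- run_mixture(y, X, genotypes, config, s2_beta, s2_e, common_variance = FALSE)
  colnames(fit$window_draws) <- colnames(genotypes)
  structure(list(
    marker_id = colnames(genotypes),
    beta_mean = setNames(as.numeric(fit$beta_mean), colnames(genotypes)),
    beta_sd = setNames(as.numeric(fit$beta_sd), colnames(genotypes)),
    model_freq = setNames(as.numeric(fit$model_freq), colnames(genotypes)),
    b_mean = setNames(as.numeric(fit$b_mean), colnames(X)),
    genetic_var_draws = as.numeric(fit$genetic_var_draws),
    residual_var_draws = as.numeric(fit$residual_var_draws),
    window_draws = fit$window_draws,
    config = config
  ), class = "chain_summary")
}

#' Genomic values from a marker-effect vector
#'
#' @param genotypes Animals x markers dosage matrix (centered internally).
#' @param effects Marker-effect vector (one draw or a posterior mean).
#' @return Per-animal genomic values (centered dosages times effects).
#' @export
genetic_values <- function(genotypes, effects) {
  stopifnot(ncol(genotypes) == length(effects))
  drop(center_dosage(genotypes) %*% effects)
}

#' Build the response and fixed-effect design for one trait
#'
#' Assembles `y` and `X` for the genomic model from a phenotype table: an
#' intercept, sex and hatch as factors, and BW42 as a covariate for the
#' weight traits (THW, BTW, ABFW, DRW). Rows with missing trait, fixed-effect
#' or covariate values are dropped.
#'
#' @param phenotypes A phenotype table from [read_phenotypes()] or
#'   [simulate_population()].
#' @param trait Trait column name (e.g. `"abfw_g"`, `"abf_pct"`).
#' @return List: `y`, `X` (model matrix), `animal_id` of retained rows, and
#'   the logical `keep` index into the input table.
#' @export
trait_design <- function(phenotypes, trait) {
  stopifnot(trait %in% names(phenotypes))
  use_bw42 <- trait %in% WEIGHT_TRAITS
  needed <- c(trait, "sex", "hatch", if (use_bw42) "bw42_g")
  keep <- complete.cases(phenotypes[needed])
  df <- phenotypes[keep, , drop = FALSE]
  fml <- if (use_bw42) ~ sex + hatch + bw42_g else ~ sex + hatch
  X <- model.matrix(fml, data = df)
  list(y = df[[trait]], X = X, animal_id = df$animal_id, keep = keep)
}
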