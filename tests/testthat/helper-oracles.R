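# Independent oracles and small fixture builders shared across tests.

# HWE exact p-value by direct enumeration with the closed-form conditional
# probability of each heterozygote count (lgamma arithmetic); independent of
# the recurrence used by hwe_exact_test().
hwe_enumeration_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- 2 * n_hom_alt + n_het
  rare <- min(n_alt, 2 * n - n_alt)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    haa <- (rare - h) / 2
    hrr <- n - h - haa
    lgamma(n + 1) - lgamma(hrr + 1) - lgamma(h + 1) - lgamma(haa + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  sum(p[p <= obs * (1 + 1e-12)])
}

# Generalized least squares with known variance components: the oracle the
# mixed-model fit must reproduce when its variance ratio is fixed at truth.
gls_oracle <- function(y, X, group, sigma2_u, sigma2_e) {
  Z <- model.matrix(~ 0 + factor(group))
  V <- sigma2_e * diag(length(y)) + sigma2_u * tcrossprod(Z)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  list(beta = drop(beta), vcov = solve(XtViX))
}

# A balanced phenotype-like frame with q dam families, 2 sexes, 5 hatches.
make_family_frame <- function(n, q, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    animal_id = sprintf("an%04d", seq_len(n)),
    sex = factor(rep_len(c("F", "M"), n)),
    hatch = factor(rep_len(1:5, n)),
    dam_family = factor(rep_len(sprintf("fam%03d", seq_len(q)), n)),
    stringsAsFactors = FALSE
  )
}

# Simulate the single-SNP association cohort: n animals in q dam families,
# one SNP at alt frequency p with additive effect 'effect' on the trait,
# family SD sigma_u, residual SD sigma_e. Returns a phenotype table plus a
# one-column genotype matrix, ready for fit_lmm().
make_assoc_cohort <- function(n = 237, q = 41, p = 0.236, effect = -3.43,
                              sigma_u = 4, sigma_e = 10, base = 47) {
  fr <- make_family_frame(n, q)
  snp <- rbinom(n, 2, p)
  u <- rnorm(q, 0, sigma_u)
  bw42 <- rnorm(n, 2220, 150)
  y <- base + 3 * (fr$sex == "M") + as.numeric(fr$hatch) + 0.005 * (bw42 - 2220) +
    effect * snp + u[as.integer(fr$dam_family)] + rnorm(n, 0, sigma_e)
  pheno <- data.frame(fr, bw42_g = bw42, btw_g = NA_real_, bt_pct = NA_real_,
                      thw_g = NA_real_, th_pct = NA_real_, drw_g = NA_real_,
                      dr_pct = NA_real_, abfw_g = y, abf_pct = NA_real_,
                      stringsAsFactors = FALSE)
  G <- matrix(as.integer(snp), ncol = 1,
              dimnames = list(fr$animal_id, "focal_snp"))
  list(phenotypes = pheno, genotypes = G)
}

extdata <- function(name) {
  path <- system.file("extdata", name, package = "fatmap")
  stopifnot(nzchar(path))
  path
}
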