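test_that("mixed-model estimates with a known variance ratio equal the GLS oracle", {
  set.seed(51)
  n <- 12
  group <- factor(rep(1:3, each = 4))
  X <- cbind(1, rnorm(n), rbinom(n, 2, 0.4))
  colnames(X) <- c("(Intercept)", "cov", "snp")
  sigma2_u <- 4; sigma2_e <- 2
  u <- rnorm(3, 0, sqrt(sigma2_u))
  y <- drop(X %*% c(10, 1.5, -2)) + u[as.integer(group)] + rnorm(n, 0, sqrt(sigma2_e))

  fit <- reml_lmm(y, X, group, lambda = sigma2_u / sigma2_e)
  oracle <- gls_oracle(y, X, group, sigma2_u, sigma2_e)
  expect_equal(fit$coefficients$estimate, unname(oracle$beta), tolerance = 1e-7)

  # zero family variance: the fixed-ratio fit at 0 is exactly OLS
  fit0 <- reml_lmm(y, X, group, lambda = 0)
  ols <- lm.fit(X, y)
  expect_equal(fit$coefficients$term, colnames(X))
  expect_equal(fit0$coefficients$estimate, unname(ols$coefficients),
               tolerance = 1e-9)
})

test_that("the REML profile optimum beats a 50-point grid and matches lmerTest", {
  skip_if_not_installed("lmerTest")
  set.seed(52)
  n <- 200; q <- 25
  group <- factor(rep_len(1:q, n))
  X <- cbind(1, rnorm(n), rbinom(n, 2, 0.3))
  colnames(X) <- c("(Intercept)", "cov", "snp")
  u <- rnorm(q, 0, 2)
  y <- drop(X %*% c(5, 1, -1)) + u[as.integer(group)] + rnorm(n, 0, 3)
  fit <- reml_lmm(y, X, group)

  prof <- function(l) fatmap:::lmm_profile(l, y, X, group)$ll
  grid <- 10^seq(-6, 3, length.out = 50)
  expect_true(all(fit$logLik >= vapply(grid, prof, numeric(1)) - 1e-6))

  lf <- lmerTest::lmer(y ~ 0 + X + (1 | group), REML = TRUE)
  s <- summary(lf)$coefficients
  expect_equal(fit$coefficients$estimate, unname(s[, "Estimate"]), tolerance = 1e-6)
  expect_equal(fit$coefficients$se, unname(s[, "Std. Error"]), tolerance = 1e-5)
  expect_equal(fit$coefficients$df, unname(s[, "df"]), tolerance = 0.02 * n)
  expect_equal(fit$coefficients$p_value, unname(s[, "Pr(>|t|)"]), tolerance = 1e-4)
  expect_equal(fit$sigma2_e, sigma(lf)^2, tolerance = 1e-6)

  # Satterthwaite df never exceeds the fixed-model residual df
  expect_true(all(fit$coefficients$df <= n - ncol(X)))
})

test_that("additive SNP effects are antisymmetric under allele relabeling", {
  set.seed(53)
  cohort <- make_assoc_cohort()
  res <- fit_lmm(cohort$phenotypes, "abfw_g", cohort$genotypes, "focal_snp")
  flipped <- cohort$genotypes
  flipped[, 1] <- 2L - flipped[, 1]
  # same variance ratio: the GLS solution flips sign exactly
  res_fix <- fit_lmm(cohort$phenotypes, "abfw_g", flipped, "focal_snp",
                     lambda = attr(res, "fit")$lambda)
  expect_equal(res_fix$estimate, -res$estimate, tolerance = 1e-12)
  expect_equal(res_fix$se, res$se, tolerance = 1e-12)
  # re-estimated ratio agrees to optimizer precision
  res_f <- fit_lmm(cohort$phenotypes, "abfw_g", flipped, "focal_snp")
  expect_equal(res_f$estimate, -res$estimate, tolerance = 1e-6)
  expect_equal(res_f$p_value, res$p_value, tolerance = 1e-5)
  expect_equal(res$n_used, 237L)
})

test_that("genotypic coding contrasts genotype classes against the reference homozygote", {
  expect_equal(colnames(genotypic_coding(c(0, 1, 2))), c("GE1", "GE2"))
  expect_equal(colnames(genotypic_coding(c(0, 1, 0))), "GE1")
  expect_error(genotypic_coding(c(1, 1, 2)), "no reference homozygotes")

  set.seed(54)
  cohort <- make_assoc_cohort(effect = -5, sigma_e = 4)
  res <- fit_lmm(cohort$phenotypes, "abfw_g", cohort$genotypes, "focal_snp",
                 model = "genotypic")
  expect_equal(res$term, c("GE1", "GE2"))
  # under additivity the hom-alt contrast is about twice the het contrast
  expect_lt(res$estimate[1], 0)
  expect_lt(res$estimate[2], res$estimate[1])

  # a SNP with no alt homozygotes yields a single contrast row
  g2 <- cohort$genotypes
  g2[g2 == 2L] <- 1L
  res1 <- fit_lmm(cohort$phenotypes, "abfw_g", g2, "focal_snp", model = "genotypic")
  expect_equal(res1$term, "GE1")
})

test_that("confounded designs and degenerate traits fail loudly", {
  set.seed(55)
  cohort <- make_assoc_cohort()
  # SNP identical to the hatch-2 indicator: aliased with a fixed effect
  confounded <- cohort$genotypes
  confounded[, 1] <- as.integer(cohort$phenotypes$hatch == "2")
  expect_error(
    fit_lmm(cohort$phenotypes, "abfw_g", confounded, "focal_snp"),
    "aliased.*focal_snp"
  )
  flat <- cohort$phenotypes
  flat$abfw_g <- 1
  expect_error(fit_lmm(flat, "abfw_g", cohort$genotypes, "focal_snp"),
               "zero variance")
})

test_that("the homozygote-deficit screen reproduces the reported expectation", {
  scr <- lethal_recessive_screen(genotype_counts(172, 65, 0))
  expect_equal(scr$alt_freq_used, 0.137)
  expect_equal(round(scr$expected_hom_alt, 2), 4.45)
  expect_true(scr$flagged)
  expect_equal(scr$prob_zero_given_hwe, (1 - 0.137^2)^237, tolerance = 1e-12)

  full <- lethal_recessive_screen(genotype_counts(172, 65, 0), round_freq = FALSE)
  expect_equal(round(full$expected_hom_alt, 2), 4.46)

  expect_false(lethal_recessive_screen(genotype_counts(146, 70, 21))$flagged)
  none <- lethal_recessive_screen(genotype_counts(100, 0, 0))
  expect_equal(none$expected_hom_alt, 0)
  expect_equal(none$prob_zero_given_hwe, 1)
  expect_false(none$flagged)

  strict <- lethal_recessive_screen(genotype_counts(172, 65, 0),
                                    require_hwe_deviation = TRUE)
  expect_true(strict$flagged)  # exact HWE p ~ 0.011 < 0.05
})

test_that("weight traits take BW42 as covariate and percent traits do not", {
  set.seed(56)
  cohort <- make_assoc_cohort()
  td_w <- trait_design(cohort$phenotypes, "abfw_g")
  expect_true("bw42_g" %in% colnames(td_w$X))
  ph <- cohort$phenotypes
  ph$abf_pct <- 100 * ph$abfw_g / ph$bw42_g
  td_p <- trait_design(ph, "abf_pct")
  expect_false("bw42_g" %in% colnames(td_p$X))
})
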