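test_that("configuration validation catches infeasible designs", {
  expect_error(sim_config(qtl_h2 = 0.6, family_variance_fraction = 0.3,
                          bw42_share = 0.2), "infeasible variance budget")
  expect_error(sim_config(n_markers = 10, n_qtl = 10))
  expect_s3_class(sim_config(), "sim_config")
})

test_that("seed-fixed simulations are bit-reproducible with the expected design structure", {
  cfg <- sim_config(n_sires = 5, n_dams = 12, offspring_per_dam = 6,
                    n_markers = 120, n_chromosomes = 2, n_qtl = 8)
  a <- simulate_population(cfg, seed = 99)
  b <- simulate_population(cfg, seed = 99)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth$effects, b$truth$effects)

  expect_equal(nrow(a$genotypes), 12 * 6)
  expect_equal(nlevels(a$phenotypes$dam_family), 12)
  expect_equal(nlevels(a$phenotypes$hatch), 5)
  expect_equal(sort(unique(as.character(a$phenotypes$sex))), c("F", "M"))
  # percent traits are percent of BW42 by construction
  expect_equal(a$phenotypes$abf_pct,
               100 * a$phenotypes$abfw_g / a$phenotypes$bw42_g)
  # focal SNP is annotated deleterious
  focal_ann <- a$annotation[a$annotation$marker_id == a$truth$focal$marker_id, ]
  expect_lte(focal_ann$sift_score, 0.05)
})

test_that("offspring dosages are Mendelian-consistent with parental genotypes", {
  sim <- simulate_population(
    sim_config(n_sires = 4, n_dams = 8, offspring_per_dam = 5, n_markers = 150,
               n_chromosomes = 3, n_qtl = 5),
    seed = 13
  )
  fd <- sim$truth$founder_dosage
  possible <- function(parent_dosage) {
    switch(parent_dosage + 1L, 0L, c(0L, 1L), 1L)  # gametes a parent can give
  }
  for (i in seq_len(nrow(sim$genotypes))) {
    d <- sim$truth$dam_of_offspring[i]
    s <- sim$truth$sire_of_dam[d]
    sire_g <- fd[s, ]
    dam_g <- fd[4 + d, ]
    child <- sim$genotypes[i, ]
    ok <- vapply(seq_along(child), function(j) {
      child[j] %in% outer(possible(sire_g[j]), possible(dam_g[j]), `+`)
    }, logical(1))
    expect_true(all(ok))
  }
})

test_that("realized allele frequencies track the configured frequencies", {
  sim <- simulate_population(
    sim_config(n_sires = 60, n_dams = 240, offspring_per_dam = 2,
               n_markers = 300, n_chromosomes = 3, n_qtl = 0),
    seed = 17
  )
  realized <- colMeans(sim$genotypes) / 2
  target <- sim$truth$p_alt
  expect_gt(cor(realized, target), 0.97)
  # 600 founder gametes + drift: deviations stay within a few binomial SEs
  expect_lt(mean(abs(realized - target)), 0.05)
})

test_that("a null architecture yields no marker-phenotype signal", {
  cfg <- sim_config(n_sires = 10, n_dams = 40, offspring_per_dam = 10,
                    n_markers = 100, n_chromosomes = 2, n_qtl = 0,
                    qtl_h2 = 0, family_variance_fraction = 0.05,
                    focal_deleterious = list(allele_freq = 0.3,
                                             additive_effect_g = 0,
                                             additive_effect_pct = 0,
                                             lethal_recessive = FALSE))
  sim <- simulate_population(cfg, seed = 23)
  cors <- suppressWarnings(cor(sim$genotypes, sim$phenotypes$abfw_g))
  expect_lt(abs(mean(cors, na.rm = TRUE)), 0.02)
  expect_lt(max(abs(cors), na.rm = TRUE), 0.25)
})

test_that("the planted abdominal-fat effect is recoverable by adjusted regression at n ~ 1000", {
  # 92 dams x 11 ~ 1012 offspring; no family effect so the OLS standard
  # error is the right yardstick for the recovery check
  cfg <- sim_config(offspring_per_dam = 11, family_variance_fraction = 0)
  sim <- simulate_population(cfg, seed = 29)
  ph <- sim$phenotypes
  d <- sim$genotypes[, sim$truth$focal$marker_id]
  fit <- lm(abfw_g ~ sex + hatch + bw42_g + d, data = cbind(ph, d = d))
  est <- coef(summary(fit))["d", ]
  expect_lt(abs(est["Estimate"] - (-3.43)), 2 * est["Std. Error"])

  # QTL variance realized within 15% of the configured per-trait budget
  g <- drop(center_dosage(sim$genotypes) %*% sim$truth$effects$thw_g)
  target <- 0.30 * 45.76^2
  expect_lt(abs(var(g) - target), 0.15 * target)
})

test_that("a lethal recessive removes alt homozygotes the screen then flags", {
  cfg <- sim_config(n_sires = 10, n_dams = 40, offspring_per_dam = 8,
                    n_markers = 80, n_chromosomes = 2, n_qtl = 0,
                    focal_deleterious = list(allele_freq = 0.35,
                                             additive_effect_g = -3.43,
                                             additive_effect_pct = -0.17,
                                             lethal_recessive = TRUE))
  sim <- simulate_population(cfg, seed = 31)
  d <- sim$genotypes[, sim$truth$focal$marker_id]
  expect_equal(sum(d == 2L), 0L)
  counts <- genotype_counts(sum(d == 0L), sum(d == 1L), sum(d == 2L))
  scr <- lethal_recessive_screen(counts)
  expect_gt(scr$expected_hom_alt, 0)
  expect_true(scr$flagged)
})

test_that("simulation files round-trip through the writers", {
  sim <- simulate_population(
    sim_config(n_sires = 3, n_dams = 6, offspring_per_dam = 4, n_markers = 40,
               n_chromosomes = 1, n_qtl = 3),
    seed = 37
  )
  out <- withr::local_tempdir()
  write_simulation(sim, out, seed = 37)
  expect_true(all(file.exists(file.path(out, c("genotypes.ped", "genotypes.map",
                                               "phenotypes.tsv", "annotation.tsv")))))
  back <- read_plink_text(file.path(out, "genotypes.ped"),
                          file.path(out, "genotypes.map"),
                          alt_alleles = sim$map$alt_allele)
  expect_identical(unname(back$genotypes), unname(sim$genotypes))
})
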