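test_that("allele frequencies reproduce reported values and always sum to one", {
  cases <- list(
    list(c(146, 70, 21), ref3 = 0.764),   # common missense at the fat locus
    list(c(1, 38, 198), alt3 = 0.916),
    list(c(10, 0, 0), ref3 = 1.000)
  )
  for (cs in cases) {
    gc <- genotype_counts(cs[[1]][1], cs[[1]][2], cs[[1]][3])
    fr <- allele_frequency(gc)
    if (!is.null(cs$ref3)) expect_equal(round(fr[["ref_freq"]], 3), cs$ref3)
    if (!is.null(cs$alt3)) expect_equal(round(fr[["alt_freq"]], 3), cs$alt3)
    expect_identical(fr[["ref_freq"]] + fr[["alt_freq"]], 1)
  }
  expect_error(genotype_counts(0, 0, 0), "n >= 1")
})

test_that("HWE exact test agrees with the enumeration oracle", {
  # modal table and sparse tables
  expect_equal(hwe_exact_test(genotype_counts(25, 50, 25)), 1.0)
  expect_equal(hwe_exact_test(genotype_counts(209, 28, 0)),
               hwe_enumeration_oracle(209, 28, 0), tolerance = 1e-12)
  p_extreme <- hwe_exact_test(genotype_counts(71, 154, 12))
  expect_lt(p_extreme, 1e-6)
  expect_equal(p_extreme, hwe_enumeration_oracle(71, 154, 12), tolerance = 1e-9)

  set.seed(42)
  for (i in 1:120) {
    n <- sample(1:200, 1)
    n_alt <- sample(0:(2 * n), 1)
    aa <- sample(0:(n_alt %/% 2), 1)
    het <- n_alt - 2 * aa
    rr <- n - aa - het
    if (rr < 0) next
    expect_equal(hwe_exact_test(genotype_counts(rr, het, aa)),
                 hwe_enumeration_oracle(rr, het, aa), tolerance = 1e-9)
  }
})

test_that("HWE chi-square cross-check matches hand arithmetic and degrades gracefully", {
  expect_equal(hwe_chi2_test(genotype_counts(25, 50, 25)), 1.0)
  # hand-computed: p = 362/474, expected (n p^2, 2npq, n q^2), 1-df chi-square
  p <- 362 / 474
  q <- 1 - p
  exp_counts <- 237 * c(p^2, 2 * p * q, q^2)
  stat <- sum((c(146, 70, 21) - exp_counts)^2 / exp_counts)
  expect_equal(hwe_chi2_test(genotype_counts(146, 70, 21)),
               pchisq(stat, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_warning(p_mono <- hwe_chi2_test(genotype_counts(10, 0, 0)), "undefined")
  expect_true(is.na(p_mono))
})

test_that("Bonferroni flags use alpha over the number of tests", {
  expect_true(bonferroni(0.0027, alpha = 0.05, m = 18))   # 0.0027 < 0.05/18
  expect_false(bonferroni(0.0028, alpha = 0.05, m = 18))
  expect_identical(bonferroni(c(0.04, 0.06), m = 1), c(TRUE, FALSE))
  expect_false(any(bonferroni(rep(1, 10))))
})

make_qc_fixture <- function() {
  # 40 animals x 20 markers with one known defect per step
  set.seed(5)
  n <- 40
  G <- sapply(rep(0.4, 20), function(p) rbinom(n, 2, p))
  colnames(G) <- sprintf("m%02d", 1:20)
  rownames(G) <- paste0("an", 1:n)
  G["an40", 6:20] <- NA                                 # bad sample: 25% call rate
  G["an1", "m02"] <- NA                                 # 1/39 missing after an40 drops
  G[, "m03"] <- c(1L, rep(0L, n - 1))                   # MAF ~0.013 -> MAF fail
  G[, "m04"] <- 0L                                      # monomorphic -> MAF fail
  G[, "m05"] <- 1L                                      # all-het -> extreme HWE
  map <- marker_map(sprintf("m%02d", 1:20),
                    c(rep("1", 19), "Z"), 1:20 * 100, "A", "G")
  list(G = G[, map$marker_id], map = map)
}

test_that("array QC applies filters in order with a faithful report", {
  fx <- make_qc_fixture()
  out <- array_qc(fx$G, fx$map)
  rep_ <- out$report
  expect_identical(rep_$step, c("sample_call_rate", "marker_call_rate", "maf",
                                "hwe", "chromosome"))
  expect_equal(rep_$removed[rep_$step == "sample_call_rate"], 1L)  # an40
  # kept + removed stays constant down the marker steps
  marker_rows <- rep_[rep_$unit == "marker", ]
  expect_identical(marker_rows$kept + marker_rows$removed, c(20L, 19L, 17L, 16L))
  expect_false("m02" %in% out$map$marker_id)  # 97.4% call rate under 98% threshold
  expect_equal(rep_$removed[rep_$step == "maf"], 2L)         # m03 and m04
  expect_equal(rep_$removed[rep_$step == "hwe"], 1L)         # all-het m05
  expect_equal(rep_$removed[rep_$step == "chromosome"], 1L)  # m20 on Z
  expect_equal(nrow(out$map), 15L)
  expect_true("m01" %in% out$map$marker_id)

  # monomorphic marker never reaches the HWE step: relax HWE to prove order
  out2 <- array_qc(fx$G, fx$map, thresholds = list(hwe_p = 0))
  expect_false("m04" %in% out2$map$marker_id)

  # idempotence
  again <- array_qc(out$genotypes, out$map)
  expect_identical(again$genotypes, out$genotypes)
  expect_identical(again$map$marker_id, out$map$marker_id)

  expect_error(array_qc(fx$G, fx$map, thresholds = list(maf = 0.6)),
               "all markers removed")
})

make_variant_fixture <- function() {
  # 6 sites: indel, triallelic, low MAF, low depth, low QUAL, one clean pass
  n <- 10
  sites <- data.frame(
    marker_id = paste0("v", 1:6),
    chromosome = "26",
    position_bp = 1:6 * 1000,
    ref_allele = c("AT", "A", "A", "A", "A", "A"),
    alt_allele = c("A", "C,G", "C", "C", "C", "C"),
    depth = c(50, 50, 50, 10, 50, 50),
    qual = c(99, 99, 99, 99, 30, 99),
    stringsAsFactors = FALSE
  )
  dos <- matrix(1L, n, 6, dimnames = list(paste0("an", 1:n), sites$marker_id))
  dos[, "v3"] <- 0L                     # monomorphic: MAF 0 < 0.05
  list(sites = sites, dosage = dos)
}

test_that("sequenced-variant filters attribute removals to the first failing predicate", {
  fx <- make_variant_fixture()
  out <- filter_sequenced_variants(fx)
  expect_identical(out$variants$sites$marker_id, "v6")
  rep_ <- setNames(out$report$removed, out$report$predicate)
  expect_equal(rep_[["indel"]], 1L)
  expect_equal(rep_[["maf"]], 1L)        # v3
  expect_equal(rep_[["biallelic"]], 1L)  # v2 passes MAF/call-rate first
  expect_equal(rep_[["depth"]], 1L)
  expect_equal(rep_[["qual"]], 1L)
  expect_equal(rep_[["kept"]], 1L)

  # empty input passes through
  empty <- list(sites = fx$sites[0, ], dosage = fx$dosage[, 0, drop = FALSE])
  out0 <- filter_sequenced_variants(empty)
  expect_equal(nrow(out0$variants$sites), 0L)

  # thresholds are inclusive: exactly MAF 0.05, depth 15, QUAL 40 is kept
  edge <- list(
    sites = data.frame(marker_id = "e1", chromosome = "1", position_bp = 1,
                       ref_allele = "A", alt_allele = "C", depth = 15, qual = 40,
                       stringsAsFactors = FALSE),
    dosage = matrix(c(1L, rep(0L, 9)), 10, 1, dimnames = list(NULL, "e1"))
  )
  kept <- filter_sequenced_variants(edge)
  expect_equal(nrow(kept$variants$sites), 1L)
})
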