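# Synthetic TT-style reference population: a sire x dam crossing design with
# full-/half-sib families and hatches, blockwise-LD founder genotypes, a
# spike-slab QTL architecture, a focal deleterious SNP with a negative
# additive effect on abdominal fat, and a dam-family random effect. Every
# downstream stage of the pipeline can be exercised against the recorded
# ground truth.

# Built-in trait scales (grams) for the simulated cohort: mean and SD of
# BW42 and the four carcass weights in a meat-type reference population.
TRAIT_SCALES <- data.frame(
  trait = c("bw42_g", "btw_g", "thw_g", "drw_g", "abfw_g"),
  mean = c(2220.30, 499.32, 309.57, 205.38, 47.10),
  sd = c(258.86, 65.56, 45.76, 31.11, 14.03),
  stringsAsFactors = FALSE
)

#' Configuration of the synthetic population
#'
#' Defaults reproduce the reference-population design the pipeline targets:
#' 20 sires crossed with 92 dams over 5 hatches, a focal predicted-
#' deleterious SNP at alt-allele frequency 0.236 with a -3.43 g additive
#' effect on abdominal fat weight (-0.17 percentage points on ABF%), a
#' spike-slab background of `n_qtl` markers explaining `qtl_h2` of each
#' trait's variance, and a dam-family random effect taking
#' `family_variance_fraction` of the variance.
#'
#' @param n_sires,n_dams,offspring_per_dam,n_hatches Mating design; dams are
#'   assigned to sires round-robin (half-sib groups), each dam produces a
#'   full-sib family.
#' @param n_chromosomes,chromosome_length_bp,n_markers Marker panel layout;
#'   markers are spread evenly over chromosomes at random positions.
#' @param ld_block_len_bp Length of the LD blocks within which founder
#'   gametes share a latent haplotype background.
#' @param ld_within_block Latent correlation of markers within a block
#'   (drives r-squared between neighbors).
#' @param n_qtl Background QTL count (markers with nonzero effects shared
#'   across traits, trait-specific scaling).
#' @param qtl_h2 Fraction of each trait's variance from background QTL.
#' @param family_variance_fraction Fraction from the dam-family effect.
#' @param bw42_share Fraction of each carcass-weight trait's variance driven
#'   by BW42 (the covariate of the association model).
#' @param focal_deleterious List: `allele_freq`, `additive_effect_g` (on
#'   ABFW), `additive_effect_pct` (implied target on ABF%, recorded in the
#'   truth), `lethal_recessive` flag.
#' @param n_decoy_deleterious Number of non-causal markers annotated as
#'   predicted deleterious.
#' @param sex_effect_g Male-minus-female effect on BW42 (g); carcass traits
#'   get a proportional direct sex effect on top of the BW42 path.
#' @param hatch_effects_g Length-`n_hatches` additive hatch effects on BW42.
#' @param residual_sd Optional fixed residual SD (g) applied to every weight
#'   trait; default `NULL` lets each trait's residual fill its remaining
#'   variance budget.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_sires = 20, n_dams = 92, offspring_per_dam = 15,
                       n_hatches = 5, n_chromosomes = 5,
                       chromosome_length_bp = 5e6, n_markers = 1000,
                       ld_block_len_bp = 5e5, ld_within_block = 0.9,
                       n_qtl = 20, qtl_h2 = 0.30,
                       family_variance_fraction = 0.10, bw42_share = 0.25,
                       focal_deleterious = list(allele_freq = 0.236,
                                                additive_effect_g = -3.43,
                                                additive_effect_pct = -0.17,
                                                lethal_recessive = FALSE),
                       n_decoy_deleterious = 10, sex_effect_g = 150,
                       hatch_effects_g = NULL, residual_sd = NULL) {
  if (is.null(hatch_effects_g)) {
    hatch_effects_g <- seq(-40, 40, length.out = n_hatches)
  }
  stopifnot(n_sires >= 1, n_dams >= n_sires, offspring_per_dam >= 1,
            n_hatches >= 1, length(hatch_effects_g) == n_hatches,
            n_markers >= n_qtl + 1, n_qtl >= 0,
            qtl_h2 >= 0, qtl_h2 <= 1,
            family_variance_fraction >= 0, family_variance_fraction <= 1,
            bw42_share >= 0, bw42_share < 1,
            ld_within_block >= 0, ld_within_block < 1,
            focal_deleterious$allele_freq > 0, focal_deleterious$allele_freq < 1)
  if (qtl_h2 + family_variance_fraction + bw42_share >= 1) {
    stop("infeasible variance budget: qtl_h2 + family_variance_fraction + bw42_share must be < 1")
  }
  structure(as.list(environment()), class = "sim_config")
}

# Draw one gamete per (individual, chromosome copy): blockwise latent-factor
# alleles. Markers in the same block share a latent normal factor with
# loading sqrt(rho), so marginal alt frequency is exactly p_j while within-
# block dosage correlation is positive; blocks are independent.
draw_founder_gametes <- function(n_gametes, p_alt, block_id, rho) {
  k <- length(p_alt)
  out <- matrix(0L, n_gametes, k)
  thr <- qnorm(p_alt)
  for (b in unique(block_id)) {
    ix <- which(block_id == b)
    u <- rnorm(n_gametes)
    z <- sqrt(rho) * u + sqrt(1 - rho) *
      matrix(rnorm(n_gametes * length(ix)), n_gametes)
    out[, ix] <- (z < rep(thr[ix], each = n_gametes)) * 1L
  }
  out
}

# Transmit one gamete from a parent's two gametes: within a block the child
# copies one parental gamete; blocks recombine freely.
transmit_gamete <- function(g1, g2, block_id) {
  out <- integer(length(g1))
  for (b in unique(block_id)) {
    ix <- which(block_id == b)
    out[ix] <- if (runif(1) < 0.5) g1[ix] else g2[ix]
  }
  out
}

#' Simulate a reference population with recorded ground truth
#'
#' Generates a marker map, founder gametes with blockwise LD, offspring
#' genotypes by Mendelian gene-dropping through the sire x dam design,
#' phenotypes under `trait = mean + sex + hatch + BW42 path + sum(a_j b_j) +
#' u_family + e`, percent traits as `100 * weight / BW42`, a VEP-style
#' annotation table marking the focal SNP (and decoys) predicted deleterious,
#' and a truth record of every generative quantity. With
#' `lethal_recessive = TRUE` the focal locus' alt-homozygote offspring are
#' re-drawn (censored before phenotyping), creating the homozygote deficit
#' the lethal screen looks for.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed; runs with the same seed are
#'   bit-reproducible.
#' @return List: `genotypes` (offspring x markers dosage matrix), `map`
#'   ([marker_map]), `phenotypes`, `annotation`, `truth`.
#' @export
simulate_population <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  cf <- config
  k <- cf$n_markers

  # --- marker map ---------------------------------------------------------
  per_chr <- diff(round(seq(0, k, length.out = cf$n_chromosomes + 1)))
  chrom <- rep(as.character(seq_len(cf$n_chromosomes)), per_chr)
  pos <- unlist(lapply(per_chr, function(m) {
    sort(sample.int(cf$chromosome_length_bp, m))
  }), use.names = FALSE)
  alleles <- t(vapply(seq_len(k), function(j) sample(c("A", "C", "G", "T"), 2),
                      character(2)))
  map <- marker_map(sprintf("snp%05d", seq_len(k)), chrom, pos,
                    alleles[, 1], alleles[, 2])
  block_id <- paste0(map$chromosome, ":",
                     (map$position_bp - 1L) %/% as.integer(cf$ld_block_len_bp))

  p_alt <- runif(k, 0.05, 0.95)
  focal_idx <- sample.int(k, 1)
  p_alt[focal_idx] <- cf$focal_deleterious$allele_freq
  focal_id <- map$marker_id[focal_idx]

  # --- founders and gene dropping ----------------------------------------
  n_founders <- cf$n_sires + cf$n_dams
  gam1 <- draw_founder_gametes(n_founders, p_alt, block_id, cf$ld_within_block)
  gam2 <- draw_founder_gametes(n_founders, p_alt, block_id, cf$ld_within_block)
  lethal <- isTRUE(cf$focal_deleterious$lethal_recessive)
  if (lethal) {
    # no live animal can be alt-homozygous at a recessive lethal: censor
    # founders at the focal locus as well
    hom <- gam1[, focal_idx] + gam2[, focal_idx] == 2L
    gam1[hom, focal_idx] <- 0L
  }
  sire_of_dam <- rep_len(seq_len(cf$n_sires), cf$n_dams)

  n_off <- cf$n_dams * cf$offspring_per_dam
  dosage <- matrix(0L, n_off, k)
  dam_of <- rep(seq_len(cf$n_dams), each = cf$offspring_per_dam)
  for (i in seq_len(n_off)) {
    d <- dam_of[i]
    s <- sire_of_dam[d]
    repeat {
      gs <- transmit_gamete(gam1[s, ], gam2[s, ], block_id)
      gd <- transmit_gamete(gam1[cf$n_sires + d, ], gam2[cf$n_sires + d, ], block_id)
      child <- gs + gd
      if (!lethal || child[focal_idx] < 2L) break  # censored before phenotyping
    }
    dosage[i, ] <- child
  }
  animal_ids <- sprintf("off%05d", seq_len(n_off))
  dimnames(dosage) <- list(animal_ids, map$marker_id)

  # --- phenotypes ---------------------------------------------------------
  sex <- factor(rep_len(c("M", "F"), n_off), levels = c("F", "M"))
  hatch <- factor(rep_len(seq_len(cf$n_hatches), n_off))
  dam_family <- factor(sprintf("fam%03d", dam_of))

  ts <- TRAIT_SCALES
  sc <- function(tr, col) ts[[col]][ts$trait == tr]
  bw_mu <- sc("bw42_g", "mean"); bw_sd <- sc("bw42_g", "sd")
  sex_sign <- ifelse(sex == "M", 0.5, -0.5)
  bw_fixed <- sex_sign * cf$sex_effect_g + cf$hatch_effects_g[as.integer(hatch)]
  bw_resid_var <- max(bw_sd^2 - var(bw_fixed), 0.25 * bw_sd^2)
  bw42 <- bw_mu + bw_fixed + rnorm(n_off, 0, sqrt(bw_resid_var))

  qtl_idx <- if (cf$n_qtl > 0) {
    sample(setdiff(seq_len(k), focal_idx), cf$n_qtl)
  } else integer(0)
  beta_base <- if (cf$n_qtl > 0) rnorm(cf$n_qtl) else numeric(0)
  M <- center_dosage(dosage)
  g_base <- if (cf$n_qtl > 0) drop(M[, qtl_idx, drop = FALSE] %*% beta_base) else
    rep(0, n_off)
  vg_base <- if (cf$n_qtl > 0) var(g_base) else 0

  weight_traits <- c("btw_g", "thw_g", "drw_g", "abfw_g")
  effects <- list()
  fam_effects <- list()
  pheno <- data.frame(animal_id = animal_ids, sex = sex, hatch = hatch,
                      dam_family = dam_family, bw42_g = bw42,
                      stringsAsFactors = FALSE)
  for (tr in weight_traits) {
    mu <- sc(tr, "mean"); vtot <- sc(tr, "sd")^2
    c_bw <- sqrt(cf$bw42_share * vtot / bw_sd^2)
    scale_t <- if (vg_base > 0) sqrt(cf$qtl_h2 * vtot / vg_base) else 0
    beta_t <- setNames(rep(0, k), map$marker_id)
    if (cf$n_qtl > 0) beta_t[qtl_idx] <- beta_base * scale_t
    if (tr == "abfw_g") beta_t[focal_idx] <- cf$focal_deleterious$additive_effect_g
    u_t <- rnorm(cf$n_dams, 0, sqrt(cf$family_variance_fraction * vtot))
    res_sd <- if (!is.null(cf$residual_sd)) cf$residual_sd else
      sqrt(vtot * (1 - cf$qtl_h2 - cf$family_variance_fraction - cf$bw42_share))
    g_t <- drop(M %*% beta_t)
    y <- mu + c_bw * (bw42 - bw_mu) + 0.03 * mu * sex_sign +
      g_t + u_t[dam_of] + rnorm(n_off, 0, res_sd)
    pheno[[tr]] <- pmax(y, 0.5)  # weights cannot be negative
    effects[[tr]] <- beta_t
    fam_effects[[tr]] <- setNames(u_t, levels(dam_family))
  }
  pheno$bt_pct <- 100 * pheno$btw_g / pheno$bw42_g
  pheno$th_pct <- 100 * pheno$thw_g / pheno$bw42_g
  pheno$dr_pct <- 100 * pheno$drw_g / pheno$bw42_g
  pheno$abf_pct <- 100 * pheno$abfw_g / pheno$bw42_g
  pheno <- pheno[PHENO_COLUMNS]

  # --- annotation ---------------------------------------------------------
  decoy_pool <- setdiff(seq_len(k), c(focal_idx, qtl_idx))
  decoys <- sample(decoy_pool, min(cf$n_decoy_deleterious, length(decoy_pool)))
  tolerated <- sample(setdiff(decoy_pool, decoys),
                      min(20, length(setdiff(decoy_pool, decoys))))
  ann_idx <- c(focal_idx, decoys, tolerated)
  annotation <- data.frame(
    marker_id = map$marker_id[ann_idx],
    gene_symbol = sprintf("GENE%04d", ann_idx),
    ensembl_gene_id = sprintf("ENSSIMG%011d", ann_idx),
    consequence = c("missense_variant",
                    rep("missense_variant", length(decoys)),
                    rep("missense_variant", length(tolerated))),
    sift_score = c(0.04, runif(length(decoys), 0, 0.05),
                   runif(length(tolerated), 0.2, 1)),
    stringsAsFactors = FALSE
  )

  truth <- list(
    qtl_marker_ids = map$marker_id[qtl_idx],
    effects = effects,
    focal = list(marker_id = focal_id, allele_freq = cf$focal_deleterious$allele_freq,
                 additive_effect_g = cf$focal_deleterious$additive_effect_g,
                 additive_effect_pct = cf$focal_deleterious$additive_effect_pct,
                 lethal_recessive = lethal),
    dam_family_effects = fam_effects,
    variance_components = list(qtl_h2 = cf$qtl_h2,
                               family_variance_fraction = cf$family_variance_fraction,
                               bw42_share = cf$bw42_share),
    p_alt = setNames(p_alt, map$marker_id),
    sire_of_dam = sire_of_dam,
    dam_of_offspring = dam_of,
    founder_dosage = gam1 + gam2  # sires first, then dams; rows align to map
  )
  list(genotypes = dosage, map = map, phenotypes = pheno,
       annotation = annotation, truth = truth)
}

#' Write a simulated population to disk
#'
#' Emits the PLINK-style `.ped`/`.map` pair, the phenotype and annotation
#' tables as tab-separated text, and the truth record as JSON (requires the
#' jsonlite package).
#'
#' @param sim Result of [simulate_population()].
#' @param out_dir Output directory (created if absent).
#' @param seed Seed recorded in the table headers.
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_plink_text(sim$genotypes, sim$map,
                   file.path(out_dir, "genotypes.ped"),
                   file.path(out_dir, "genotypes.map"))
  write_result_table(sim$phenotypes, file.path(out_dir, "phenotypes.tsv"), seed)
  write_result_table(sim$annotation, file.path(out_dir, "annotation.tsv"), seed)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- sim$truth
    truth$effects <- lapply(truth$effects, function(b) b[b != 0])
    truth$founder_dosage <- NULL
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}
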