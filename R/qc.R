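# Quality control: allele frequencies, Hardy-Weinberg testing, array-style
# marker/sample filters and the post-calling filters for sequenced variants.

#' Genotype counts at a biallelic locus
#'
#' @param n_hom_ref,n_het,n_hom_alt Non-negative integer counts of
#'   reference-homozygote, heterozygote and alternative-homozygote animals.
#' @return A named list of class `genotype_counts` with the three counts and
#'   their total `n`.
#' @export
genotype_counts <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(length(n_hom_ref) == 1, length(n_het) == 1, length(n_hom_alt) == 1)
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) stop("at least one genotyped animal required (n >= 1)")
  structure(list(n_hom_ref = as.integer(n_hom_ref), n_het = as.integer(n_het),
                 n_hom_alt = as.integer(n_hom_alt), n = as.integer(n)),
            class = "genotype_counts")
}

# Count genotype classes of one dosage vector (alt-allele copies, NA missing).
count_genotypes <- function(dosage) {
  d <- dosage[!is.na(dosage)]
  genotype_counts(sum(d == 0L), sum(d == 1L), sum(d == 2L))
}

#' Allele frequencies from genotype counts
#'
#' `ref_freq = (2 n_RR + n_RA) / 2n`; the two frequencies sum to one exactly.
#'
#' @param counts A [genotype_counts] object.
#' @return Named numeric vector `c(ref_freq, alt_freq)`.
#' @export
allele_frequency <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  ref <- (2 * counts$n_hom_ref + counts$n_het) / (2 * counts$n)
  c(ref_freq = ref, alt_freq = 1 - ref)
}

#' Hardy-Weinberg exact test
#'
#' Exact test conditioning on the observed allele counts: the p-value is the
#' sum of probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed table. Probabilities are
#' built with the standard heterozygote-count recurrence for numerical
#' stability.
#'
#' @param counts A [genotype_counts] object.
#' @return The exact p-value in \[0,1\].
#' @export
hwe_exact_test <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  n <- counts$n
  n_alt <- 2L * counts$n_hom_alt + counts$n_het   # rarer-or-not alt allele count
  n_ref <- 2L * n - n_alt
  rare <- min(n_alt, n_ref)
  if (rare == 0L) return(1)                        # monomorphic: only one table

  # feasible heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2L, rare, by = 2L)
  probs <- numeric(length(hets))
  # start from the largest feasible het count and recur downward:
  # P(h-2)/P(h) = h (h-1) / (4 * n_rr(h-2) * n_aa(h-2))  with
  # n_rr(h) = (common - h)/2 hom-common, n_aa(h) = (rare - h)/2 hom-rare.
  m <- length(hets)
  probs[m] <- 1
  for (i in rev(seq_len(m - 1L))) {
    h <- hets[i + 1L]
    n_aa <- (rare - h) / 2 + 1          # hom-rare count at h-2
    n_rr <- n - (h - 2) - n_aa          # hom-common count at h-2
    probs[i] <- probs[i + 1L] * h * (h - 1) / (4 * n_aa * n_rr)
  }
  probs <- probs / sum(probs)
  obs <- probs[match(counts$n_het, hets)]
  # tolerance guards ties against floating-point noise in the recurrence
  sum(probs[probs <= obs * (1 + 1e-12)])
}

#' Hardy-Weinberg 1-df chi-square test
#'
#' Cross-check statistic: Pearson chi-square of observed genotype counts
#' against expectations `n p^2, 2npq, nq^2` from the observed allele
#' frequency. Monomorphic loci (an expected cell of zero) give `NA` with a
#' warning.
#'
#' @param counts A [genotype_counts] object.
#' @return p-value, or `NA` for a degenerate (monomorphic) table.
#' @export
hwe_chi2_test <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  p <- allele_frequency(counts)[["ref_freq"]]
  q <- 1 - p
  expected <- counts$n * c(p^2, 2 * p * q, q^2)
  if (any(expected == 0)) {
    warning("expected genotype count of zero; chi-square HWE test undefined")
    return(NA_real_)
  }
  observed <- c(counts$n_hom_ref, counts$n_het, counts$n_hom_alt)
  stat <- sum((observed - expected)^2 / expected)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Bonferroni significance flags
#'
#' @param p_values Numeric vector of raw p-values.
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of tests; defaults to `length(p_values)`.
#' @return Logical vector: `p < alpha / m`.
#' @export
bonferroni <- function(p_values, alpha = 0.05, m = length(p_values)) {
  stopifnot(m >= 1, alpha > 0)
  p_values < alpha / m
}

# MAF of one dosage vector over non-missing calls.
maf_of <- function(dosage) {
  d <- dosage[!is.na(dosage)]
  if (!length(d)) return(NA_real_)
  f <- mean(d) / 2
  min(f, 1 - f)
}

#' Array-style genotype quality control
#'
#' Applies, in order: sample call rate, marker call rate, minor allele
#' frequency, Hardy-Weinberg equilibrium (exact test), and sex/unplaced
#' chromosome removal. Each step's kept/removed counts are recorded.
#'
#' @param genotypes Animals x markers dosage matrix (`NA` missing).
#' @param map A [marker_map] aligned to the columns.
#' @param thresholds Named list overriding any of: `sample_call_rate` (0.90),
#'   `marker_call_rate` (0.98), `maf` (0.02), `hwe_p` (1e-6),
#'   `drop_chromosomes` (`c("Z","W","unplaced")`). Call-rate and MAF
#'   thresholds are inclusive (`>=`); HWE removes markers with p strictly
#'   below `hwe_p`.
#' @return A list with filtered `genotypes`, `map` and a `report` data frame
#'   (one row per step: unit, threshold, kept, removed).
#' @export
array_qc <- function(genotypes, map, thresholds = list()) {
  stopifnot(ncol(genotypes) == nrow(map))
  th <- utils::modifyList(
    list(sample_call_rate = 0.90, marker_call_rate = 0.98, maf = 0.02,
         hwe_p = 1e-6, drop_chromosomes = c("Z", "W", "unplaced")),
    thresholds
  )
  report <- data.frame(step = character(), unit = character(),
                       threshold = character(), kept = integer(),
                       removed = integer(), stringsAsFactors = FALSE)
  log_step <- function(step, unit, threshold, kept, removed) {
    rbind(report, data.frame(step = step, unit = unit, threshold = threshold,
                             kept = kept, removed = removed))
  }

  cr_sample <- rowMeans(!is.na(genotypes))
  keep_s <- cr_sample >= th$sample_call_rate
  report <- log_step("sample_call_rate", "sample", sprintf(">=%g", th$sample_call_rate),
                     sum(keep_s), sum(!keep_s))
  genotypes <- genotypes[keep_s, , drop = FALSE]

  cr_marker <- colMeans(!is.na(genotypes))
  keep <- cr_marker >= th$marker_call_rate
  report <- log_step("marker_call_rate", "marker", sprintf(">=%g", th$marker_call_rate),
                     sum(keep), sum(!keep))
  genotypes <- genotypes[, keep, drop = FALSE]
  map <- map[keep, , drop = FALSE]

  maf <- apply(genotypes, 2, maf_of)
  keep <- !is.na(maf) & maf >= th$maf
  report <- log_step("maf", "marker", sprintf(">=%g", th$maf), sum(keep), sum(!keep))
  genotypes <- genotypes[, keep, drop = FALSE]
  map <- map[keep, , drop = FALSE]

  hwe_p <- apply(genotypes, 2, function(d) hwe_exact_test(count_genotypes(d)))
  keep <- hwe_p >= th$hwe_p
  report <- log_step("hwe", "marker", sprintf("p>=%g", th$hwe_p), sum(keep), sum(!keep))
  genotypes <- genotypes[, keep, drop = FALSE]
  map <- map[keep, , drop = FALSE]

  keep <- !(map$chromosome %in% th$drop_chromosomes)
  report <- log_step("chromosome", "marker",
                     paste("drop", paste(th$drop_chromosomes, collapse = "/")),
                     sum(keep), sum(!keep))
  genotypes <- genotypes[, keep, drop = FALSE]
  map <- map[keep, , drop = FALSE]

  if (ncol(genotypes) == 0L) stop("all markers removed by QC")
  rownames(map) <- NULL
  list(genotypes = genotypes, map = map, report = report)
}

#' Filter sequenced variants
#'
#' Post-calling filters for amplicon/whole-genome sequenced variants, applied
#' as six predicates in fixed order: indel removal, minor allele frequency,
#' call rate, biallelic locus, sequencing depth and site quality. A removed
#' record is attributed to the first predicate it fails. Thresholds are
#' inclusive (`>=`).
#'
#' @param variants A list as returned by [read_sequenced_variants()]:
#'   `sites` data frame and `dosage` matrix (animals x sites).
#' @param maf,call_rate,depth,qual Thresholds (defaults 0.05, 0.7, 15, 40).
#' @return List with the surviving `variants` and a `report` data frame of
#'   per-predicate removal counts.
#' @export
filter_sequenced_variants <- function(variants, maf = 0.05, call_rate = 0.7,
                                      depth = 15, qual = 40) {
  sites <- variants$sites
  dosage <- variants$dosage
  k <- nrow(sites)
  predicates <- c("indel", "maf", "call_rate", "biallelic", "depth", "qual")
  removed_by <- setNames(integer(length(predicates)), predicates)
  keep <- logical(k)

  for (j in seq_len(k)) {
    alts <- strsplit(sites$alt_allele[j], ",")[[1]]
    fail <- NULL
    if (nchar(sites$ref_allele[j]) > 1L || any(nchar(alts) > 1L)) {
      fail <- "indel"
    } else if (is.na(m <- maf_of(dosage[, j])) || m < maf) {
      fail <- "maf"
    } else if (mean(!is.na(dosage[, j])) < call_rate) {
      fail <- "call_rate"
    } else if (length(alts) != 1L) {
      fail <- "biallelic"
    } else if (is.na(sites$depth[j]) || sites$depth[j] < depth) {
      fail <- "depth"
    } else if (is.na(sites$qual[j]) || sites$qual[j] < qual) {
      fail <- "qual"
    }
    if (is.null(fail)) keep[j] <- TRUE else removed_by[fail] <- removed_by[fail] + 1L
  }

  report <- data.frame(predicate = predicates, removed = as.integer(removed_by),
                       stringsAsFactors = FALSE)
  report <- rbind(report, data.frame(predicate = "kept", removed = sum(keep)))
  list(
    variants = list(sites = sites[keep, , drop = FALSE],
                    dosage = dosage[, keep, drop = FALSE]),
    report = report
  )
}
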