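# Single-SNP / joint-SNP association under a linear mixed model with one
# random effect (dam family), fitted by REML profiling of the variance ratio,
# plus the homozygote-deficit screen for recessive lethals.
#
# Model: y = X beta + W a + Z u + e, u ~ N(0, sigma2_u I_q), e ~ N(0,
# sigma2_e I_n). With lambda = sigma2_u / sigma2_e and H = I + lambda Z Z',
# the single grouping factor gives closed forms via the Woodbury identity:
# H^-1 = I - Z diag(lambda / (1 + lambda n_k)) Z', log|H| = sum log(1 +
# lambda n_k), so each profile evaluation costs O(n p^2).

# Profile REML criterion and GLS quantities at a fixed variance ratio.
lmm_profile <- function(lambda, y, X, group) {
  n <- length(y)
  p <- ncol(X)
  sizes <- as.numeric(table(group))
  d <- if (lambda > 0) lambda / (1 + lambda * sizes) else rep(0, length(sizes))
  ZtX <- rowsum(X, group)                       # q x p group sums
  Zty <- rowsum(y, group)[, 1]
  XtHiX <- crossprod(X) - crossprod(ZtX * sqrt(d))
  XtHiy <- drop(crossprod(X, y)) - drop(crossprod(ZtX, d * Zty))
  ytHiy <- sum(y * y) - sum(d * Zty^2)
  ch <- tryCatch(chol(XtHiX), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  beta <- backsolve(ch, backsolve(ch, XtHiy, transpose = TRUE))
  rss <- ytHiy - sum(XtHiy * beta)
  if (rss <= 0) return(list(ll = -Inf))
  ll <- -0.5 * ((n - p) * log(rss) + sum(log1p(lambda * sizes)) +
                  2 * sum(log(diag(ch))))
  list(ll = ll, beta = beta, chol_XtHiX = ch, rss = rss,
       sigma2_e = rss / (n - p), d = d, sizes = sizes)
}

#' REML fit of a linear mixed model with one random grouping factor
#'
#' Profiles the restricted likelihood over the variance ratio
#' `lambda = sigma2_u / sigma2_e` (coarse log-spaced grid search followed by
#' golden-section refinement in the bracketing interval), solves the mixed-
#' model equations at the optimum, and attaches per-coefficient standard
#' errors, Satterthwaite denominator degrees of freedom and t-test p-values.
#' A boundary optimum (`lambda = 0`) is returned with a warning; the fit then
#' coincides with ordinary least squares.
#'
#' @param y Numeric response (complete cases only).
#' @param X Fixed-effect design matrix, full column rank (intercept included).
#' @param group Factor with at least 2 levels: the random-effect grouping.
#' @param lambda Optional fixed variance ratio; `NULL` (default) estimates it
#'   by REML. `lambda = 0` gives the OLS fit in mixed-model clothing.
#' @return List of class `lmm_fit`: `coefficients` (data frame term,
#'   estimate, se, df, t, p_value), `lambda`, `sigma2_e`, `sigma2_u`,
#'   `logLik` (profile REML criterion), `n`, `boundary`.
#' @export
reml_lmm <- function(y, X, group, lambda = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  group <- droplevels(factor(group))
  stopifnot(nrow(X) == n, length(group) == n)
  if (nlevels(group) < 2) stop("random grouping factor needs >= 2 levels")
  if (sd(y) == 0) stop("response has zero variance")
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("fixed design is singular; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }

  boundary <- FALSE
  if (is.null(lambda)) {
    grid <- c(0, 10^seq(-8, 4, length.out = 60))
    lls <- vapply(grid, function(l) lmm_profile(l, y, X, group)$ll, numeric(1))
    best <- which.max(lls)
    if (best == 1L) {
      lambda <- 0
      boundary <- TRUE
      warning("REML variance-ratio estimate at boundary (sigma2_u = 0)")
    } else {
      lo <- grid[max(best - 1L, 2L)]
      hi <- grid[min(best + 1L, length(grid))]
      opt <- optimize(function(ll) lmm_profile(exp(ll), y, X, group)$ll,
                      interval = log(c(lo, hi)), maximum = TRUE, tol = 1e-10)
      lambda <- exp(opt$maximum)
      # accept the boundary if it is not strictly beaten
      if (lls[1] >= opt$objective - 1e-10) {
        lambda <- 0
        boundary <- TRUE
        warning("REML variance-ratio estimate at boundary (sigma2_u = 0)")
      }
    }
  }

  prof <- lmm_profile(lambda, y, X, group)
  if (!is.finite(prof$ll)) stop("mixed model profile criterion is degenerate")
  beta <- drop(prof$beta)
  names(beta) <- colnames(X)
  sigma2_e <- prof$sigma2_e
  XtHiX_inv <- chol2inv(prof$chol_XtHiX)
  vcov_beta <- sigma2_e * XtHiX_inv
  se <- sqrt(diag(vcov_beta))
  df <- satterthwaite_df(y, X, group, lambda, sigma2_e, XtHiX_inv, prof$d)
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)

  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = beta, se = se,
                              df = df, t = tval, p_value = pval,
                              row.names = NULL, stringsAsFactors = FALSE),
    vcov = vcov_beta, lambda = lambda, sigma2_e = sigma2_e,
    sigma2_u = lambda * sigma2_e, logLik = prof$ll, n = n, p = p,
    boundary = boundary, group = group
  ), class = "lmm_fit")
}

# Satterthwaite denominator df for each fixed-effect coefficient, via the
# delta method over (sigma2_u, sigma2_e) with the expected REML information.
satterthwaite_df <- function(y, X, group, lambda, sigma2_e, XtHiX_inv, d) {
  n <- length(y)
  p <- ncol(X)
  gidx <- as.integer(group)
  # Hi = I - Z diag(d) Z' explicitly (n x n); adequate at cohort sizes
  Hi <- diag(n)
  if (lambda > 0) {
    Dz <- d[gidx]
    for (k in seq_along(d)) {
      ix <- which(gidx == k)
      Hi[ix, ix] <- Hi[ix, ix] - d[k]
    }
  }
  HiX <- Hi %*% X
  B <- HiX %*% XtHiX_inv               # n x p; a_l = B[, l]
  Pt <- Hi - B %*% t(HiX)              # scaled projector: P = Pt / sigma2_e
  PtZ <- t(rowsum(t(Pt), gidx))        # n x q
  ZPtZ <- rowsum(PtZ, gidx)            # q x q
  tr11 <- sum(ZPtZ^2)
  tr12 <- sum(PtZ^2)
  tr22 <- sum(Pt^2)
  info <- 0.5 * matrix(c(tr11, tr12, tr12, tr22), 2, 2) / sigma2_e^2
  vtheta <- tryCatch(solve(info), error = function(e) NULL)

  f <- sigma2_e * diag(XtHiX_inv)      # var(beta_hat_l)
  out <- numeric(p)
  for (l in seq_len(p)) {
    a <- B[, l]
    g2 <- sum(a * a)
    g1 <- sum(rowsum(a, gidx)^2)
    g <- c(g1, g2)
    denom <- if (is.null(vtheta)) NA_real_ else drop(t(g) %*% vtheta %*% g)
    out[l] <- if (is.finite(denom) && denom > 0) 2 * f[l]^2 / denom else n - p
  }
  pmin(pmax(out, 1), n - p)
}

#' Genotypic (non-additive) coding of a dosage vector
#'
#' Turns alt-allele dosages into a 3-level genotype factor design with the
#' reference homozygote as baseline: one indicator for heterozygotes (`GE1`)
#' and one for alternative homozygotes (`GE2`). Absent genotype classes
#' contribute no column; data with no reference homozygotes are an error
#' (no baseline to contrast against).
#'
#' @param dosage Integer dosages in `{0,1,2}` (no `NA`).
#' @return Matrix with 0-2 indicator columns named `GE1`, `GE2`.
#' @export
genotypic_coding <- function(dosage) {
  stopifnot(!anyNA(dosage), all(dosage %in% 0:2))
  if (!any(dosage == 0L)) stop("no reference homozygotes: genotypic coding has no baseline level")
  cols <- list()
  if (any(dosage == 1L)) cols$GE1 <- as.numeric(dosage == 1L)
  if (any(dosage == 2L)) cols$GE2 <- as.numeric(dosage == 2L)
  if (!length(cols)) {
    return(matrix(numeric(0), nrow = length(dosage), ncol = 0))
  }
  do.call(cbind, cols)
}

#' Joint single-locus association of candidate SNPs with one trait
#'
#' Fits the mixed model `y = X beta + W a + Z u + e` by REML: sex and hatch
#' as fixed effects, BW42 as a covariate for the weight traits, all candidate
#' SNPs for the trait entering one joint model (`W`), and dam family as the
#' random effect. `model = "additive"` codes each SNP as its 0/1/2 dosage;
#' `model = "genotypic"` as genotype-class contrasts against the reference
#' homozygote ([genotypic_coding()]). Complete cases on the trait, fixed
#' effects and all candidate dosages are analyzed.
#'
#' @param phenotypes Phenotype table.
#' @param trait Trait column name.
#' @param genotypes Animals x markers dosage matrix (rownames = animal ids).
#' @param snp_ids Candidate marker ids (columns of `genotypes`).
#' @param model `"additive"` or `"genotypic"`.
#' @param lambda Optional fixed variance ratio passed to [reml_lmm()].
#' @param alpha Comparison-wise significance level (default 0.05).
#' @return Data frame (class `assoc_result`): marker_id, trait, model, term,
#'   estimate, se, df, p_value, significant, n_used. One row per SNP under
#'   the additive model; one per observed non-reference genotype class under
#'   the genotypic model.
#' @export
fit_lmm <- function(phenotypes, trait, genotypes, snp_ids,
                    model = c("additive", "genotypic"), lambda = NULL,
                    alpha = 0.05) {
  model <- match.arg(model)
  if (length(snp_ids) < 1) stop("no candidate SNPs supplied")
  stopifnot(all(snp_ids %in% colnames(genotypes)))
  td <- trait_design(phenotypes, trait)
  gidx <- match(td$animal_id, rownames(genotypes))
  if (anyNA(gidx)) stop("phenotyped animal(s) missing from genotype matrix")
  W_raw <- genotypes[gidx, snp_ids, drop = FALSE]
  cc <- complete.cases(W_raw)
  y <- td$y[cc]
  X <- td$X[cc, , drop = FALSE]
  W_raw <- W_raw[cc, , drop = FALSE]
  fam <- droplevels(factor(phenotypes$dam_family[td$keep][cc]))

  if (model == "additive") {
    W <- W_raw
    colnames(W) <- snp_ids
    term_marker <- snp_ids
    term_label <- rep("additive", length(snp_ids))
  } else {
    blocks <- lapply(snp_ids, function(id) {
      m <- genotypic_coding(W_raw[, id])
      if (ncol(m)) colnames(m) <- paste(id, colnames(m), sep = ".")
      m
    })
    W <- do.call(cbind, blocks)
    term_marker <- sub("\\.GE[12]$", "", colnames(W))
    term_label <- sub("^.*\\.", "", colnames(W))
  }

  fit <- reml_lmm(y, cbind(X, W), fam, lambda = lambda)
  co <- fit$coefficients
  snp_rows <- co[match(colnames(W), co$term), , drop = FALSE]
  out <- data.frame(
    marker_id = term_marker, trait = trait, model = model, term = term_label,
    estimate = snp_rows$estimate, se = snp_rows$se, df = snp_rows$df,
    p_value = snp_rows$p_value, significant = snp_rows$p_value < alpha,
    n_used = length(y), stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Homozygote-deficit screen for recessive lethals
#'
#' Compares the observed count of alternative-allele homozygotes with the
#' Hardy-Weinberg expectation `q^2 n`. By default `q` is the alt-allele
#' frequency rounded to 3 decimal places, matching how such frequencies are
#' reported; `round_freq = FALSE` uses full precision. A locus is flagged
#' when no alt homozygotes are observed although at least one was expected
#' (and, when `require_hwe_deviation`, the exact HWE test is significant at
#' `alpha`).
#'
#' @param counts A [genotype_counts] object.
#' @param require_hwe_deviation Also require HWE-exact significance to flag.
#' @param round_freq Round the alt frequency to 3 dp before squaring.
#' @param alpha Significance level for the optional HWE requirement.
#' @return List of class `lethal_screen_result`: observed and expected alt-
#'   homozygote counts, `prob_zero_given_hwe = (1 - q^2)^n`, the HWE p-value
#'   and the flag.
#' @export
lethal_recessive_screen <- function(counts, require_hwe_deviation = FALSE,
                                    round_freq = TRUE, alpha = 0.05) {
  stopifnot(inherits(counts, "genotype_counts"))
  q <- allele_frequency(counts)[["alt_freq"]]
  if (round_freq) q <- round(q, 3)
  expected <- q^2 * counts$n
  prob_zero <- (1 - q^2)^counts$n
  hwe_p <- hwe_exact_test(counts)
  flagged <- counts$n_hom_alt == 0L && expected >= 1 &&
    (!require_hwe_deviation || hwe_p < alpha)
  structure(list(observed_hom_alt = counts$n_hom_alt, expected_hom_alt = expected,
                 alt_freq_used = q, prob_zero_given_hwe = prob_zero,
                 hwe_p = hwe_p, flagged = flagged),
            class = "lethal_screen_result")
}
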