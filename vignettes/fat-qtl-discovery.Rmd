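---
title: "Window-based Bayesian GWAS and deleterious-variant association: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based Bayesian GWAS and deleterious-variant association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatmap)
```

This vignette is the package's own account of its statistical machinery:
the models, the parameters that matter, the numerical choices made where
several defensible options existed, and what the synthetic-data validation
does and does not establish about real data.

## The discovery chain

The package implements a four-stage chain used to go from a dense SNP array
to a short list of putative causal variants for carcass and abdominal-fat
traits in a meat-type chicken reference population (a sire × dam design
with full- and half-sib families, hatched in batches):

1. **QC** of array genotypes and, later, of amplicon-sequenced variants.
2. **Window-based Bayesian GWAS**: spike–slab whole-genome regression, with
   the genetic variance decomposed over non-overlapping 1-Mb windows.
3. **Candidate triage**: missense SNPs predicted deleterious (SIFT ≤ 0.05)
   inside significant windows, thinned so that no two candidates have
   r² > 0.7.
4. **Single-SNP mixed-model association** of the surviving candidates, with
   a dam-family random effect, plus a homozygote-deficit screen for
   recessive lethals.

## Spike–slab whole-genome regression

The genomic model is

$$y = Xb + \sum_{j=1}^{k} a_j \beta_j \delta_j + e,$$

where $a_j$ is the centered alt-allele dosage at locus $j$, $\beta_j$ its
substitution effect, and $\delta_j$ a 0/1 inclusion indicator with prior
exclusion probability $\pi$ (default 0.9970, i.e. three markers per
thousand in the model a priori). Fixed effects are sex and hatch, with
BW42 as a covariate for weight traits. Two passes are run:

* **BayesC** — a single common effect variance $\sigma^2_\beta$ — to
  estimate the genetic variance (variance across animals of the sampled
  genomic values $\sum_j a_j\beta_j\delta_j$) and the residual variance.
* **BayesB** — per-locus variances $\sigma^2_{\beta_j}$ with
  scaled-inverse-$\chi^2(\nu_\beta, S^2_\beta)$ priors — for marker
  effects, using the BayesC estimates as priors.

Both are single-site Gibbs samplers (Rcpp): fixed effects with flat priors,
then each marker in map order with the effect marginalized out of the
inclusion update, then the variances. The chain default is 41,000
iterations with 1,000 burn-in, retaining every 100th post-burn-in effect
vector for the window decomposition; reduced chains are adequate for the
simulated validations (see below). With a fixed seed chains are
bit-reproducible (the sampler draws from R's RNG stream).

Numerical and structural choices:

* **Per-locus prior scale.** The conversion from a total genetic variance
  $V_g$ to a per-locus scale is
  $S^2_\beta = V_g\,\frac{\nu_\beta-2}{\nu_\beta} \big/ \big[(1-\pi)\sum_j 2p_jq_j\big]$ —
  the standard spread of $V_g$ over the expected number of included loci
  weighted by heterozygosity. $\nu_\beta = \nu_e = 4$ by default (weakly
  informative).
* **Missing dosages** are mean-imputed before centering; a marker with zero
  variance after centering is permanently excluded ($\delta_j = 0$).
* **BayesC runs with the same $\pi$ as BayesB** (the choice is exposed, not
  hard-wired).
* **Degenerate runs.** A non-finite residual-variance draw aborts with a
  diagnostic rather than silently continuing. Setting
  $\nu_\beta = \infty$ (and/or $\nu_e = \infty$) pins the corresponding
  variance at its scale; with $\pi = 0$ this reduces the sampler to
  Bayesian ridge regression with a known variance ratio, which the test
  suite compares against the closed-form solution.

## Window variance decomposition

Markers are assigned to per-chromosome half-open 1-based bins,
`floor((position_bp - 1)/1e6)`, so positions 1–1,000,000 share bin 0 and
1,000,001 opens bin 1; only windows containing a marker are instantiated,
and no window spans a chromosome boundary. For each retained draw, a
window's genomic values are its markers' centered dosages times their
sampled effects, and its share is the variance of those values across
animals as a percentage of the draw's **total genetic variance, defined as
the sum of the per-window variances**. Defining the denominator as the sum
(rather than the variance of the summed genomic values) makes shares sum
to exactly 100 within every draw — the invariant the downstream summaries
rely on — at the cost of ignoring between-window covariance, which is
small when windows are in weak LD. A draw with zero genetic variance
yields uniform shares with a warning.

A window is significant when its posterior mean share reaches
`fold × 100 / n_windows` percent (default fold 5; for 947 windows the
threshold is 0.53% to two decimals). The PPA of a window is the fraction
of retained draws in which its share exceeds the infinitesimal expectation
`100 / n_windows`; an alternative convention (fraction of draws with at
least one included marker in the window) exists in the literature, and the
exceedance definition was chosen because it is well defined even for
draws in which the window's markers are all excluded.

## Quality control

* **Array filters**, in order: sample call rate ≥ 0.90, marker call rate
  ≥ 0.98, MAF ≥ 0.02 (computed on non-missing calls), HWE exact-test
  p ≥ 1e-6, and removal of sex-chromosome/unplaced markers. Applying
  samples before markers and MAF before HWE means a monomorphic marker is
  removed as a MAF failure and never reaches the HWE test (whose exact
  p-value for a monomorphic table is 1 anyway). The filter set is
  idempotent.
* **HWE exact test**: the sum of probabilities, conditional on allele
  counts, of all heterozygote counts no more probable than the observed
  one, computed with the standard recurrence over feasible heterozygote
  counts. Ties are compared with a 1+1e-12 relative guard so that
  floating-point noise cannot drop the observed table itself. A 1-df
  chi-square version is provided as a cross-check; it returns `NA` with a
  warning when an expected genotype class is empty.
* **Sequenced-variant filters**, applied as six predicates in fixed order
  (indel, MAF ≥ 0.05, call rate ≥ 0.7, biallelic, depth ≥ 15, QUAL ≥ 40);
  all thresholds inclusive. A removed record is attributed to the first
  predicate it fails, which makes the removal report additive.
* **Bonferroni** flags use `p < α/m` with `m` the number of tests actually
  carried into the table at hand (e.g. 18 candidate SNPs), not a
  genome-wide count.

## Candidate triage

LD is measured as composite r² — the squared Pearson correlation of dosage
vectors over animals non-missing at both markers — because founder phase
is not part of the package's inputs; composite r² is the standard
phase-free surrogate. Tag selection is greedy: markers are visited by
decreasing MAF (ties: ascending position, then id); each visited
still-active marker becomes a tag and removes every remaining marker with
r² strictly above the threshold (default 0.7). The kept set therefore has
all pairwise r² ≤ 0.7, and the procedure is deterministic under the stated
ordering. SIFT triage keeps annotated markers with score ≤ 0.05 whose
position falls inside a significant window's span; annotation rows whose
marker is absent from the map are skipped with a warning rather than
silently dropped.

## Mixed-model association

With a single grouping factor (dam family), the REML problem for
$y = X\beta + Wa + Zu + e$ reduces to one dimension. Writing
$\lambda = \sigma^2_u/\sigma^2_e$ and $H = I + \lambda ZZ'$, the Woodbury
identity gives $H^{-1} = I - Z\,\mathrm{diag}\big(\lambda/(1+\lambda
n_k)\big)Z'$ and $\log|H| = \sum_k \log(1+\lambda n_k)$ with $n_k$ the
family sizes, so each profile evaluation costs $O(np^2)$. The profile is
maximized by a coarse log-spaced grid (60 points spanning $10^{-8}$ to
$10^4$, plus 0) followed by golden-section refinement in the bracketing
interval; the grid stage guards against the profile's occasional flatness
near the boundary. A boundary optimum is returned as $\lambda = 0$ with a
warning — the fit is then exactly ordinary least squares. A fixed
$\lambda$ can be supplied instead, which is how the test suite compares
against a generalized-least-squares oracle with the true variance
components.

Per-coefficient t-tests use Satterthwaite denominator degrees of freedom,
computed by the delta method over $(\sigma^2_u, \sigma^2_e)$ with the
expected REML information; df are clamped to $[1, n-p]$ (the fixed-model
residual df is the mathematical ceiling; the clamp only absorbs numerical
noise). Estimates, standard errors and p-values agree with
lme4/lmerTest — which the original analysis used — to six or more
significant figures on shared fixtures, with df differing only by the
expected-vs-observed information convention (well under 1 df).

All candidate SNPs for a trait enter one joint model; complete cases on
the trait, the fixed effects and every candidate dosage are analyzed
(the joint-model description leaves missing-genotype handling open;
complete-case is the conservative reading, and an imputation route was
deliberately not defaulted). A singular fixed design — e.g. a SNP
confounded with hatch — is an error naming the aliased columns. The
genotypic coding contrasts heterozygotes (GE 1) and alt-homozygotes (GE 2)
against the reference homozygote; absent classes simply contribute no
contrast, and data without reference homozygotes are an error.

The homozygote-deficit screen computes the expected alt-homozygote count
$q^2 n$ with $q$ rounded to 3 decimals by default — matching how such
frequencies are reported, so that e.g. counts (172, 65, 0) in 237 animals
give expected 4.45 — with a full-precision mode (same counts: 4.46). The
flag requires zero observed alt homozygotes and expected ≥ 1, optionally
plus HWE-exact significance.

## What the synthetic population emulates — and what it does not

`simulate_population()` mirrors the reference-population design: 20 sires
× 92 dams (round-robin sire assignment → half-sib groups; each dam a
full-sib family), 5 hatches and two sexes assigned round-robin as fixed
structure, ~15 offspring per dam by default. Founder gametes get
blockwise LD from a latent-factor model: markers within an `ld_block_len_bp`
block share a standard-normal factor with loading √ρ (default ρ = 0.9)
and are thresholded at their target frequencies, so marginal allele
frequencies are exactly the configured ones while within-block dosage
correlation is positive and between-block correlation is ~0. Offspring
are produced by Mendelian gene-dropping, transmitting one parental gamete
per block (free recombination between blocks, none within). Phenotypes
follow mean + sex + hatch + BW42 path + $\sum_j a_j\beta_j\delta_j$ +
dam-family effect + residual; percent traits are computed as
100·weight/BW42, and weights are floored at 0.5 g (the unfloored model is
Gaussian and could otherwise produce a handful of negative fat weights in
large cohorts). The focal deleterious SNP defaults to alt frequency 0.236
with a −3.43 g additive effect on abdominal-fat weight; with
`lethal_recessive = TRUE`, alt-homozygotes are censored before
phenotyping — in founders as well as offspring, since no live carrier of
two lethal alleles can appear in any generation (this also guarantees the
gene-dropping rejection loop terminates).

Background QTL effects are drawn once and scaled so that the realized
variance of $\sum_j a_j\beta_j$ equals the configured `qtl_h2` share of
the trait's nominal variance; the same QTL are shared across traits with
trait-specific scaling (implied genetic correlation ~1 — genetic
correlations are not otherwise modeled). Trait means and SDs are built-in
cohort-level values (e.g. BW42 2220 ± 259 g, abdominal fat 47.1 ± 14.0 g).

Not emulated: coalescent/forward population-genetic realism (mutation,
selection over generations, realistic allele-frequency spectra),
genotyping error, long-range LD across block boundaries, genotype phasing,
and non-Gaussian trait components. Consequently, passing the simulation
checks shows that the estimators recover the generative model they assume
— effect sizes, variance shares, window ranking, type-I error under the
stated random-effects structure — not that they are robust to model
misspecification in real populations.

## Validation problem sizes

The test suite exercises the samplers and the mixed model at reduced but
structurally faithful sizes, chosen so the whole suite runs comfortably on
one CPU: sampler recovery uses 20 seeded replicates of an 800-animal ×
2,000-marker population with one QTL at 30% of phenotypic variance and
5,000-iteration chains (the QTL's window must rank first with PPA > 0.9 in
at least 18 of 20); effect recovery uses 100 cohorts of 237 animals in 41
dam families with the −3.43 g focal effect at frequency 0.236; type-I
error uses 500 null cohorts of the same dimensions (acceptance band ±2
Monte-Carlo SE around 0.05); the HWE exact test is compared against
brute-force enumeration exhaustively for all tables with n ≤ 30 and on 300
random tables up to n = 200.

## Known limitations

* The window-share denominator ignores between-window covariance (see
  above); windows in strong mutual LD can have their joint contribution
  split or double-counted relative to a covariance-aware decomposition.
* The Gibbs sampler is a single long chain; no convergence diagnostics are
  computed beyond the divergence guard, and short chains on small data can
  under-disperse posterior summaries.
* Satterthwaite df use the expected information; for severely unbalanced
  family sizes the observed-information version can differ slightly.
* The lethal-recessive screen is a flag, not a test: `prob_zero_given_hwe`
  is reported so users can judge the evidence, and confirmation requires
  carrier × carrier matings.
* PLINK text `.map` files carry no allele columns, so dosage orientation
  on re-read is by alphabetical convention unless the designated alt
  alleles are supplied (`alt_alleles=`).
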