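# 1-Mb window construction over the marker map, per-draw window variance
# decomposition of the genomic values, posterior summaries (percent variance,
# PPA, five-fold significance rule), and the downstream summaries used when
# reporting QTL (unique-window dedup, cumulative variance).

#' Assign markers to non-overlapping physical windows
#'
#' Window bins are half-open 1-based megabase intervals per chromosome:
#' `window_mb = floor((position_bp - 1) / size_bp)`, so positions 1..size_bp
#' fall in bin 0. Only windows containing at least one marker are
#' instantiated.
#'
#' @param map A [marker_map] (sorted; [marker_map()] sorts on construction).
#' @param size_bp Window size in base pairs (default 1 Mb).
#' @return A list: `marker_window` (data frame marker_id, chromosome,
#'   window_mb, window_id) and `windows` (one row per instantiated window:
#'   window_id, chromosome, window_mb, first/last marker positions, n_snps).
#' @export
assign_windows <- function(map, size_bp = 1e6) {
  stopifnot(size_bp >= 1)
  bin <- (map$position_bp - 1L) %/% as.integer(size_bp)
  wid <- paste0(map$chromosome, ":", bin)
  marker_window <- data.frame(marker_id = map$marker_id,
                              chromosome = map$chromosome,
                              window_mb = bin, window_id = wid,
                              stringsAsFactors = FALSE)
  agg_first <- tapply(map$position_bp, wid, min)
  agg_last <- tapply(map$position_bp, wid, max)
  agg_n <- tapply(map$position_bp, wid, length)
  ids <- unique(wid)  # map order: chromosome then position
  windows <- data.frame(
    window_id = ids,
    chromosome = sub(":[0-9]+$", "", ids),
    window_mb = as.integer(sub("^.*:", "", ids)),
    first_bp = as.integer(agg_first[ids]),
    last_bp = as.integer(agg_last[ids]),
    n_snps = as.integer(agg_n[ids]),
    stringsAsFactors = FALSE
  )
  rownames(windows) <- NULL
  list(marker_window = marker_window, windows = windows)
}

#' Per-draw window shares of the genetic variance
#'
#' For each retained MCMC draw of the marker effects, computes each window's
#' genomic values (centered dosages times the window's sampled effects), takes
#' their variance across animals, and expresses it as a percentage of the
#' total genetic variance of that draw. The total is the sum of the per-window
#' variances, so shares sum to 100 exactly within each draw. A draw with zero
#' genetic variance yields uniform shares with a warning.
#'
#' @param effect_draws Draws x markers matrix of sampled marker effects
#'   (thinned chain output, e.g. `$window_draws` of [fit_bayes_b()]).
#' @param genotypes Animals x markers dosage matrix; columns are mean-imputed
#'   and centered internally.
#' @param window_assign Result of [assign_windows()] for the matching map.
#' @return Draws x windows matrix of percent shares (columns named by
#'   window_id, ordered as `window_assign$windows`).
#' @export
window_variance_draws <- function(effect_draws, genotypes, window_assign) {
  if (ncol(effect_draws) != ncol(genotypes) ||
      ncol(genotypes) != nrow(window_assign$marker_window)) {
    stop("effect draws, genotypes and window assignment have mismatched marker dimensions")
  }
  M <- center_dosage(genotypes)
  wids <- window_assign$windows$window_id
  widx <- split(seq_len(ncol(M)), factor(window_assign$marker_window$window_id,
                                         levels = wids))
  n_draws <- nrow(effect_draws)
  shares <- matrix(0, n_draws, length(wids), dimnames = list(NULL, wids))
  for (d in seq_len(n_draws)) {
    beta <- effect_draws[d, ]
    vw <- vapply(widx, function(ix) {
      nz <- ix[beta[ix] != 0]
      if (!length(nz)) return(0)
      var(M[, nz, drop = FALSE] %*% beta[nz])[1]
    }, numeric(1))
    tot <- sum(vw)
    if (tot <= 0) {
      warning("draw ", d, " has zero genetic variance; uniform shares assigned")
      shares[d, ] <- 100 / length(wids)
    } else {
      shares[d, ] <- 100 * vw / tot
    }
  }
  shares
}

#' Significance threshold under the k-fold infinitesimal rule
#'
#' Under an infinitesimal model each of `n_windows` windows is expected to
#' explain `100 / n_windows` percent of the genetic variance; a window is
#' called significant when its posterior mean share reaches `fold` times that
#' expectation.
#'
#' @param n_windows Number of non-overlapping windows.
#' @param fold Multiplier over the infinitesimal expectation (default 5).
#' @return Threshold in percent of genetic variance (full precision).
#' @export
window_threshold <- function(n_windows, fold = 5) {
  stopifnot(n_windows >= 1, fold > 0)
  fold * 100 / n_windows
}

#' Posterior window summaries and significance calls
#'
#' Averages per-draw window shares into posterior mean percentages, computes
#' each window's posterior probability of association (PPA) as the fraction of
#' draws in which its share exceeds the infinitesimal expectation, and flags
#' windows at or above the `fold`-times-expected threshold.
#'
#' @param share_draws Draws x windows percent-share matrix from
#'   [window_variance_draws()].
#' @param window_info The `windows` data frame from [assign_windows()]
#'   (aligned to the columns of `share_draws`).
#' @param fold Significance multiplier (default 5).
#' @return `window_info` augmented with `pct_genetic_variance`, `ppa` and
#'   `significant`.
#' @export
summarize_windows <- function(share_draws, window_info, fold = 5) {
  stopifnot(ncol(share_draws) == nrow(window_info))
  n_windows <- nrow(window_info)
  expected <- 100 / n_windows
  out <- window_info
  out$pct_genetic_variance <- colMeans(share_draws)
  out$ppa <- colMeans(share_draws > expected)
  out$significant <- out$pct_genetic_variance >= window_threshold(n_windows, fold)
  out
}

#' Deduplicate significant windows across traits
#'
#' Trait-level window results often report the same physical window for
#' several traits; the unique-QTL count is the number of distinct
#' (chromosome, window) pairs.
#'
#' @param results Data frame with at least `chromosome` and `window_mb`
#'   columns (rows from one or more traits).
#' @return List with `windows` (distinct chromosome/window_mb pairs, first
#'   occurrence order) and `n` (their count).
#' @export
unique_qtl <- function(results) {
  if (nrow(results) == 0L) {
    return(list(windows = results[, c("chromosome", "window_mb"), drop = FALSE], n = 0L))
  }
  key <- paste(results$chromosome, results$window_mb, sep = ":")
  first <- !duplicated(key)
  windows <- results[first, c("chromosome", "window_mb"), drop = FALSE]
  rownames(windows) <- NULL
  list(windows = windows, n = sum(first))
}

#' Cumulative genetic variance of a trait's significant windows
#'
#' @param results Window results for one trait with columns
#'   `pct_genetic_variance` and (optionally) `significant`; when the flag is
#'   present only significant rows are summed.
#' @return Percent sum.
#' @export
cumulative_variance <- function(results) {
  if ("significant" %in% names(results)) {
    results <- results[results$significant, , drop = FALSE]
  }
  sum(results$pct_genetic_variance)
}
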