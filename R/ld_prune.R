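# Pairwise composite r-squared, greedy one-tag-per-correlated-set pruning,
# and triage of predicted-deleterious SNPs inside significant windows.

#' Pairwise r-squared between markers
#'
#' Composite (genotype-correlation) linkage disequilibrium: the squared
#' Pearson correlation of dosage vectors over animals non-missing at both
#' markers. Phase is not inferred. Zero-variance markers give `NA` for their
#' pairs; pairs with fewer than two complete observations are `NA`.
#'
#' @param genotypes Animals x markers dosage matrix.
#' @param markers Optional marker ids (column names) restricting the matrix.
#' @return Symmetric matrix of r-squared values with unit diagonal for
#'   polymorphic markers.
#' @export
pairwise_r2 <- function(genotypes, markers = NULL) {
  if (!is.null(markers)) {
    missing_ids <- setdiff(markers, colnames(genotypes))
    if (length(missing_ids)) stop("markers not in genotype matrix: ",
                                  paste(missing_ids, collapse = ", "))
    genotypes <- genotypes[, markers, drop = FALSE]
  }
  r <- suppressWarnings(cor(genotypes, use = "pairwise.complete.obs"))
  r2 <- r^2
  diag(r2)[apply(genotypes, 2, function(x) sd(x, na.rm = TRUE) > 0)] <- 1
  r2
}

#' Greedy tag-SNP selection
#'
#' Markers are visited in order of decreasing minor allele frequency (ties
#' broken by ascending position, then marker id); each visited marker not yet
#' removed becomes a tag, and every remaining marker with `r2 > threshold` to
#' it is removed and recorded against that tag. The kept set therefore has
#' all pairwise `r2 <= threshold`.
#'
#' @param r2 Symmetric r-squared matrix (dimnames = marker ids), e.g. from
#'   [pairwise_r2()]. `NA` entries are treated as no LD.
#' @param maf Named minor-allele-frequency vector for the same markers.
#' @param position_bp Named position vector used for tie-breaks.
#' @param threshold Remove markers with `r2 >` this value to a tag
#'   (default 0.7).
#' @return List of class `ld_prune_result`: `kept` (marker ids) and
#'   `removed` (data frame marker_id, tag, r2).
#' @export
tag_select <- function(r2, maf, position_bp, threshold = 0.7) {
  ids <- colnames(r2)
  stopifnot(!is.null(ids), all(ids %in% names(maf)), all(ids %in% names(position_bp)))
  ord <- ids[order(-maf[ids], position_bp[ids], ids)]
  removed <- data.frame(marker_id = character(), tag = character(),
                        r2 = numeric(), stringsAsFactors = FALSE)
  active <- setNames(rep(TRUE, length(ids)), ids)
  kept <- character()
  for (id in ord) {
    if (!active[id]) next
    kept <- c(kept, id)
    active[id] <- FALSE
    r2_to_tag <- r2[id, names(active)[active]]
    hits <- names(r2_to_tag)[!is.na(r2_to_tag) & r2_to_tag > threshold]
    if (length(hits)) {
      removed <- rbind(removed, data.frame(marker_id = hits, tag = id,
                                           r2 = as.numeric(r2[id, hits]),
                                           stringsAsFactors = FALSE))
      active[hits] <- FALSE
    }
  }
  structure(list(kept = kept, removed = removed), class = "ld_prune_result")
}

#' Select predicted-deleterious SNPs inside significant windows
#'
#' Keeps annotated markers whose SIFT score is at or below the deleterious
#' cutoff and whose map position falls within the span of a significant
#' window. Annotated markers absent from the map are skipped with a warning.
#'
#' @param annotation Annotation table ([read_annotation()] format).
#' @param windows Window results (rows of [summarize_windows()] output);
#'   only rows with `significant == TRUE` are used when the flag is present.
#' @param map A [marker_map].
#' @param sift_cutoff Deleterious threshold on the SIFT score (default 0.05,
#'   inclusive).
#' @param size_bp Window size used when the windows were built (default 1 Mb).
#' @return Data frame of candidate markers: marker_id, chromosome,
#'   position_bp, window_mb, gene_symbol, sift_score.
#' @export
select_deleterious <- function(annotation, windows, map, sift_cutoff = 0.05,
                               size_bp = 1e6) {
  if ("significant" %in% names(windows)) {
    windows <- windows[windows$significant, , drop = FALSE]
  }
  del <- annotation[!is.na(annotation$sift_score) &
                      annotation$sift_score <= sift_cutoff, , drop = FALSE]
  unknown <- setdiff(del$marker_id, map$marker_id)
  if (length(unknown)) {
    warning("annotated marker(s) absent from map, skipped: ",
            paste(unknown, collapse = ", "))
    del <- del[!del$marker_id %in% unknown, , drop = FALSE]
  }
  idx <- match(del$marker_id, map$marker_id)
  chrom <- map$chromosome[idx]
  pos <- map$position_bp[idx]
  wmb <- (pos - 1L) %/% as.integer(size_bp)
  in_sig <- paste(chrom, wmb) %in% paste(windows$chromosome, windows$window_mb)
  out <- data.frame(marker_id = del$marker_id, chromosome = chrom,
                    position_bp = pos, window_mb = wmb,
                    gene_symbol = del$gene_symbol, sift_score = del$sift_score,
                    stringsAsFactors = FALSE)[in_sig, , drop = FALSE]
  rownames(out) <- NULL
  out
}
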