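# Readers and writers for the plain-text interchange formats the pipeline
# uses: PLINK-style .ped/.map genotypes, delimited phenotype / annotation /
# sequenced-variant tables, and tab-separated result tables. All downstream
# modules consume only the in-memory objects produced here.

#' Construct and validate a marker map
#'
#' A marker map holds one row per SNP: identifier, chromosome label, 1-based
#' physical position and the two alleles. The second (`alt`) allele is the
#' counted "B" allele of the dosage coding unless a reader is told otherwise.
#'
#' @param marker_id Character vector of unique marker identifiers.
#' @param chromosome Character (or coercible) chromosome labels.
#' @param position_bp Integer 1-based physical positions.
#' @param ref_allele,alt_allele Single-character nucleotide codes; must differ
#'   within a marker.
#' @return A `data.frame` with class `marker_map`, sorted by chromosome then
#'   position.
#' @export
marker_map <- function(marker_id, chromosome, position_bp, ref_allele, alt_allele) {
  mm <- data.frame(
    marker_id = as.character(marker_id),
    chromosome = as.character(chromosome),
    position_bp = as.integer(position_bp),
    ref_allele = as.character(ref_allele),
    alt_allele = as.character(alt_allele),
    stringsAsFactors = FALSE
  )
  mm <- mm[order(mm$chromosome, mm$position_bp), , drop = FALSE]
  rownames(mm) <- NULL
  class(mm) <- c("marker_map", "data.frame")
  validate_marker_map(mm)
}

#' @rdname marker_map
#' @param x A candidate marker map.
#' @export
validate_marker_map <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("marker_id", "chromosome", "position_bp", "ref_allele", "alt_allele")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("marker map lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$marker_id)) stop("marker_id values must be unique")
  if (any(x$position_bp < 1L)) stop("position_bp must be >= 1 (1-based)")
  same <- x$ref_allele == x$alt_allele
  if (any(same)) {
    stop("ref and alt alleles identical for marker(s): ",
         paste(utils::head(x$marker_id[same], 5), collapse = ", "))
  }
  by_chr <- split(x$position_bp, x$chromosome)
  bad <- names(by_chr)[vapply(by_chr, function(p) any(diff(sort(p)) == 0), logical(1))]
  if (length(bad)) stop("duplicated positions within chromosome(s): ",
                        paste(bad, collapse = ", "))
  x
}

#' Read PLINK-style text genotypes
#'
#' Parses a whitespace-delimited `.map` (chromosome, marker id, cM, bp) and
#' `.ped` (6 metadata columns then two allele calls per marker) file pair into
#' an animals-by-markers dosage matrix counting copies of the designated
#' allele. `"0 0"` allele pairs become `NA` (missing).
#'
#' @param ped_path,map_path Paths to the `.ped` and `.map` files.
#' @param count_allele Which allele of each marker is counted by the dosage:
#'   `"alt"` (the second allele, the default) or `"ref"`.
#' @param alt_alleles Optional character vector (length = number of markers)
#'   fixing each marker's alt allele, e.g. `map$alt_allele` from a trusted
#'   map. The `.map` format itself carries no allele columns, so without this
#'   the alt allele is taken as the alphabetically second allele observed in
#'   the `.ped`.
#' @return A list with `genotypes` (integer matrix, animals x markers, dimnames
#'   set) and `map` (a [marker_map]). Allele columns of the map record the
#'   alleles observed in the `.ped`; monomorphic markers get `"0"` as the
#'   unseen allele.
#' @export
read_plink_text <- function(ped_path, map_path, count_allele = c("alt", "ref"),
                            alt_alleles = NULL) {
  count_allele <- match.arg(count_allele)
  stopifnot(file.exists(ped_path), file.exists(map_path))

  map_raw <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "numeric", "integer"))
  if (ncol(map_raw) != 4L) stop(".map must have 4 whitespace-separated columns")
  names(map_raw) <- c("chromosome", "marker_id", "cm", "position_bp")
  k <- nrow(map_raw)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0L) stop(".ped is empty")
  alleles_ok <- c("A", "C", "G", "T", "0", "1", "2")

  animal_ids <- character(n)
  calls <- matrix("0", nrow = 2L * k, ncol = n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != 6L + 2L * k) {
      stop(sprintf(".ped line %d has %d fields; expected %d (6 metadata + 2 alleles x %d markers)",
                   i, length(f), 6L + 2L * k, k))
    }
    a <- f[-(1:6)]
    bad <- setdiff(unique(a), alleles_ok)
    if (length(bad)) stop(sprintf(".ped line %d: unknown allele symbol(s) %s",
                                  i, paste(bad, collapse = ", ")))
    animal_ids[i] <- f[2]
    calls[, i] <- a
  }
  if (anyDuplicated(animal_ids)) stop("duplicate animal ids in .ped")

  dosage <- matrix(NA_integer_, nrow = n, ncol = k,
                   dimnames = list(animal_ids, map_raw$marker_id))
  ref <- alt <- character(k)
  for (j in seq_len(k)) {
    a1 <- calls[2L * j - 1L, ]
    a2 <- calls[2L * j, ]
    obs <- a1[a1 != "0"]
    obs <- sort(unique(c(obs, a2[a2 != "0"])))
    if (length(obs) > 2L) {
      stop(sprintf("marker %s has >2 alleles: %s", map_raw$marker_id[j],
                   paste(obs, collapse = ", ")))
    }
    if (!is.null(alt_alleles)) {
      alt[j] <- alt_alleles[j]
      other <- setdiff(obs, alt[j])
      if (length(other) > 1L) {
        stop(sprintf("marker %s: observed alleles %s inconsistent with designated alt %s",
                     map_raw$marker_id[j], paste(obs, collapse = "/"), alt[j]))
      }
      ref[j] <- if (length(other) == 1L) other else "0"
    } else {
      ref[j] <- if (length(obs) >= 1L) obs[1] else "0"
      alt[j] <- if (length(obs) == 2L) obs[2] else "0"
    }
    counted <- if (count_allele == "alt") alt[j] else ref[j]
    d <- (a1 == counted) + (a2 == counted)
    d[a1 == "0" | a2 == "0"] <- NA_integer_
    dosage[, j] <- as.integer(d)
  }

  mm <- data.frame(marker_id = map_raw$marker_id, chromosome = map_raw$chromosome,
                   position_bp = map_raw$position_bp, ref_allele = ref,
                   alt_allele = alt, stringsAsFactors = FALSE)
  class(mm) <- c("marker_map", "data.frame")
  list(genotypes = dosage, map = mm)
}

#' Write genotypes as PLINK-style text
#'
#' Inverse of [read_plink_text()]: dosages of the map's alt allele become
#' allele-call pairs; `NA` becomes `"0 0"`.
#'
#' @param genotypes Integer dosage matrix (animals x markers, alt-allele
#'   counts, `NA` missing).
#' @param map A [marker_map] aligned to the matrix columns.
#' @param ped_path,map_path Output paths.
#' @export
write_plink_text <- function(genotypes, map, ped_path, map_path) {
  stopifnot(ncol(genotypes) == nrow(map))
  write.table(
    data.frame(map$chromosome, map$marker_id, 0, map$position_bp),
    map_path, quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE
  )
  n <- nrow(genotypes)
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    d <- genotypes[i, ]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, map$alt_allele, map$ref_allele))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2L, map$alt_allele, map$ref_allele))
    writeLines(paste(c("FAM", ids[i], "0", "0", "0", "-9",
                       as.vector(rbind(a1, a2))), collapse = " "), con)
  }
  invisible(NULL)
}

# Sniff the delimiter of a delimited text file from its header line
# (tab wins over comma when both occur).
detect_delim <- function(path) {
  hdr <- readLines(path, n = 50L)
  hdr <- hdr[!startsWith(hdr, "#")][1]
  if (is.na(hdr)) stop("no header line found in ", path)
  if (grepl("\t", hdr)) "\t" else ","
}

read_delim_checked <- function(path, required, numeric_cols = character()) {
  delim <- detect_delim(path)
  df <- read.table(path, header = TRUE, sep = delim, stringsAsFactors = FALSE,
                   comment.char = "#", na.strings = c("NA", ""))
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("file ", path, " lacks mandatory column(s): ", paste(miss, collapse = ", "))
  }
  for (cc in intersect(numeric_cols, names(df))) df[[cc]] <- as.numeric(df[[cc]])
  df
}

#' Read a phenotype table
#'
#' Expects a delimited (tab or comma; auto-detected) table with header columns
#' `animal_id, sex, hatch, dam_family, bw42_g, btw_g, bt_pct, thw_g, th_pct,
#' drw_g, dr_pct, abfw_g, abf_pct`. Weights are grams; `*_pct` traits are
#' percent of BW42. Rows failing validation (duplicate ids, percent outside
#' \[0,100\], negative weights) are rejected, with counts reported via the
#' `n_accepted` / `n_rejected` attributes and a message.
#'
#' @param path Path to the delimited text file.
#' @return A validated `data.frame` of phenotypes (factors for sex, hatch and
#'   dam_family).
#' @export
read_phenotypes <- function(path) {
  df <- read_delim_checked(path, PHENO_COLUMNS,
                           numeric_cols = PHENO_COLUMNS[-(1:4)])
  n_in <- nrow(df)
  ok <- !duplicated(df$animal_id)
  pct_cols <- grep("_pct$", PHENO_COLUMNS, value = TRUE)
  wt_cols <- grep("_g$", PHENO_COLUMNS, value = TRUE)
  for (cc in pct_cols) ok <- ok & (is.na(df[[cc]]) | (df[[cc]] >= 0 & df[[cc]] <= 100))
  for (cc in wt_cols) ok <- ok & (is.na(df[[cc]]) | df[[cc]] >= 0)
  rejected <- sum(!ok)
  if (rejected) message(rejected, " phenotype row(s) rejected during validation")
  df <- df[ok, , drop = FALSE]
  df$animal_id <- as.character(df$animal_id)
  df$sex <- factor(df$sex)
  df$hatch <- factor(df$hatch)
  df$dam_family <- factor(df$dam_family)
  rownames(df) <- NULL
  attr(df, "n_accepted") <- nrow(df)
  attr(df, "n_rejected") <- rejected
  stopifnot(n_in == nrow(df) + rejected)
  df
}

#' Read a variant annotation table
#'
#' Delimited table emulating VEP output: `marker_id, gene_symbol,
#' ensembl_gene_id, consequence, sift_score`. SIFT scores must lie in \[0,1\]
#' when present; offending rows are rejected and counted.
#'
#' @param path Path to the delimited text file.
#' @return A `data.frame` of annotations with `n_accepted`/`n_rejected`
#'   attributes.
#' @export
read_annotation <- function(path) {
  df <- read_delim_checked(
    path, c("marker_id", "gene_symbol", "ensembl_gene_id", "consequence", "sift_score"),
    numeric_cols = "sift_score"
  )
  ok <- is.na(df$sift_score) | (df$sift_score >= 0 & df$sift_score <= 1)
  rejected <- sum(!ok)
  if (rejected) message(rejected, " annotation row(s) rejected (sift_score outside [0,1])")
  df <- df[ok, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_accepted") <- nrow(df)
  attr(df, "n_rejected") <- rejected
  df
}

#' Read sequenced variants from a minimal VCF or a delimited table
#'
#' Accepts either a minimal VCF (CHROM/POS/ID/REF/ALT/QUAL with `DP` in INFO
#' and GT genotypes; parsed with the vcfR package) or a delimited table with
#' columns `marker_id, chromosome, position_bp, ref_allele, alt_allele, depth,
#' qual` followed by one genotype column per animal holding alt-allele dosages
#' (`NA` missing).
#'
#' @param path Path to a `.vcf` file or delimited text table.
#' @return A list with `sites` (a `data.frame`; `alt_allele` may hold a
#'   comma-separated list for multi-allelic sites) and `dosage` (animals x
#'   sites integer matrix of first-alt-allele counts).
#' @export
read_sequenced_variants <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF requires the vcfR package")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
    sites <- data.frame(
      marker_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                         paste0(fix$CHROM, ":", fix$POS), fix$ID),
      chromosome = fix$CHROM,
      position_bp = as.integer(fix$POS),
      ref_allele = fix$REF,
      alt_allele = fix$ALT,
      depth = dp,
      qual = suppressWarnings(as.numeric(fix$QUAL)),
      stringsAsFactors = FALSE
    )
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_integer_)
      a <- strsplit(g, "[/|]")[[1]]
      if (any(a == ".")) return(NA_integer_)
      sum(a == "1")
    })
    dosage <- t(dos)
    colnames(dosage) <- sites$marker_id
  } else {
    df <- read_delim_checked(
      path, c("marker_id", "chromosome", "position_bp", "ref_allele",
              "alt_allele", "depth", "qual"),
      numeric_cols = c("position_bp", "depth", "qual")
    )
    site_cols <- c("marker_id", "chromosome", "position_bp", "ref_allele",
                   "alt_allele", "depth", "qual")
    sites <- df[site_cols]
    gcols <- setdiff(names(df), site_cols)
    dosage <- t(as.matrix(df[gcols]))
    mode(dosage) <- "integer"
    colnames(dosage) <- sites$marker_id
    rownames(dosage) <- gcols
  }
  list(sites = sites, dosage = dosage)
}

#' Write a result table as tab-separated text
#'
#' All pipeline outputs share this writer: tab-separated values with a header
#' comment line carrying the package version and, when supplied, the seed of
#' the run, so results are traceable.
#'
#' @param x A `data.frame`.
#' @param path Output path.
#' @param seed Optional integer recorded in the header comment.
#' @export
write_result_table <- function(x, path, seed = NULL) {
  hdr <- sprintf("# fatmap %s%s", as.character(packageVersion("fatmap")),
                 if (is.null(seed)) "" else sprintf("; seed=%d", as.integer(seed)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(x, con, quote = FALSE, sep = "\t",
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Read a table written by [write_result_table()]
#'
#' @param path Path to the tab-separated file.
#' @return A `data.frame`.
#' @export
read_result_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, na.strings = "NA")
}
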