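# Quality-control filters for OTU tables, genotypes and animal records,
# standardization of counts to the B matrix, descriptive statistics and
# the cow-clustering dendrogram.

#' Filter an OTU count table by sequencing depth and OTU abundance
#'
#' Animals (rows) with fewer total reads than `min_sample_reads` are removed
#' first; then OTUs (columns) whose total count over the remaining animals
#' is below `min_total_count` are removed.
#'
#' @param table integer matrix of counts, animals x OTUs, with ids as
#'   dimnames.
#' @param min_total_count OTUs with column total < this are dropped
#'   (default 10).
#' @param min_sample_reads animals with row total < this are dropped
#'   (default 50000).
#' @return the filtered count matrix, with attributes `dropped_animals` and
#'   `dropped_otus` listing removed ids.
#' @export
filter_otus <- function(table, min_total_count = 10, min_sample_reads = 50000) {
  table <- as_otu_matrix(table)
  keep_animals <- rowSums(table) >= min_sample_reads
  dropped_animals <- rownames(table)[!keep_animals]
  table <- table[keep_animals, , drop = FALSE]
  if (nrow(table) == 0L)
    stop_config("no animals with at least %g reads remain", min_sample_reads)
  keep_otus <- colSums(table) >= min_total_count
  dropped_otus <- colnames(table)[!keep_otus]
  table <- table[, keep_otus, drop = FALSE]
  if (ncol(table) == 0L)
    stop_config("no OTUs with total count of at least %g remain",
                min_total_count)
  structure(table, dropped_animals = dropped_animals,
            dropped_otus = dropped_otus)
}

#' Center and scale OTU counts to the B matrix
#'
#' Each OTU column is centered at its mean and divided by its sample
#' standard deviation (n-1 divisor).  Columns with zero variance carry no
#' between-animal signal and are dropped (recorded in the `dropped_otus`
#' attribute).
#'
#' @param table count matrix, animals x OTUs (>= 2 animals).
#' @return numeric matrix `B` with zero-mean unit-SD columns; attributes
#'   `dropped_otus` (ids of constant columns), `center` and `scale`
#'   (per retained column, for reconstruction).
#' @export
standardize_counts <- function(table) {
  if (is.data.frame(table)) table <- as.matrix(table)
  if (nrow(table) < 2L)
    stop_config("standardization needs at least 2 animals")
  ctr <- colMeans(table)
  sds <- apply(table, 2L, stats::sd)
  keep <- sds > 0
  if (!any(keep))
    stop_config("all OTU columns are constant; nothing to standardize")
  B <- scale(table[, keep, drop = FALSE], center = ctr[keep], scale = sds[keep])
  dropped <- colnames(table)[!keep]
  structure(`attributes<-`(B, list(dim = dim(B), dimnames = dimnames(B))),
            dropped_otus = dropped, center = ctr[keep], scale = sds[keep])
}

#' Filter genotypes by call rate and minor allele frequency
#'
#' Individuals with call rate below `min_individual_call_rate` are removed
#' first; then loci with call rate below `min_locus_call_rate` or minor
#' allele frequency below `min_maf` (both computed after the individual
#' drop) are removed.
#'
#' @param gt genotype matrix, animals x SNPs, entries `{0, 1, 2, NA}`.
#' @param min_individual_call_rate default 0.80.
#' @param min_locus_call_rate default 0.95.
#' @param min_maf default 0.01; loci with MAF strictly below are excluded.
#' @return filtered genotype matrix with attributes `dropped_animals` and
#'   `dropped_snps`.
#' @export
filter_genotypes <- function(gt, min_individual_call_rate = 0.80,
                             min_locus_call_rate = 0.95, min_maf = 0.01) {
  gt <- as_genotype_matrix(gt)
  ind_cr <- rowMeans(!is.na(gt))
  keep_ind <- ind_cr >= min_individual_call_rate
  dropped_animals <- rownames(gt)[!keep_ind]
  gt <- gt[keep_ind, , drop = FALSE]
  if (nrow(gt) == 0L) stop_config("no individuals pass the call-rate filter")

  loc_cr <- colMeans(!is.na(gt))
  p <- colMeans(gt, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0            # loci with no calls at all
  keep_loc <- loc_cr >= min_locus_call_rate & maf >= min_maf
  dropped_snps <- colnames(gt)[!keep_loc]
  gt <- gt[, keep_loc, drop = FALSE]
  if (ncol(gt) == 0L) stop_config("no loci pass the call-rate/MAF filters")
  structure(gt, dropped_animals = dropped_animals, dropped_snps = dropped_snps)
}

#' Restrict phenotype records to matched animals within the lactation window
#'
#' Keeps animals present in every provided id set (typically the rumen,
#' milk and genotype sample lists) whose days in milk do not exceed
#' `max_dim`.
#'
#' @param pheno phenotype data frame with columns `animal_id`, `herd`,
#'   `parity`, `dim` and trait columns.
#' @param matched_ids a list of character vectors of animal ids; animals
#'   must appear in all of them.
#' @param max_dim maximum days in milk retained (default 400; animals with
#'   `dim > max_dim` are removed).
#' @return the filtered data frame, attribute `dropped_animals`.
#' @export
filter_animals <- function(pheno, matched_ids = list(), max_dim = 400) {
  pheno <- as_phenotype_records(pheno)
  keep <- pheno$dim <= max_dim
  for (ids in matched_ids) keep <- keep & pheno$animal_id %in% ids
  dropped <- pheno$animal_id[!keep]
  out <- pheno[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    stop_config("no animals remain after matching ids and dim <= %g filter",
                max_dim)
  rownames(out) <- NULL
  structure(out, dropped_animals = dropped)
}

#' Descriptive statistics per trait
#'
#' Mean, sample SD (n-1 divisor) and coefficient of variation
#' `CV% = 100 * SD / mean` over non-missing values, per trait column.
#' A trait with mean 0 has an undefined CV, reported as `NA`.
#'
#' @param pheno phenotype data frame (see [filter_animals()]).
#' @param traits trait column names; default: every column after `dim`.
#' @return data frame with columns `trait`, `n`, `mean`, `sd`, `cv`.
#' @export
descriptive_stats <- function(pheno, traits = NULL) {
  pheno <- as_phenotype_records(pheno)
  traits <- traits %||% trait_columns(pheno)
  rows <- lapply(traits, function(tr) {
    v <- pheno[[tr]]
    v <- v[!is.na(v)]
    if (length(v) < 2L)
      stop_config("trait '%s' has fewer than 2 non-missing values", tr)
    m <- mean(v); s <- stats::sd(v)
    data.frame(trait = tr, n = length(v), mean = m, sd = s,
               cv = if (m == 0) NA_real_ else 100 * s / m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson distance between animals
#'
#' `d(i, k) = 1 - r(i, k)` where `r` is the Pearson correlation between the
#' standardized OTU abundance profiles (rows) of animals i and k.  Values
#' lie in `[0, 2]`; the diagonal is 0.
#'
#' @param B numeric matrix, animals x OTUs (rows are profiles).
#' @return symmetric n x n distance matrix with animal ids as dimnames.
#' @export
pearson_distance <- function(B) {
  if (is.data.frame(B)) B <- as.matrix(B)
  if (nrow(B) < 2L) stop_config("need at least 2 animals")
  row_sd <- apply(B, 1L, stats::sd)
  if (any(row_sd == 0)) {
    bad <- rownames(B)[row_sd == 0] %||% which(row_sd == 0)
    stop_config("zero-variance profile for animal(s): %s — Pearson distance undefined",
                paste(bad, collapse = ", "))
  }
  D <- 1 - stats::cor(t(B))
  diag(D) <- 0
  D
}

#' Hierarchical clustering of animals
#'
#' Agglomerative clustering of a distance matrix; a thin wrapper around
#' [stats::hclust()] that validates its input.  Default linkage is
#' `"complete"` (the `hclust` default).
#'
#' @param distances symmetric non-negative distance matrix.
#' @param linkage linkage method passed to `hclust` (default `"complete"`).
#' @return an `hclust` object (merge tree with heights).
#' @export
hierarchical_cluster <- function(distances, linkage = "complete") {
  if (is.data.frame(distances)) distances <- as.matrix(distances)
  if (!is.matrix(distances) || nrow(distances) != ncol(distances))
    stop_config("`distances` must be a square matrix")
  if (max(abs(distances - t(distances))) >= 1e-10)
    stop_config("`distances` must be symmetric")
  if (any(distances < 0))
    stop_config("`distances` must be non-negative")
  stats::hclust(stats::as.dist(distances), method = linkage)
}

# ---- internal coercions ------------------------------------------------

as_otu_matrix <- function(table) {
  if (is.data.frame(table)) table <- as.matrix(table)
  if (!is.matrix(table) || !is.numeric(table))
    stop_config("OTU counts must be a numeric matrix (animals x OTUs)")
  if (any(is.na(table)) || any(table < 0) || any(table != floor(table))) {
    bad <- which(is.na(table) | table < 0 | table != floor(table),
                 arr.ind = TRUE)[1L, ]
    stop_config("OTU counts must be non-negative integers (violated at row %d, column %d)",
                bad[1L], bad[2L])
  }
  if (is.null(rownames(table)))
    stop_config("OTU count matrix needs animal ids as rownames")
  check_ids(rownames(table), "animal")
  if (!is.null(colnames(table))) check_ids(colnames(table), "OTU")
  table
}

as_phenotype_records <- function(pheno) {
  if (!is.data.frame(pheno))
    stop_config("phenotypes must be a data frame")
  need <- c("animal_id", "herd", "parity", "dim")
  miss <- setdiff(need, names(pheno))
  if (length(miss))
    stop_config("phenotype table lacks column(s): %s", paste(miss, collapse = ", "))
  check_ids(pheno$animal_id, "animal")
  if (any(pheno$dim < 1, na.rm = TRUE))
    stop_config("days in milk must be >= 1")
  pheno
}

trait_columns <- function(pheno) {
  setdiff(names(pheno), c("animal_id", "herd", "parity", "dim"))
}
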