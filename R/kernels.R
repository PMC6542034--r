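# Relationship kernels: genomic (G), microbial (M) and their Hadamard
# interaction (GxM).  All kernels are symmetric n x n matrices keyed by
# animal id, positive semi-definite up to a small tolerance; if numerical
# noise pushes the smallest eigenvalue below the tolerance a diagonal
# jitter is added and recorded.

PSD_TOL <- 1e-8
JITTER_LADDER <- c(0, 1e-8, 1e-6, 1e-4)

#' Construct a relationship matrix object
#'
#' Wraps a symmetric similarity matrix with its kind (`"G"`, `"M"`, `"GxM"`
#' or `"I"`) and the diagonal jitter (if any) that was needed to make it
#' positive semi-definite within tolerance.  Users normally obtain these
#' from [grm_vanraden()], [microbial_relationship()] or [hadamard_kernel()]
#' rather than calling this directly.
#'
#' @param values symmetric numeric matrix with animal ids as dimnames.
#' @param kind one of `"G"`, `"M"`, `"GxM"`, `"I"`.
#' @param check_psd if `TRUE` (default), verify the smallest eigenvalue is
#'   above `-1e-8`, adding the smallest jitter from `{1e-8, 1e-6, 1e-4}`
#'   that restores it; an error is raised if none does.
#' @return an object of class `rel_matrix`: the numeric matrix with
#'   attributes `kind` and `psd_adjustment`.
#' @export
rel_matrix <- function(values, kind = c("G", "M", "GxM", "I"),
                       check_psd = TRUE) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop_config("a relationship matrix must be square")
  ids <- rownames(values)
  if (is.null(ids) || is.null(colnames(values)))
    stop_config("relationship matrix needs animal ids as dimnames")
  if (!identical(ids, colnames(values)))
    stop_config("row and column ids of a relationship matrix must agree")
  check_ids(ids, "animal")
  asym <- max(abs(values - t(values)))
  if (asym >= 1e-10)
    stop_config("relationship matrix is not symmetric (max |K - K'| = %g)", asym)
  values <- (values + t(values)) / 2   # scrub rounding asymmetry

  jitter <- 0
  if (check_psd) {
    for (delta in JITTER_LADDER) {
      cand <- values
      if (delta > 0) diag(cand) <- diag(cand) + delta
      lam_min <- min(eigen(cand, symmetric = TRUE, only.values = TRUE)$values)
      if (lam_min >= -PSD_TOL) {
        values <- cand
        jitter <- delta
        break
      }
      if (delta == JITTER_LADDER[length(JITTER_LADDER)])
        stop_config("kernel is not positive semi-definite even after jitter %g",
                    delta)
    }
  }
  structure(values, kind = kind, psd_adjustment = jitter,
            class = c("rel_matrix", "matrix", "array"))
}

#' @export
print.rel_matrix <- function(x, ...) {
  cat(sprintf("<rel_matrix %s> %d animals, psd jitter %g\n",
              attr(x, "kind"), nrow(x), attr(x, "psd_adjustment")))
  invisible(x)
}

kernel_kind <- function(K) attr(K, "kind") %||% "I"

#' Genomic relationship matrix (VanRaden method 1)
#'
#' Builds the GRM from additive genotype codes 0/1/2.  Missing codes are
#' mean-imputed to twice the observed allele frequency of their locus, the
#' codes are centered columnwise at `2 p_j`, and
#' `G = Z Z' / (2 * sum_j p_j (1 - p_j))` where `p_j` is the observed
#' counted-allele frequency.
#'
#' @param gt genotype matrix, animals x SNPs, entries in `{0, 1, 2, NA}`,
#'   animal ids as rownames.
#' @return a [rel_matrix()] of kind `"G"`.
#' @export
grm_vanraden <- function(gt) {
  gt <- as_genotype_matrix(gt)
  p <- colMeans(gt, na.rm = TRUE) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop_config("all loci are monomorphic: VanRaden denominator 2*sum(p(1-p)) is 0")
  Z <- sweep(gt, 2L, 2 * p)
  Z[is.na(Z)] <- 0        # mean imputation: missing -> 2p, i.e. centered 0
  G <- tcrossprod(Z) / denom
  rel_matrix(G, kind = "G")
}

#' Microbial relationship matrix
#'
#' `M = B B' / c` where `B` is the centered-and-scaled OTU count matrix
#' from [standardize_counts()] and `c` the number of OTUs.  Because each
#' column of `B` has unit sample SD (n-1 divisor), `trace(M) = n - 1`
#' exactly.
#'
#' @param B standardized OTU matrix (animals x OTUs), animal ids as rownames.
#' @return a [rel_matrix()] of kind `"M"`.
#' @export
microbial_relationship <- function(B) {
  if (!is.matrix(B) || !is.numeric(B))
    stop_config("`B` must be a numeric matrix of standardized OTU abundances")
  if (ncol(B) < 1L) stop_config("`B` has no OTU columns")
  if (is.null(rownames(B)))
    stop_config("`B` needs animal ids as rownames")
  M <- tcrossprod(B) / ncol(B)
  rel_matrix(M, kind = "M")
}

#' Hadamard (elementwise) interaction kernel
#'
#' Elementwise product of two relationship matrices on the same animals in
#' the same order; models genome-by-microbiome interaction covariance.  No
#' rescaling is applied, so its diagonal is the product of the parent
#' diagonals, not ~1.
#'
#' @param K1,K2 [rel_matrix()] objects with identical animal id order.
#' @return a [rel_matrix()] of kind `"GxM"`.
#' @export
hadamard_kernel <- function(K1, K2) {
  if (!identical(rownames(K1), rownames(K2)))
    stop_config("Hadamard product requires identical animal id order")
  rel_matrix(unclass(K1) * unclass(K2), kind = "GxM")
}

#' Subset and reorder a kernel to a given id list
#'
#' @param K a [rel_matrix()].
#' @param ids animal ids to keep, in the desired order; must all be present.
#' @return the kernel restricted to `ids`, same kind, no PSD re-check
#'   (a principal submatrix of a PSD matrix is PSD).
#' @export
align_kernel <- function(K, ids) {
  missing_ids <- setdiff(ids, rownames(K))
  if (length(missing_ids))
    stop_config("ids not present in kernel: %s",
                paste(missing_ids, collapse = ", "))
  out <- unclass(K)[ids, ids, drop = FALSE]
  structure(out, kind = kernel_kind(K),
            psd_adjustment = attr(K, "psd_adjustment") %||% 0,
            class = c("rel_matrix", "matrix", "array"))
}

#' Identity kernel for a set of animals
#' @param ids animal ids.
#' @return a [rel_matrix()] of kind `"I"`.
#' @export
identity_kernel <- function(ids) {
  n <- length(ids)
  I <- diag(n)
  dimnames(I) <- list(ids, ids)
  rel_matrix(I, kind = "I", check_psd = FALSE)
}

# Coerce/validate an animals x SNPs genotype matrix.
as_genotype_matrix <- function(gt) {
  if (is.data.frame(gt)) gt <- as.matrix(gt)
  if (!is.matrix(gt) || !is.numeric(gt))
    stop_config("genotypes must be a numeric matrix (animals x SNPs)")
  ok <- is.na(gt) | gt %in% c(0, 1, 2)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop_config("genotype code outside {0,1,2,NA} at row %d, column %d",
                bad[1L], bad[2L])
  }
  if (is.null(rownames(gt)))
    stop_config("genotype matrix needs animal ids as rownames")
  check_ids(rownames(gt), "animal")
  gt
}
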