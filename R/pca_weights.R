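#' Construct a per-SNP weight vector
#'
#' @param weight numeric weights, one per SNP of the target dataset (`NA`
#'   allowed; such SNPs are ignored downstream).
#' @param snp_id SNP identifiers.
#' @param provenance `"freq-difference"` or `"pca-loading"`.
#' @param axis principal-component index (for PCA loadings).
#' @return An object of class `weight_vector`.
#' @export
weight_vector <- function(weight, snp_id,
                          provenance = c("freq-difference", "pca-loading"),
                          axis = NA_integer_) {
  provenance <- match.arg(provenance)
  stopifnot(length(weight) == length(snp_id),
            all(is.finite(weight) | is.na(weight)))
  structure(list(weight = as.numeric(weight), snp_id = as.character(snp_id),
                 provenance = provenance, axis = axis),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("weight_vector:", length(x$weight), "SNPs, provenance =",
      x$provenance, if (!is.na(x$axis)) paste0("(axis ", x$axis, ")"), "\n")
  invisible(x)
}

#' Standardize a dosage matrix for PCA
#'
#' Per SNP: subtract the mean dosage and divide by `sqrt(p(1-p))` with `p`
#' the sample alternate-allele frequency; missing entries are set to 0 after
#' centering. Monomorphic and constant-dosage SNPs are dropped.
#'
#' @param data a [genotype_dataset()].
#' @param verbose log the number of monomorphic SNPs dropped.
#' @return list with `X` (samples x SNPs standardized matrix) and `keep`
#'   (logical index of retained SNPs).
#' @export
standardize_genotypes <- function(data, verbose = FALSE) {
  stopifnot(inherits(data, "genotype_dataset"))
  G <- data$geno
  mu <- rowMeans(G, na.rm = TRUE)
  p <- mu / 2
  rv <- rowSums((G - mu)^2, na.rm = TRUE)   # 0 for constant columns
  keep <- !is.na(p) & p > 0 & p < 1 & rv > 0
  if (verbose && any(!keep))
    message("standardize_genotypes: dropped ", sum(!keep),
            " monomorphic/all-missing SNPs")
  Z <- (G[keep, , drop = FALSE] - mu[keep]) /
    sqrt(p[keep] * (1 - p[keep]))
  Z[is.na(Z)] <- 0
  list(X = t(Z), keep = keep)
}

#' PCA loadings of a reference panel as admixture-LD weights
#'
#' Performs sample PCA on SMARTPCA-style standardized genotypes of a
#' reference panel and returns the per-SNP loadings of one axis as a
#' [weight_vector()]. By default the axis is the one whose sample scores
#' best separate the panel's population labels (largest between- to
#' within-population variance ratio); loadings are unit-normalized (their
#' scale only affects curve amplitude, never fitted dates).
#'
#' @param reference a [genotype_dataset()] holding the reference panel (at
#'   least two populations for automatic axis selection).
#' @param axis principal-component index, or `NULL` to auto-select.
#' @param target_snp_ids optional SNP id vector of the target dataset; the
#'   returned weights are aligned to it (`NA` where a SNP is absent from the
#'   reference).
#' @param n_axes number of axes to examine during auto-selection.
#' @return A [weight_vector()] with provenance `"pca-loading"`.
#' @export
pca_loadings <- function(reference, axis = NULL, target_snp_ids = NULL,
                         n_axes = 5L) {
  stopifnot(inherits(reference, "genotype_dataset"))
  if (nrow(reference$ind) < 2L) stop("need at least 2 reference samples")
  std <- standardize_genotypes(reference)
  X <- std$X
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X))
  K <- tcrossprod(Xc) / (n - 1)          # n x n Gram matrix
  eig <- eigen(K, symmetric = TRUE)
  n_axes <- min(n_axes, n - 1L)
  if (is.null(axis)) {
    if (length(unique(reference$ind$pop)) < 2L)
      stop("axis auto-selection needs >= 2 reference populations")
    ratio <- vapply(seq_len(n_axes), function(k) {
      sc <- eig$vectors[, k]
      fit <- stats::aov(sc ~ factor(reference$ind$pop))
      ss <- summary(fit)[[1]][["Sum Sq"]]
      ss[1] / (ss[2] + 1e-12)
    }, numeric(1))
    axis <- which.max(ratio)
  }
  u <- eig$vectors[, axis]
  load <- drop(crossprod(Xc, u))         # SNP loadings of the chosen axis
  load <- load / sqrt(sum(load^2))
  ids <- reference$snp$id[std$keep]
  if (!is.null(target_snp_ids)) {
    w <- load[match(target_snp_ids, ids)]
    weight_vector(w, target_snp_ids, "pca-loading", axis)
  } else {
    weight_vector(load, ids, "pca-loading", axis)
  }
}

#' Allele-frequency-difference weights
#'
#' The classical admixture-LD weight: `w = pA - pB` per SNP, with `pA`,
#' `pB` the alternate-allele frequencies in the two ancestral (or surrogate)
#' populations.
#'
#' @param freqs an `allele_freq_table` (see [allele_frequencies()]).
#' @param popA,popB population names present in `freqs`.
#' @return A [weight_vector()] with provenance `"freq-difference"`; SNPs with
#'   a missing frequency get weight `NA`.
#' @export
freq_difference_weights <- function(freqs, popA, popB) {
  stopifnot(inherits(freqs, "allele_freq_table"),
            popA %in% freqs$pops, popB %in% freqs$pops)
  w <- freqs$freq[, popA] - freqs$freq[, popB]
  w[!is.finite(w)] <- NA_real_
  weight_vector(w, freqs$snp$id, "freq-difference")
}
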