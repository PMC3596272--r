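#' Construct a genotype dataset
#'
#' The universal container consumed by every estimator in the package: a
#' SNP-major dosage matrix (count of the alternate allele, `NA` = missing)
#' together with a genetic/physical map and per-sample population labels.
#'
#' @param geno integer matrix, one row per SNP and one column per sample,
#'   values in `{0, 1, 2, NA}`.
#' @param snp data frame with columns `id`, `chrom`, `gpos` (genetic position
#'   in Morgans), `ppos` (physical position, 1-based bp), `ref`, `alt`.
#' @param ind data frame with columns `id`, `sex` (`"M"`, `"F"` or `"U"`) and
#'   `pop` (population label).
#'
#' @details Genetic positions must be non-decreasing within each chromosome;
#'   positions supplied in centimorgans should be divided by 100 at the
#'   boundary (all internal distances are Morgans).
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(geno, snp, ind) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  snp <- as.data.frame(snp)
  ind <- as.data.frame(ind)
  stopifnot(
    all(c("id", "chrom", "gpos", "ppos", "ref", "alt") %in% names(snp)),
    all(c("id", "pop") %in% names(ind))
  )
  if (is.null(ind$sex)) ind$sex <- "U"
  if (nrow(geno) != nrow(snp))
    stop("geno has ", nrow(geno), " rows but snp table has ", nrow(snp))
  if (ncol(geno) != nrow(ind))
    stop("geno has ", ncol(geno), " columns but ind table has ", nrow(ind))
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("dosages must be in {0, 1, 2, NA}")
  for (ch in unique(snp$chrom)) {
    g <- snp$gpos[snp$chrom == ch]
    if (is.unsorted(g))
      stop("genetic positions not non-decreasing within chromosome ", ch)
  }
  rownames(geno) <- snp$id
  colnames(geno) <- ind$id
  structure(list(geno = geno, snp = snp, ind = ind),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$snp), "SNPs x", nrow(x$ind), "samples\n")
  cat("  chromosomes:", length(unique(x$snp$chrom)),
      " populations:", paste(unique(x$ind$pop), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$geno)

n_snps <- function(data) nrow(data$snp)
n_samples <- function(data) nrow(data$ind)

#' Construct a phased haplotype dataset
#'
#' Holds two haplotypes per sample as a 0/1 matrix; columns are ordered as
#' sample 1 haplotype 1, sample 1 haplotype 2, sample 2 haplotype 1, ...
#'
#' @param haps integer matrix (SNPs x haplotypes) with values in `{0, 1}`.
#' @param snp SNP map as in [genotype_dataset()].
#' @param ind sample table as in [genotype_dataset()]; the haplotype count
#'   must equal twice the sample count.
#' @return An object of class `haplotype_dataset`.
#' @export
haplotype_dataset <- function(haps, snp, ind) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  snp <- as.data.frame(snp)
  ind <- as.data.frame(ind)
  if (is.null(ind$sex)) ind$sex <- "U"
  if (ncol(haps) != 2L * nrow(ind))
    stop("haplotype count must be 2 x sample count")
  if (nrow(haps) != nrow(snp))
    stop("haps rows must match SNP table")
  if (!all(haps %in% 0:1))
    stop("haplotype alleles must be 0/1")
  colnames(haps) <- paste0(rep(ind$id, each = 2L), "_", c(1L, 2L))
  structure(list(haps = haps, snp = snp, ind = ind),
            class = "haplotype_dataset")
}

#' @export
print.haplotype_dataset <- function(x, ...) {
  cat("haplotype_dataset:", nrow(x$snp), "SNPs x", ncol(x$haps),
      "haplotypes (", nrow(x$ind), "samples )\n")
  invisible(x)
}

#' Collapse haplotypes to genotype dosages
#'
#' Sums each haplotype pair into a dosage and (optionally) masks calls at
#' random to emulate genotyping dropout.
#'
#' @param haps a [haplotype_dataset()].
#' @param missing_rate probability in `[0, 1)` that an individual call is set
#'   to missing, independently per call.
#' @param seed optional integer seed for the masking draw.
#' @return A [genotype_dataset()].
#' @export
genotypes_from_haplotypes <- function(haps, missing_rate = 0, seed = NULL) {
  stopifnot(inherits(haps, "haplotype_dataset"),
            missing_rate >= 0, missing_rate < 1)
  n <- nrow(haps$ind)
  g <- haps$haps[, 2L * seq_len(n) - 1L, drop = FALSE] +
       haps$haps[, 2L * seq_len(n), drop = FALSE]
  if (missing_rate > 0) {
    if (!is.null(seed)) set.seed(seed)
    g[stats::runif(length(g)) < missing_rate] <- NA_integer_
  }
  genotype_dataset(g, haps$snp, haps$ind)
}

#' Subset a genotype dataset
#'
#' @param data a [genotype_dataset()].
#' @param snps logical/integer index over SNPs (default: keep all).
#' @param samples logical/integer index over samples (default: keep all).
#' @return The subsetted [genotype_dataset()].
#' @export
subset_dataset <- function(data, snps = NULL, samples = NULL) {
  stopifnot(inherits(data, "genotype_dataset"))
  if (is.null(snps)) snps <- seq_len(nrow(data$snp))
  if (is.null(samples)) samples <- seq_len(nrow(data$ind))
  genotype_dataset(data$geno[snps, samples, drop = FALSE],
                   data$snp[snps, , drop = FALSE],
                   data$ind[samples, , drop = FALSE])
}

#' Per-population alternate-allele frequencies
#'
#' Computes, for each SNP and each requested population, the alternate-allele
#' frequency over non-missing genotypes and the number of observed alleles.
#'
#' @param data a [genotype_dataset()].
#' @param pops character vector of population labels; defaults to all
#'   populations present.
#' @return An object of class `allele_freq_table` with components `freq`
#'   (SNP x population frequency matrix, `NaN` where a population has no
#'   call), `count` (observed allele counts), `snp` (the map) and `pops`.
#'   SNPs missing in every requested population are flagged in the logical
#'   vector `all_missing`.
#' @export
allele_frequencies <- function(data, pops = NULL) {
  stopifnot(inherits(data, "genotype_dataset"))
  if (is.null(pops)) pops <- unique(data$ind$pop)
  unknown <- setdiff(pops, data$ind$pop)
  if (length(unknown))
    stop("unknown population(s): ", paste(unknown, collapse = ", "))
  freq <- matrix(NA_real_, nrow(data$snp), length(pops),
                 dimnames = list(data$snp$id, pops))
  count <- matrix(0L, nrow(data$snp), length(pops),
                  dimnames = list(data$snp$id, pops))
  for (k in seq_along(pops)) {
    g <- data$geno[, data$ind$pop == pops[k], drop = FALSE]
    nobs <- rowSums(!is.na(g))
    count[, k] <- 2L * nobs
    freq[, k] <- rowSums(g, na.rm = TRUE) / (2 * nobs)  # NaN when nobs = 0
  }
  structure(list(freq = freq, count = count, snp = data$snp, pops = pops,
                 all_missing = rowSums(count) == 0L),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat("allele_freq_table:", nrow(x$freq), "SNPs x",
      length(x$pops), "populations (", paste(x$pops, collapse = ", "), ")\n")
  invisible(x)
}

#' Filter samples and SNPs by missingness
#'
#' Two passes at the same threshold: samples whose missing-call fraction
#' exceeds `max_rate` are removed first, then SNPs are filtered on the
#' surviving samples. The sample-first order is fixed so results are
#' reproducible.
#'
#' @param data a [genotype_dataset()].
#' @param max_rate maximum tolerated missing fraction (default 0.05).
#' @param verbose log the counts removed by each pass.
#' @return The filtered [genotype_dataset()]; possibly empty (with a warning).
#' @export
filter_missingness <- function(data, max_rate = 0.05, verbose = FALSE) {
  stopifnot(inherits(data, "genotype_dataset"),
            max_rate >= 0, max_rate <= 1)
  miss_s <- colMeans(is.na(data$geno))
  keep_s <- miss_s <= max_rate
  g <- data$geno[, keep_s, drop = FALSE]
  miss_m <- if (ncol(g)) rowMeans(is.na(g)) else rep(0, nrow(g))
  keep_m <- miss_m <= max_rate
  if (verbose)
    message("filter_missingness: dropped ", sum(!keep_s), " samples then ",
            sum(!keep_m), " SNPs at rate > ", max_rate)
  if (!any(keep_s) || !any(keep_m))
    warning("filter_missingness removed every sample or SNP")
  subset_dataset(data, snps = keep_m, samples = keep_s)
}

#' Thin SNPs by pairwise genotypic correlation
#'
#' Sliding-window LD pruning: within each window of `window` SNPs, any pair
#' with squared genotypic (dosage) correlation above `r2_max` loses its
#' later-index member; the window then advances by `step` SNPs. The greedy
#' pass is deterministic: when a pair exceeds the threshold the lower-index
#' SNP is always the one retained.
#'
#' @param data a [genotype_dataset()].
#' @param r2_max squared-correlation threshold (default 0.1).
#' @param window window size in SNPs (default 50).
#' @param step window increment in SNPs (default 5).
#' @return The thinned [genotype_dataset()].
#' @export
ld_thin <- function(data, r2_max = 0.1, window = 50L, step = 5L) {
  stopifnot(inherits(data, "genotype_dataset"), nrow(data$snp) >= 2L)
  p <- nrow(data$snp)
  keep <- rep(TRUE, p)
  G <- data$geno
  start <- 1L
  repeat {
    end <- min(start + window - 1L, p)
    idx <- start:end
    idx <- idx[keep[idx]]
    if (length(idx) >= 2L) {
      cc <- suppressWarnings(
        stats::cor(G[idx, , drop = FALSE] |> t(),
                   use = "pairwise.complete.obs"))
      cc[is.na(cc)] <- 0
      r2 <- cc^2
      for (a in seq_along(idx)) {
        if (!keep[idx[a]]) next
        for (b in seq_along(idx)) {
          if (b <= a || !keep[idx[b]]) next
          if (r2[a, b] > r2_max) keep[idx[b]] <- FALSE
        }
      }
    }
    if (end >= p) break
    start <- start + step
  }
  subset_dataset(data, snps = keep)
}
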