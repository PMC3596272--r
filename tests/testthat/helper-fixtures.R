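# Shared fixtures and independent brute-force oracles. The oracles are
# plain-R double loops kept deliberately separate from the package kernels.

make_snp_map <- function(n, chrom = "chr1", gpos = NULL, ppos = NULL) {
  if (is.null(gpos)) gpos <- seq(0, 0.5, length.out = n)
  if (is.null(ppos)) ppos <- round(gpos * 1e8) + 1
  data.frame(id = paste0("s", seq_len(n)), chrom = chrom, gpos = gpos,
             ppos = ppos, ref = "A", alt = "C")
}

make_ind <- function(n, pop = "P1", prefix = "i") {
  data.frame(id = paste0(prefix, seq_len(n)), sex = "U",
             pop = rep_len(pop, n))
}

# Small deterministic dataset with a bit of missingness.
make_tiny_dataset <- function(n_snps = 10L, n_samples = 8L, seed = 42L,
                              missing = 2L, chrom = NULL) {
  set.seed(seed)
  g <- matrix(sample(0:2, n_snps * n_samples, replace = TRUE),
              n_snps, n_samples)
  if (missing > 0L)
    g[sample(length(g), missing)] <- NA_integer_
  if (is.null(chrom)) chrom <- rep("chr1", n_snps)
  gpos <- numeric(n_snps)
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    gpos[ix] <- sort(runif(length(ix), 0, 0.4))
  }
  genotype_dataset(g, make_snp_map(n_snps, chrom = chrom, gpos = gpos),
                   make_ind(n_samples))
}

make_freq_table <- function(freq, gpos = NULL, chrom = "chr1",
                            count = NULL) {
  n <- nrow(freq)
  snp <- make_snp_map(n, chrom = chrom, gpos = gpos)
  if (is.null(count))
    count <- matrix(Inf, n, ncol(freq), dimnames = dimnames(freq))
  structure(list(freq = freq, count = count, snp = snp,
                 pops = colnames(freq),
                 all_missing = rep(FALSE, n)),
            class = "allele_freq_table")
}

# Brute-force weighted-LD curve: double loop over SNP pairs, pairwise-
# complete sample covariance via stats::cov.
brute_force_ld_curve <- function(data, w, bin_width, d_max) {
  ord <- order(data$snp$chrom, data$snp$gpos)
  G <- data$geno[ord, , drop = FALSE]
  pos <- data$snp$gpos[ord]
  chrom <- data$snp$chrom[ord]
  wv <- w[ord]
  n_bins <- ceiling(d_max / bin_width - 1e-12)
  sums <- counts <- numeric(n_bins)
  p <- nrow(G)
  for (x in seq_len(p - 1)) for (y in (x + 1):p) {
    if (chrom[y] != chrom[x]) next
    d <- pos[y] - pos[x]
    if (d > d_max) next
    b <- min(floor(d / bin_width) + 1, n_bins)
    cv <- suppressWarnings(
      stats::cov(G[x, ], G[y, ], use = "pairwise.complete.obs"))
    if (is.na(cv)) next
    sums[b] <- sums[b] + cv * wv[x] * wv[y]
    counts[b] <- counts[b] + 1
  }
  list(value = ifelse(counts > 0, sums / counts, NA_real_), count = counts)
}

# Brute-force allele-sharing autocorrelation (within minus cross), mirroring
# the documented estimator with stats::cor.
brute_force_sharing_curve <- function(data, target_pop, reference_pop,
                                      bin_width, d_max) {
  ord <- order(data$snp$chrom, data$snp$gpos)
  G <- data$geno[ord, , drop = FALSE]
  pos <- data$snp$gpos[ord]
  chrom <- data$snp$chrom[ord]
  ti <- which(data$ind$pop == target_pop)
  ri <- which(data$ind$pop == reference_pop)
  share <- function(i, j) 1 - abs(G[, i] - G[, j]) / 2
  within <- utils::combn(ti, 2L)
  Sw <- sapply(seq_len(ncol(within)),
               function(k) share(within[1, k], within[2, k]))
  cross <- expand.grid(i = ti, j = ri)
  cross <- cross[cross$i != cross$j, ]
  Sx <- sapply(seq_len(nrow(cross)),
               function(k) share(cross$i[k], cross$j[k]))
  curve_of <- function(S) {
    p <- nrow(S)
    n_bins <- ceiling(d_max / bin_width - 1e-12)
    sums <- counts <- numeric(n_bins)
    for (x in seq_len(p - 1)) for (y in (x + 1):p) {
      if (chrom[y] != chrom[x]) next
      d <- pos[y] - pos[x]
      if (d > d_max) next
      if (stats::sd(S[x, ]) == 0 || stats::sd(S[y, ]) == 0) next
      b <- min(floor(d / bin_width) + 1, n_bins)
      sums[b] <- sums[b] + stats::cor(S[x, ], S[y, ])
      counts[b] <- counts[b] + 1
    }
    list(value = ifelse(counts > 0, sums / counts, NA_real_),
         count = counts)
  }
  # S rows = SNPs here (transposed relative to the package internals)
  cw <- curve_of(Sw)
  cx <- curve_of(Sx)
  list(value = cw$value - cx$value, count = pmin(cw$count, cx$count))
}

# Reference weighted jackknife (Busing-style) computed independently.
oracle_weighted_jackknife_se <- function(theta, loo, m) {
  g <- length(loo)
  n <- sum(m)
  h <- n / m
  theta_j <- g * theta - sum((1 - m / n) * loo)
  tau <- h * theta - (h - 1) * loo
  sqrt(sum((tau - theta_j)^2 / (h - 1)) / g)
}
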