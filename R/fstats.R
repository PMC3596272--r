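#' Assign SNPs to jackknife blocks
#'
#' Blocks are delimited on the genetic map: either consecutive windows of
#' `size` Morgans within each chromosome (default 0.05 M = 5 cM, last
#' partial block kept) or whole chromosomes.
#'
#' @param snp SNP map data frame (columns `chrom`, `gpos`).
#' @param block `"5cM"`, `"chromosome"`, or a numeric block size in
#'   Morgans.
#' @return Integer block index per SNP.
#' @export
assign_blocks <- function(snp, block = "5cM") {
  if (identical(block, "chromosome"))
    return(as.integer(factor(snp$chrom)))
  size <- if (identical(block, "5cM")) 0.05 else as.numeric(block)
  stopifnot(size > 0)
  key <- paste(snp$chrom, floor(snp$gpos / size))
  as.integer(factor(key, levels = unique(key)))
}

# Weighted delete-one-block jackknife (Busing-style): theta is the full
# estimate, loo the delete-one-block estimates, m the block weights.
jackknife_from_loo <- function(theta, loo, m) {
  g <- length(loo)
  if (g < 2L) stop("jackknife needs >= 2 blocks")
  n <- sum(m)
  h <- n / m
  theta <- unname(theta)
  loo <- unname(loo)
  theta_j <- g * theta - sum((1 - m / n) * loo)
  tau <- h * theta - (h - 1) * loo
  var_j <- sum((tau - theta_j)^2 / (h - 1)) / g
  structure(list(estimate = theta, se = sqrt(var_j), n_blocks = g,
                 block_type = NA_character_),
            class = "jackknife_estimate")
}

#' @export
print.jackknife_estimate <- function(x, ...) {
  cat(sprintf("estimate = %.6g +/- %.3g (%d blocks%s)",
              x$estimate, x$se, x$n_blocks,
              if (!is.na(x$block_type)) paste0(", ", x$block_type) else ""))
  if (!is.null(x$Z)) cat(sprintf(", Z = %.2f", x$Z))
  cat("\n")
  invisible(x)
}

# Generic block jackknife of a statistic defined by per-SNP sufficient
# sums: stat_fun(colSums of kept rows) -> scalar. S is a matrix with one
# row per SNP.
jackknife_sums <- function(S, blocks, stat_fun, weights = NULL) {
  g <- max(blocks)
  if (g < 2L) stop("need >= 2 jackknife blocks")
  tot <- colSums(S)
  by_block <- rowsum(S, blocks)
  m <- if (is.null(weights)) tabulate(blocks, g) else weights
  theta <- stat_fun(tot)
  loo <- vapply(seq_len(g), function(j) stat_fun(tot - by_block[j, ]),
                numeric(1))
  jackknife_from_loo(theta, loo, m)
}

#' Weighted block jackknife of a per-SNP mean
#'
#' Delete-one-block jackknife of `mean(values)` with block weights equal to
#' block SNP counts.
#'
#' @param values per-SNP numeric values (`NA` excluded).
#' @param snp SNP map matching `values`.
#' @param block block definition as in [assign_blocks()].
#' @return A `jackknife_estimate` (fields `estimate`, `se`, `n_blocks`,
#'   `block_type`).
#' @export
block_jackknife <- function(values, snp, block = "5cM") {
  keep <- is.finite(values)
  blocks <- assign_blocks(snp[keep, , drop = FALSE], block)
  v <- values[keep]
  jk <- jackknife_sums(cbind(v, 1), blocks,
                       function(s) s[1] / s[2])
  jk$block_type <- if (is.numeric(block)) paste0(block, "M") else block
  jk
}

# Frequencies for 4 populations with complete data; rows with any missing
# frequency are dropped.
f4_freq_rows <- function(freqs, pops) {
  stopifnot(inherits(freqs, "allele_freq_table"),
            all(pops %in% freqs$pops))
  P <- freqs$freq[, pops, drop = FALSE]
  keep <- rowSums(!is.finite(P)) == 0L
  list(P = P[keep, , drop = FALSE], snp = freqs$snp[keep, , drop = FALSE])
}

#' The f4 statistic with block jackknife standard error
#'
#' `f4(A, B; C, D)` = mean over SNPs of `(a - b)(c - d)` with `a..d` the
#' population allele frequencies; zero in expectation when `(A, B)` and
#' `(C, D)` form disjoint clades of an unadmixed tree. SNPs with a missing
#' frequency in any of the four populations are excluded.
#'
#' @param freqs an `allele_freq_table` (see [allele_frequencies()]).
#' @param A,B,C,D population names.
#' @param block jackknife block definition (default 5 cM).
#' @return A `jackknife_estimate` with an added `Z` field (`estimate / se`).
#' @export
f4 <- function(freqs, A, B, C, D, block = "5cM") {
  fr <- f4_freq_rows(freqs, c(A, B, C, D))
  v <- (fr$P[, 1] - fr$P[, 2]) * (fr$P[, 3] - fr$P[, 4])
  jk <- block_jackknife(v, fr$snp, block)
  jk$Z <- if (jk$se > 0) jk$estimate / jk$se else 0
  jk$n_snps <- length(v)
  jk
}

#' The 4-population test of treeness
#'
#' Computes the Pearson correlation over SNPs between the frequency
#' difference vectors `A - B` and `C - D`. Under the unrooted tree
#' `((A, B), (C, D))` with no gene flow the expected correlation is zero;
#' `|Z| > z_crit` (default 3) is reported as a tree rejection, i.e.
#' evidence of admixture. Standard errors come from a 5 cM block jackknife
#' of the correlation.
#'
#' @inheritParams f4
#' @param z_crit rejection threshold on `|Z|`.
#' @return list with `correlation`, `Z`, `reject`, `jackknife` (the
#'   `jackknife_estimate` of the correlation) and `f4` (the companion f4
#'   estimate).
#' @export
four_population_test <- function(freqs, A, B, C, D, block = "5cM",
                                 z_crit = 3) {
  fr <- f4_freq_rows(freqs, c(A, B, C, D))
  x <- fr$P[, 1] - fr$P[, 2]
  y <- fr$P[, 3] - fr$P[, 4]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant frequency-difference vector; correlation undefined")
  blocks <- assign_blocks(fr$snp, block)
  S <- cbind(x, y, x * y, x^2, y^2, 1)
  corr_fun <- function(s) {
    n <- s[6]
    cv <- s[3] / n - (s[1] / n) * (s[2] / n)
    vx <- s[4] / n - (s[1] / n)^2
    vy <- s[5] / n - (s[2] / n)^2
    cv / sqrt(vx * vy)
  }
  jk <- jackknife_sums(S, blocks, corr_fun)
  jk$block_type <- if (is.numeric(block)) paste0(block, "M") else block
  Z <- if (jk$se > 0) jk$estimate / jk$se else 0
  list(correlation = jk$estimate, Z = Z, reject = abs(Z) > z_crit,
       jackknife = jk, f4 = f4(freqs, A, B, C, D, block))
}

#' Ancestry proportion by ratio of f4 statistics
#'
#' Estimates the fraction `p` of the admixed population `X`'s ancestry that
#' derives from the lineage of `cladeW`, as
#' `f4(outgroup, reference; X, cladeS) / f4(outgroup, reference; cladeW,
#' cladeS)`. The estimator is valid when `cladeW` forms a clade with X's
#' W-side source and `cladeS` with its S-side source, relative to
#' `(outgroup, reference)`; no unadmixed sample of either true source is
#' needed. The standard error is a delete-one-block jackknife of the ratio.
#'
#' @param freqs an `allele_freq_table`.
#' @param outgroup,reference,X,cladeW,cladeS population names (outgroup and
#'   reference span the drift used as the measuring stick, e.g. an African
#'   outgroup and a Caucasus reference).
#' @param block jackknife block definition (default 5 cM).
#' @return A `jackknife_estimate` of `p` with fields `num`, `den` (the two
#'   f4 estimates) added.
#' @export
f4_ratio_ancestry <- function(freqs, outgroup, reference, X, cladeW,
                              cladeS, block = "5cM") {
  fr <- f4_freq_rows(freqs, c(outgroup, reference, X, cladeW, cladeS))
  ab <- fr$P[, 1] - fr$P[, 2]
  num_v <- ab * (fr$P[, 3] - fr$P[, 5])
  den_v <- ab * (fr$P[, 4] - fr$P[, 5])
  den_jk <- block_jackknife(den_v, fr$snp, block)
  if (abs(den_jk$estimate) <= 2 * den_jk$se)
    stop("denominator f4 within 2 SE of zero; ratio is unreliable ",
         "(check that cladeW/cladeS are on opposite sides of the mixture)")
  blocks <- assign_blocks(fr$snp, block)
  jk <- jackknife_sums(cbind(num_v, den_v), blocks,
                       function(s) s[1] / s[2])
  jk$block_type <- if (is.numeric(block)) paste0(block, "M") else block
  jk$num <- mean(num_v)
  jk$den <- mean(den_v)
  jk$n_snps <- length(num_v)
  jk
}

#' Hudson-style pairwise Fst with block jackknife
#'
#' Ratio-of-averages estimator: per SNP the numerator is
#' `(p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) - p2 (1 - p2) / (n2 - 1)` (allele
#' counts `n1`, `n2` give the sample-size correction) and the denominator
#' is `p1 (1 - p2) + p2 (1 - p1)`; Fst is the ratio of the two genome-wide
#' sums.
#'
#' @param freqs an `allele_freq_table` carrying observed allele counts.
#' @param popA,popB population names.
#' @param block jackknife block definition.
#' @return A `jackknife_estimate` of Fst.
#' @export
fst_pairwise <- function(freqs, popA, popB, block = "5cM") {
  stopifnot(inherits(freqs, "allele_freq_table"),
            popA %in% freqs$pops, popB %in% freqs$pops)
  p1 <- freqs$freq[, popA]; p2 <- freqs$freq[, popB]
  n1 <- freqs$count[, popA]; n2 <- freqs$count[, popB]
  keep <- is.finite(p1) & is.finite(p2) & n1 >= 2 & n2 >= 2
  p1 <- p1[keep]; p2 <- p2[keep]; n1 <- n1[keep]; n2 <- n2[keep]
  corr1 <- ifelse(is.finite(n1), p1 * (1 - p1) / (n1 - 1), 0)
  corr2 <- ifelse(is.finite(n2), p2 * (1 - p2) / (n2 - 1), 0)
  num <- (p1 - p2)^2 - corr1 - corr2
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (sum(den) == 0)
    stop("all SNPs monomorphic in both populations; Fst undefined")
  blocks <- assign_blocks(freqs$snp[keep, , drop = FALSE], block)
  jk <- jackknife_sums(cbind(num, den), blocks, function(s) s[1] / s[2])
  jk$block_type <- if (is.numeric(block)) paste0(block, "M") else block
  jk$n_snps <- length(num)
  jk
}
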