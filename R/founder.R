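# Allele-sharing matrix: one column per SNP, one row per individual pair;
# sharing s in {0, 1/2, 1} = fraction of allele comparisons identical in
# state between the two genotypes, NA when either call is missing.
sharing_matrix <- function(G, pairs_i, pairs_j) {
  gi <- G[pairs_i, , drop = FALSE]
  gj <- G[pairs_j, , drop = FALSE]
  1 - abs(gi - gj) / 2                   # dosage IBS: 0, 1/2 or 1
}

#' Allele-sharing autocorrelation curve
#'
#' LD statistic sensitive to founder events: for each pair of individuals,
#' allele sharing at a SNP is the fraction of alleles identical in state
#' between the two genotypes (0, 1/2 or 1). For each pair of SNPs at
#' genetic distance `d`, the Pearson correlation of the two sharing vectors
#' is computed across the within-`target_pop` individual pairs and averaged
#' per distance bin; the same quantity computed over (target, reference)
#' cross-population pairs is subtracted bin-wise to remove ancestral allele
#' sharing. A founder event of age `t` generations leaves an excess that
#' decays approximately as `exp(-2 t d)`.
#'
#' @param data a [genotype_dataset()].
#' @param target_pop population whose founder history is probed (>= 2
#'   samples).
#' @param reference_pop population supplying the cross-pair baseline (>= 1
#'   sample).
#' @param bin_width bin width in Morgans (default 0.002 = 0.2 cM).
#' @param d_max largest SNP separation considered, Morgans (default 0.2).
#' @return A `decay_curve` (columns `d`, `value`, `n_pairs`) of the
#'   subtracted autocorrelation.
#' @export
allele_sharing_autocorrelation <- function(data, target_pop, reference_pop,
                                           bin_width = 0.002, d_max = 0.2) {
  stopifnot(inherits(data, "genotype_dataset"))
  ti <- which(data$ind$pop == target_pop)
  ri <- which(data$ind$pop == reference_pop)
  if (length(ti) < 2L) stop("need >= 2 target samples")
  if (length(ri) < 1L) stop("need >= 1 reference sample")

  ord <- order(data$snp$chrom, data$snp$gpos)
  G <- t(data$geno[ord, , drop = FALSE]) * 1.0   # individuals x SNPs
  pos <- data$snp$gpos[ord]
  chrom <- as.integer(factor(data$snp$chrom[ord])) - 1L

  within <- utils::combn(ti, 2L)
  cross <- expand.grid(i = ti, j = ri)
  cross <- cross[cross$i != cross$j, , drop = FALSE]  # target == reference case

  curve_of <- function(pi, pj) {
    S <- sharing_matrix(G, pi, pj)
    mu <- colMeans(S, na.rm = TRUE)
    S <- sweep(S, 2L, mu)
    S[is.na(S)] <- 0
    ss <- sqrt(colSums(S^2))
    ok <- ss > 0
    S[, ok] <- sweep(S[, ok, drop = FALSE], 2L, ss[ok], "/")
    res <- cpp_sharing_autocorr(S, ok, pos, chrom, bin_width, d_max)
    list(value = ifelse(res$count > 0, res$sum / res$count, NA_real_),
         count = res$count)
  }
  cw <- curve_of(within[1, ], within[2, ])
  cx <- curve_of(cross$i, cross$j)
  n_bins <- length(cw$count)
  decay_curve(d = (seq_len(n_bins) - 0.5) * bin_width,
              value = cw$value - cx$value,
              n_pairs = pmin(cw$count, cx$count),
              bin_width = bin_width, d_max = d_max)
}

#' Date a founder event from an allele-sharing autocorrelation curve
#'
#' Least-squares fit of `A * exp(-rate_factor * t * D) + c` to the curve.
#' The default `rate_factor = 2` encodes that both lineages of an
#' individual pair accumulate recombination since the event, so the decay
#' rate per Morgan is twice the event age in generations.
#'
#' @param curve a `decay_curve` from [allele_sharing_autocorrelation()].
#' @param d_min,d_max fit window in Morgans (defaults 0.001 and the curve's
#'   extent).
#' @param rate_factor multiplier linking decay rate to event age (default
#'   2).
#' @return An object of class `founder_fit`: list with `t` (generations),
#'   `A`, `c`, `no_event` (`TRUE` when the fitted amplitude is not
#'   positive, i.e. no founder-event signal), `window`.
#' @export
fit_founder_date <- function(curve, d_min = 0.001, d_max = NULL,
                             rate_factor = 2) {
  stopifnot(inherits(curve, "decay_curve"))
  if (is.null(d_max)) d_max <- max(curve$d)
  sel <- curve$d >= d_min & curve$d <= d_max & curve$n_pairs > 0 &
    is.finite(curve$value)
  if (sum(sel) < 5L) stop("need >= 5 usable bins")
  d <- curve$d[sel]; v <- curve$value[sel]; wts <- curve$n_pairs[sel]
  wts <- wts / mean(wts)
  best <- fit_exp_nls(d, v, wts, starts = c(10, 40, 100, 200))
  if (is.null(best)) {
    # flat or noise-only curve: report the no-event verdict
    return(structure(list(t = NA_real_, A = NA_real_, c = mean(v),
                          no_event = TRUE, window = c(d_min, d_max)),
                     class = "founder_fit"))
  }
  cf <- stats::coef(best$fit)
  amp <- unname(cf[["A"]])
  no_event <- amp <= 0 ||
    amp < 2 * stats::sd(stats::residuals(best$fit))  # amplitude within noise
  structure(list(t = unname(cf[["n"]]) / rate_factor, A = amp,
                 c = unname(cf[["c"]]), no_event = no_event,
                 window = c(d_min, d_max)),
            class = "founder_fit")
}

#' @export
print.founder_fit <- function(x, ...) {
  if (isTRUE(x$no_event)) {
    cat("founder_fit: no founder-event signal detected\n")
  } else {
    cat(sprintf("founder_fit: t = %.2f generations (A = %.3g, c = %.3g)\n",
                x$t, x$A, x$c))
  }
  invisible(x)
}
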