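#' @useDynLib admixdate, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

decay_curve <- function(d, value, n_pairs, bin_width, d_min = NA,
                        d_max = NA) {
  structure(data.frame(d = d, value = value, n_pairs = n_pairs),
            bin_width = bin_width, d_min = d_min, d_max = d_max,
            class = c("decay_curve", "data.frame"))
}

# Align a weight vector to a dataset; returns weights with NA -> 0 and the
# usable-SNP flag.
align_weights <- function(data, weights) {
  stopifnot(inherits(weights, "weight_vector"))
  w <- weights$weight[match(data$snp$id, weights$snp_id)]
  usable <- !is.na(w)
  w[!usable] <- 0
  if (!any(w != 0)) stop("all weights are zero/NA after alignment")
  list(w = w, usable = usable)
}

# Shared preprocessing for the pair kernels: SNP sort order, centered
# matrix, missingness flags, chromosome codes.
prep_pair_inputs <- function(data, w) {
  ord <- order(data$snp$chrom, data$snp$gpos)
  G <- data$geno[ord, , drop = FALSE]
  pos <- data$snp$gpos[ord]
  chrom <- as.integer(factor(data$snp$chrom[ord])) - 1L
  w <- w[ord]
  Gt <- t(G) * 1.0                       # individuals x SNPs
  hasmiss <- colSums(is.na(Gt)) > 0L
  mu <- colMeans(Gt, na.rm = TRUE)
  Z <- sweep(Gt, 2L, mu)
  Z[is.na(Z)] <- 0
  v <- colSums(Z^2) / (nrow(Z) - 1L)
  list(Z = Z, G = Gt, hasmiss = hasmiss, w = w, sd = sqrt(v),
       pos = pos, chrom = chrom, n_chrom = max(chrom) + 1L)
}

#' Weighted-LD decay curve (covariance form)
#'
#' For every SNP pair (x, y) on the same chromosome separated by at most
#' `d_max` Morgans, accumulates `cov(x, y) * w(x) * w(y)` into the genetic-
#' distance bin containing the pair, where `cov` is the sample covariance of
#' dosages over individuals with both calls present. Each bin's value is
#' the accumulated sum divided by its pair count. Under pulse admixture the
#' expectation of this statistic decays as `exp(-n d)` with `n` the
#' generations since admixture.
#'
#' @param data a [genotype_dataset()] of the admixed samples (at least 2).
#' @param weights a [weight_vector()] aligned by SNP id.
#' @param bin_width bin width in Morgans (default 0.001 = 0.1 cM).
#' @param d_max largest separation considered, Morgans (default 0.3).
#' @return A `decay_curve` data frame with columns `d` (bin centre,
#'   Morgans), `value`, `n_pairs`.
#' @export
weighted_ld_curve <- function(data, weights, bin_width = 0.001,
                              d_max = 0.3) {
  stopifnot(inherits(data, "genotype_dataset"), nrow(data$ind) >= 2L)
  aw <- align_weights(data, weights)
  pp <- prep_pair_inputs(data, aw$w)
  res <- cpp_pair_curve(pp$Z, pp$G, pp$hasmiss, pp$w, pp$sd, pp$pos,
                        pp$chrom, bin_width, d_max, FALSE)
  n_bins <- length(res$count)
  decay_curve(d = (seq_len(n_bins) - 0.5) * bin_width,
              value = ifelse(res$count > 0, res$sum_cov / res$count, NA_real_),
              n_pairs = res$count, bin_width = bin_width, d_max = d_max)
}

#' Legacy correlation-form statistic and its normalization diagnostic
#'
#' Reconstruction of the original correlation-coefficient formulation of the
#' weighted-LD statistic: per distance bin it computes the correlation
#' across SNP pairs between the weight product `w(x) w(y)` and the genotype
#' correlation `corr(x, y)`, i.e.
#' `sum(w w' corr) / sqrt(sum((w w')^2) * sum(corr^2))`, and separately
#' returns the squared normalization term `mean(corr(x, y)^2)` per bin. In
#' a population without a post-admixture founder event the normalization
#' term is dominated by finite-sampling noise and is flat in `d`; a strong
#' founder event of age `g` makes it decay approximately as `exp(-2 g d)`,
#' which is the source of the downward bias of the correlation form that
#' the covariance form removes.
#'
#' @inheritParams weighted_ld_curve
#' @return list with `statistic` (correlation-form `decay_curve`) and
#'   `normalization` (squared-normalization-term `decay_curve`).
#' @export
legacy_correlation_curve <- function(data, weights, bin_width = 0.001,
                                     d_max = 0.3) {
  stopifnot(inherits(data, "genotype_dataset"), nrow(data$ind) >= 2L)
  aw <- align_weights(data, weights)
  pp <- prep_pair_inputs(data, aw$w)
  res <- cpp_pair_curve(pp$Z, pp$G, pp$hasmiss, pp$w, pp$sd, pp$pos,
                        pp$chrom, bin_width, d_max, TRUE)
  n_bins <- length(res$count)
  d <- (seq_len(n_bins) - 0.5) * bin_width
  denom <- sqrt(res$sum_ww * res$sum_zz)
  stat <- ifelse(res$count > 0 & denom > 0, res$sum_wz / denom, NA_real_)
  norm2 <- ifelse(res$count > 0, res$sum_zz / res$count, NA_real_)
  list(statistic = decay_curve(d, stat, res$count, bin_width, d_max = d_max),
       normalization = decay_curve(d, norm2, res$count, bin_width,
                                   d_max = d_max))
}

# Count-weighted nonlinear least squares of A * exp(-n * d) + c with
# multi-start over n; returns NULL if no start converges.
fit_exp_nls <- function(d, v, wts, starts = c(5, 20, 50, 150, 400),
                        affine = TRUE) {
  best <- NULL
  for (n0 in starts) {
    a0 <- unname(stats::coef(stats::lm(v ~ exp(-n0 * d), weights = wts))[2])
    if (!is.finite(a0) || a0 == 0) a0 <- max(abs(v))
    c0 <- if (affine) min(v) else 0
    fit <- tryCatch(
      if (affine)
        minpack.lm::nlsLM(v ~ A * exp(-n * d) + c,
                          start = list(A = a0, n = n0, c = c0),
                          weights = wts,
                          control = minpack.lm::nls.lm.control(
                            maxiter = 200, ftol = 1e-12, ptol = 1e-12))
      else
        minpack.lm::nlsLM(v ~ A * exp(-n * d),
                          start = list(A = a0, n = n0),
                          weights = wts,
                          control = minpack.lm::nls.lm.control(
                            maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    rss <- sum(wts * stats::residuals(fit)^2)
    if (stats::coef(fit)[["n"]] <= 0) next
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  best
}

#' Fit a single exponential with affine term to a decay curve
#'
#' Count-weighted nonlinear least squares of `A * exp(-n d) + c` over the
#' bins in `[d_min, d_max]`, with multi-start initialization over
#' `n = 5, 20, 50, 150, 400` generations. The default lower cutoff of
#' 0.5 cM excludes the range where background LD confounds admixture LD in
#' real data.
#'
#' @param curve a `decay_curve` from [weighted_ld_curve()].
#' @param d_min lower fit bound in Morgans (default 0.005 = 0.5 cM).
#' @param d_max upper fit bound in Morgans (default: the curve's extent).
#' @return An object of class `exp_fit`: list with `n` (generations), `A`,
#'   `c`, `window`, `resid_norm`, `n_bins`, and `no_signal` (`TRUE` when
#'   the fitted amplitude is negative).
#' @export
fit_single_exponential <- function(curve, d_min = 0.005, d_max = NULL) {
  stopifnot(inherits(curve, "decay_curve"))
  if (is.null(d_max)) d_max <- max(curve$d)
  sel <- curve$d >= d_min & curve$d <= d_max & curve$n_pairs > 0 &
    is.finite(curve$value)
  if (sum(sel) < 5L) stop("need >= 5 usable bins in the fit window")
  d <- curve$d[sel]; v <- curve$value[sel]; wts <- curve$n_pairs[sel]
  wts <- wts / mean(wts)
  best <- fit_exp_nls(d, v, wts)
  if (is.null(best)) stop("exponential fit did not converge from any start")
  cf <- stats::coef(best$fit)
  structure(list(n = unname(cf[["n"]]), A = unname(cf[["A"]]),
                 c = unname(cf[["c"]]), window = c(d_min, d_max),
                 resid_norm = sqrt(best$rss), n_bins = sum(sel),
                 no_signal = unname(cf[["A"]]) < 0),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("exp_fit: n = %.2f generations (A = %.3g, c = %.3g)%s\n",
              x$n, x$A, x$c,
              if (isTRUE(x$no_signal)) "  [no-signal: A < 0]" else ""))
  invisible(x)
}

#' Fit a two-pulse (sum of two exponentials) model to a decay curve
#'
#' Count-weighted least squares of `A1 exp(-n1 d) + A2 exp(-n2 d) + c` with
#' a multi-start grid over ordered rate pairs; the solution is reported with
#' `n1 > n2`. When the two rates are nearly indistinguishable
#' (`n1 / n2 < ratio_min`) the model is degenerate and the function falls
#' back to the single-pulse fit with a warning.
#'
#' @inheritParams fit_single_exponential
#' @param ratio_min identifiability guard on `n1 / n2` (default 1.5).
#' @return An object of class `two_pulse_fit`: list with `n1 > n2`, `A1`,
#'   `A2`, `c`, `converged`, `degenerate` and (when degenerate) `single`,
#'   the fallback `exp_fit`.
#' @export
fit_two_pulse <- function(curve, d_min = 0.005, d_max = NULL,
                          ratio_min = 1.5) {
  stopifnot(inherits(curve, "decay_curve"))
  if (is.null(d_max)) d_max <- max(curve$d)
  sel <- curve$d >= d_min & curve$d <= d_max & curve$n_pairs > 0 &
    is.finite(curve$value)
  if (sum(sel) < 8L) stop("need >= 8 usable bins in the fit window")
  d <- curve$d[sel]; v <- curve$value[sel]; wts <- curve$n_pairs[sel]
  wts <- wts / mean(wts)

  grid <- expand.grid(n1 = c(20, 40, 80, 150, 300), n2 = c(2, 5, 10, 30))
  grid <- grid[grid$n1 > grid$n2, ]
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    n10 <- grid$n1[g]; n20 <- grid$n2[g]
    lmfit <- stats::coef(stats::lm(v ~ exp(-n10 * d) + exp(-n20 * d),
                                   weights = wts))
    a10 <- unname(lmfit[2]); a20 <- unname(lmfit[3]); c0 <- unname(lmfit[1])
    if (!all(is.finite(c(a10, a20, c0)))) {
      a10 <- a20 <- max(abs(v)); c0 <- 0
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ A1 * exp(-n1 * d) + A2 * exp(-n2 * d) + c,
                        start = list(A1 = a10, n1 = n10, A2 = a20,
                                     n2 = n20, c = c0),
                        weights = wts,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 300, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    if (cf[["n1"]] <= 0 || cf[["n2"]] <= 0) next
    rss <- sum(wts * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(cf = cf, rss = rss)
  }
  if (is.null(best)) stop("two-pulse fit did not converge from any start")
  cf <- best$cf
  if (cf[["n1"]] < cf[["n2"]]) {    # enforce n1 > n2 ordering
    cf[c("n1", "n2")] <- cf[c("n2", "n1")]
    cf[c("A1", "A2")] <- cf[c("A2", "A1")]
  }
  if (cf[["n1"]] / cf[["n2"]] < ratio_min) {
    warning("two-pulse rates nearly equal (ratio < ", ratio_min,
            "); falling back to single-pulse fit")
    single <- fit_single_exponential(curve, d_min, d_max)
    return(structure(list(n1 = NA_real_, n2 = NA_real_, A1 = NA_real_,
                          A2 = NA_real_, c = NA_real_, converged = TRUE,
                          degenerate = TRUE, single = single),
                     class = "two_pulse_fit"))
  }
  structure(list(n1 = unname(cf[["n1"]]), n2 = unname(cf[["n2"]]),
                 A1 = unname(cf[["A1"]]), A2 = unname(cf[["A2"]]),
                 c = unname(cf[["c"]]), converged = TRUE,
                 degenerate = FALSE, resid_norm = sqrt(best$rss)),
            class = "two_pulse_fit")
}

#' @export
print.two_pulse_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("two_pulse_fit: degenerate (rates indistinguishable); single-pulse",
        sprintf("n = %.2f\n", x$single$n))
  } else {
    cat(sprintf("two_pulse_fit: n1 = %.2f, n2 = %.2f generations\n",
                x$n1, x$n2))
  }
  invisible(x)
}

#' Admixture date with delete-one-chromosome jackknife standard error
#'
#' Computes the weighted-LD curve once with per-chromosome bin
#' contributions, then refits the single-exponential model with each
#' chromosome deleted in turn. The standard error is the weighted jackknife
#' over chromosomes with weights proportional to chromosome SNP counts.
#'
#' @inheritParams weighted_ld_curve
#' @param d_min,fit_d_max fit window bounds in Morgans.
#' @return A `jackknife_estimate` (see [block_jackknife()]) whose `estimate`
#'   is the full-data fitted date in generations; the full `exp_fit` is
#'   attached as `$fit`.
#' @export
jackknife_date <- function(data, weights, bin_width = 0.001, d_max = 0.3,
                           d_min = 0.005, fit_d_max = NULL) {
  stopifnot(inherits(data, "genotype_dataset"))
  n_chrom <- length(unique(data$snp$chrom))
  if (n_chrom < 2L) stop("delete-one-chromosome jackknife needs >= 2 chromosomes")
  aw <- align_weights(data, weights)
  pp <- prep_pair_inputs(data, aw$w)
  res <- cpp_pair_curve_bychrom(pp$Z, pp$G, pp$hasmiss, pp$w, pp$pos,
                                pp$chrom, pp$n_chrom, bin_width, d_max)
  n_bins <- nrow(res$sum_cov)
  d <- (seq_len(n_bins) - 0.5) * bin_width
  tot_sum <- rowSums(res$sum_cov)
  tot_cnt <- rowSums(res$count)
  mk_curve <- function(s, cnt)
    decay_curve(d, ifelse(cnt > 0, s / cnt, NA_real_), cnt, bin_width,
                d_max = d_max)
  full <- fit_single_exponential(mk_curve(tot_sum, tot_cnt), d_min,
                                 fit_d_max)
  snp_per_chrom <- tabulate(pp$chrom + 1L, pp$n_chrom)
  loo <- rep(NA_real_, pp$n_chrom)
  for (k in seq_len(pp$n_chrom)) {
    cv <- mk_curve(tot_sum - res$sum_cov[, k], tot_cnt - res$count[, k])
    fit_k <- tryCatch(fit_single_exponential(cv, d_min, fit_d_max),
                      error = function(e) NULL)
    if (is.null(fit_k)) {
      warning("delete-one fit failed for chromosome block ", k,
              "; excluded from jackknife")
      next
    }
    loo[k] <- fit_k$n
  }
  ok <- is.finite(loo)
  jk <- jackknife_from_loo(full$n, loo[ok], snp_per_chrom[ok])
  jk$block_type <- "chromosome"
  jk$fit <- full
  jk
}

#' Convert generations to calendar years
#'
#' @param n generations (positive; vectors allowed, e.g. `c(27, 31)` for an
#'   interval).
#' @param gen_time years per generation (default 29).
#' @return `n * gen_time` years.
#' @export
generations_to_years <- function(n, gen_time = 29) {
  if (any(n <= 0)) stop("generations must be positive")
  n * gen_time
}
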