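#' Run the end-to-end demonstration pipeline on a synthetic scenario
#'
#' Composes every stage of the package on one simulated admixed population
#' with known truth: simulate genotypes, build admixture-LD weights (PCA
#' loadings of the reference panel by default), estimate the admixture date
#' with chromosome-drop jackknife, estimate the ancestry proportion by
#' ratio of f4 statistics, date the founder event (if any) from
#' allele-sharing autocorrelation, summarize runs of homozygosity, and
#' compute the IBD sharing matrix. Every stage is seeded from the scenario
#' seed, so a fixed config yields an identical report.
#'
#' @param config a [scenario_config()].
#' @param weight_mode `"pca"` (default) or `"freq-diff"`.
#' @param bin_width,d_max,d_min weighted-LD curve and fit parameters
#'   (Morgans).
#' @param two_pulse also fit the two-pulse model.
#' @param ibd logical: run the IBD stages (skipped by default at large SNP
#'   counts where seed hashing dominates runtime).
#' @param verbose log stage timings to stderr.
#' @return list of class `demo_report` with per-stage results and the
#'   scenario truth.
#' @export
run_demo_pipeline <- function(config, weight_mode = c("pca", "freq-diff"),
                              bin_width = 0.001, d_max = 0.3,
                              d_min = 0.005, two_pulse = FALSE,
                              ibd = FALSE, verbose = TRUE) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(inherits(config, "scenario_config"))
  say <- function(...) if (verbose) message("[", format(Sys.time(), "%H:%M:%S"),
                                            "] ", ...)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say(name, " done in ", sprintf("%.1fs", as.numeric(Sys.time() - t0,
                                                       units = "secs")))
    out
  }

  sim <- stage("simulate", simulate_scenario(config))
  adm <- subset_dataset(sim$data, samples = sim$data$ind$pop == "ADMIXED")
  ref <- subset_dataset(sim$data, samples = sim$data$ind$pop %in% c("A", "B"))

  weights <- stage("weights", {
    if (weight_mode == "pca") {
      pca_loadings(ref, target_snp_ids = adm$snp$id)
    } else {
      freq_difference_weights(allele_frequencies(ref, c("A", "B")), "A", "B")
    }
  })

  date_jk <- stage("admixture-date",
                   jackknife_date(adm, weights, bin_width = bin_width,
                                  d_max = d_max, d_min = d_min))
  tp <- if (two_pulse)
    stage("two-pulse", {
      cv <- weighted_ld_curve(adm, weights, bin_width, d_max)
      fit_two_pulse(cv, d_min)
    })

  anc <- stage("ancestry-proportion", {
    fr <- allele_frequencies(sim$data)
    mean_freq_X <- rowMeans(sim$data$geno[, sim$data$ind$pop == "ADMIXED",
                                          drop = FALSE], na.rm = TRUE) / 2
    true_alpha <- mean(sim$truth == 1L)
    est <- tryCatch(
      f4_ratio_from_pools(fr, adm),
      error = function(e) NULL)
    list(estimate = est, truth = true_alpha, mean_freq = mean(mean_freq_X))
  })

  founder <- stage("founder-date", {
    cv <- allele_sharing_autocorrelation(sim$data, "ADMIXED", "A")
    fit_founder_date(cv)
  })

  roh <- stage("roh", {
    segs <- detect_roh(adm)
    autozygosity_summary(segs, adm$ind$id)
  })

  ibd_out <- if (ibd) stage("ibd", {
    segs <- detect_ibd_segments(sim$haps)
    list(segments = segs,
         within = sharing_distance(segs, "ADMIXED", "ADMIXED",
                                   sim$haps$ind))
  })

  truth <- list(
    pulse_times = config$pulses$time,
    alpha = mean(sim$truth == 1L),
    founder_time = if (!is.null(config$founder_event))
      config$founder_event$time)
  structure(list(config = config, truth = truth, weights_mode = weight_mode,
                 admixture_date = date_jk, two_pulse = tp,
                 ancestry = anc, founder = founder, roh = roh,
                 ibd = ibd_out),
            class = "demo_report")
}

# Ancestry proportion of the admixed samples from the two pool frequency
# estimates (used by the demo report where no five-population panel
# exists): method-of-moments solution of freq_X = p freq_A + (1-p) freq_B.
# The pool frequencies are sample estimates, so the naive ratio
# sum((fx-pb)(pa-pb)) / sum((pa-pb)^2) is biased by their sampling
# variance; both sums are debiased with the usual p(1-p)/(n-1) terms.
f4_ratio_from_pools <- function(fr, adm) {
  fx <- rowMeans(adm$geno, na.rm = TRUE) / 2
  pa <- fr$freq[, "A"]; pb <- fr$freq[, "B"]
  va <- pa * (1 - pa) / pmax(fr$count[, "A"] - 1, 1)
  vb <- pb * (1 - pb) / pmax(fr$count[, "B"] - 1, 1)
  va[!is.finite(va)] <- 0                # population-level (Inf-count) pools
  vb[!is.finite(vb)] <- 0
  keep <- is.finite(fx) & is.finite(pa) & is.finite(pb)
  num <- ((fx - pb) * (pa - pb) - vb)[keep]
  den <- ((pa - pb)^2 - va - vb)[keep]
  blocks <- assign_blocks(adm$snp[keep, , drop = FALSE], "5cM")
  jk <- jackknife_sums(cbind(num, den), blocks, function(s) s[1] / s[2])
  jk$block_type <- "5cM"
  jk
}

#' @export
print.demo_report <- function(x, ...) {
  cat("demo_report (synthetic admixed population)\n")
  cat(sprintf("  true pulse time(s): %s generations; true alpha: %.3f\n",
              paste(x$truth$pulse_times, collapse = ", "), x$truth$alpha))
  cat(sprintf("  admixture date: %.1f +/- %.1f generations (%s weights)\n",
              x$admixture_date$estimate, x$admixture_date$se,
              x$weights_mode))
  if (!is.null(x$two_pulse) && !isTRUE(x$two_pulse$degenerate))
    cat(sprintf("  two-pulse dates: %.1f and %.1f generations\n",
                x$two_pulse$n1, x$two_pulse$n2))
  if (!is.null(x$ancestry$estimate))
    cat(sprintf("  ancestry proportion: %.3f +/- %.3f (truth %.3f)\n",
                x$ancestry$estimate$estimate, x$ancestry$estimate$se,
                x$ancestry$truth))
  if (isTRUE(x$founder$no_event)) {
    cat("  founder event: none detected",
        if (!is.null(x$truth$founder_time))
          sprintf("(truth: %g generations)", x$truth$founder_time), "\n")
  } else {
    cat(sprintf("  founder event: %.1f generations%s\n", x$founder$t,
                if (!is.null(x$truth$founder_time))
                  sprintf(" (truth %g)", x$truth$founder_time) else ""))
  }
  cat(sprintf("  ROH: mean %.2f segments, %.2f Mb per sample\n",
              mean(x$roh$n_segments), mean(x$roh$total_mb)))
  invisible(x)
}
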