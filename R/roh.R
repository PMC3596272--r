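#' Detect runs of homozygosity
#'
#' Per individual and chromosome, scans for maximal stretches of SNPs that
#' span at least `min_mb` megabases, contain at least `min_snps` SNPs, and
#' include at most `max_het` heterozygous and `max_miss` missing calls.
#' The scan is greedy and deterministic: moving left to right, the longest
#' feasible run starting at or after the current position that meets all
#' four thresholds is emitted and the scan resumes past its end, so
#' reported segments never overlap and each individually satisfies every
#' threshold.
#'
#' @param data a [genotype_dataset()] with physical positions.
#' @param min_mb minimum segment length in megabases (default 1).
#' @param min_snps minimum SNP count per segment (default 100).
#' @param max_het maximum heterozygous calls tolerated per segment
#'   (default 1).
#' @param max_miss maximum missing calls tolerated per segment (default 5).
#' @return data frame with one row per segment: `sample`, `chrom`,
#'   `start_bp`, `end_bp`, `length_mb`, `n_snps`, `n_het`, `n_miss`.
#' @export
detect_roh <- function(data, min_mb = 1, min_snps = 100L, max_het = 1L,
                       max_miss = 5L) {
  stopifnot(inherits(data, "genotype_dataset"))
  out <- list()
  for (ch in unique(data$snp$chrom)) {
    sel <- which(data$snp$chrom == ch)
    sel <- sel[order(data$snp$ppos[sel])]
    pos <- data$snp$ppos[sel]
    for (s in seq_len(nrow(data$ind))) {
      g <- data$geno[sel, s]
      het <- !is.na(g) & g == 1L
      mis <- is.na(g)
      ch_het <- cumsum(het)
      ch_mis <- cumsum(mis)
      p <- length(g)
      i <- 1L
      j_prev <- 0L
      while (i <= p) {
        # extend j as far as the het/missing budgets allow from start i
        j <- max(i, j_prev)
        while (j < p &&
               ch_het[j + 1L] - ch_het[i] + het[i] <= max_het &&
               ch_mis[j + 1L] - ch_mis[i] + mis[i] <= max_miss)
          j <- j + 1L
        j_prev <- j
        n_snp <- j - i + 1L
        len_mb <- (pos[j] - pos[i]) / 1e6
        if (n_snp >= min_snps && len_mb >= min_mb) {
          out[[length(out) + 1L]] <- data.frame(
            sample = data$ind$id[s], chrom = ch,
            start_bp = pos[i], end_bp = pos[j], length_mb = len_mb,
            n_snps = n_snp,
            n_het = ch_het[j] - ch_het[i] + het[i],
            n_miss = ch_mis[j] - ch_mis[i] + mis[i])
          i <- j + 1L
        } else {
          i <- i + 1L
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(sample = character(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      length_mb = numeric(), n_snps = integer(),
                      n_het = integer(), n_miss = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-sample autozygosity summary
#'
#' @param segments ROH table from [detect_roh()].
#' @param sample_ids optional full sample id vector so that samples with no
#'   segment appear with zeros.
#' @return data frame with `sample`, `n_segments`, `total_mb`.
#' @export
autozygosity_summary <- function(segments, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- unique(segments$sample)
  n_seg <- vapply(sample_ids,
                  function(s) sum(segments$sample == s), integer(1))
  tot <- vapply(sample_ids,
                function(s) sum(segments$length_mb[segments$sample == s]),
                numeric(1))
  data.frame(sample = sample_ids, n_segments = n_seg, total_mb = tot,
             row.names = NULL)
}
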