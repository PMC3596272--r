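#' Detect IBD segments from phased haplotypes
#'
#' Simplified seed-and-extend matcher: the SNP index is cut into
#' consecutive seed windows of `seed_snps` sites; haplotypes identical
#' across a window are grouped (hash match), every matching haplotype pair
#' is extended in both directions with zero mismatches, matches are
#' collapsed from haplotype pairs to individual pairs (overlapping or
#' adjacent stretches merged), and segments shorter than `min_cm` are
#' discarded. Self-comparisons (the two haplotypes of one individual) are
#' excluded.
#'
#' @param haps a [haplotype_dataset()].
#' @param seed_snps seed window length in SNPs (default 75).
#' @param min_cm minimum reported segment length in centimorgans
#'   (default 3).
#' @return data frame with one row per segment: `sample_i`, `sample_j`
#'   (ids, `i < j` by sample order), `chrom`, `start_cm`, `end_cm`,
#'   `length_cm`.
#' @export
detect_ibd_segments <- function(haps, seed_snps = 75L, min_cm = 3) {
  stopifnot(inherits(haps, "haplotype_dataset"))
  H <- haps$haps
  n_hap <- ncol(H)
  samp_of <- rep(seq_len(nrow(haps$ind)), each = 2L)
  segs <- list()

  for (ch in unique(haps$snp$chrom)) {
    sel <- which(haps$snp$chrom == ch)
    sel <- sel[order(haps$snp$gpos[sel])]
    pos_cm <- haps$snp$gpos[sel] * 100
    Hc <- H[sel, , drop = FALSE]
    p <- length(sel)
    if (p < seed_snps) next
    starts <- seq(1L, p - seed_snps + 1L, by = seed_snps)
    # per haplotype pair, collect matched SNP intervals
    found <- new.env(hash = TRUE)
    for (st in starts) {
      win <- st:(st + seed_snps - 1L)
      key <- apply(Hc[win, , drop = FALSE], 2L, paste, collapse = "")
      groups <- split(seq_len(n_hap), key)
      for (grp in groups) {
        if (length(grp) < 2L) next
        for (a in seq_len(length(grp) - 1L)) {
          for (b in (a + 1L):length(grp)) {
            h1 <- grp[a]; h2 <- grp[b]
            if (samp_of[h1] == samp_of[h2]) next
            pkey <- paste0(h1, "_", h2)
            prev <- found[[pkey]]
            if (!is.null(prev) && any(st >= prev$lo & st <= prev$hi)) next
            dif <- Hc[, h1] != Hc[, h2]
            lo <- st
            while (lo > 1L && !dif[lo - 1L]) lo <- lo - 1L
            hi <- st + seed_snps - 1L
            while (hi < p && !dif[hi + 1L]) hi <- hi + 1L
            iv <- data.frame(lo = lo, hi = hi)
            found[[pkey]] <- if (is.null(prev)) iv else rbind(prev, iv)
          }
        }
      }
    }
    # collapse haplotype-pair intervals to individual pairs, merge overlaps
    keys <- ls(found)
    if (!length(keys)) next
    iv_all <- do.call(rbind, lapply(keys, function(k) {
      hp <- as.integer(strsplit(k, "_", fixed = TRUE)[[1]])
      cbind(found[[k]], i = samp_of[hp[1]], j = samp_of[hp[2]])
    }))
    ij <- cbind(pmin(iv_all$i, iv_all$j), pmax(iv_all$i, iv_all$j))
    for (pk in unique(paste(ij[, 1], ij[, 2]))) {
      rows <- which(paste(ij[, 1], ij[, 2]) == pk)
      iv <- iv_all[rows, c("lo", "hi"), drop = FALSE]
      iv <- iv[order(iv$lo), , drop = FALSE]
      merged <- list(iv[1, ])
      if (nrow(iv) > 1L) for (r in 2:nrow(iv)) {
        last <- merged[[length(merged)]]
        if (iv$lo[r] <= last$hi + 1L) {
          last$hi <- max(last$hi, iv$hi[r])
          merged[[length(merged)]] <- last
        } else merged[[length(merged) + 1L]] <- iv[r, ]
      }
      si <- ij[rows[1], 1]; sj <- ij[rows[1], 2]
      for (m in merged) {
        len <- pos_cm[m$hi] - pos_cm[m$lo]
        if (len >= min_cm)
          segs[[length(segs) + 1L]] <- data.frame(
            sample_i = haps$ind$id[si], sample_j = haps$ind$id[sj],
            chrom = ch, start_cm = pos_cm[m$lo], end_cm = pos_cm[m$hi],
            length_cm = len)
      }
    }
  }
  if (!length(segs))
    return(data.frame(sample_i = character(), sample_j = character(),
                      chrom = character(), start_cm = numeric(),
                      end_cm = numeric(), length_cm = numeric()))
  res <- do.call(rbind, segs)
  rownames(res) <- NULL
  res
}

#' Average pairwise IBD sharing between two populations
#'
#' Sum of IBD segment lengths over all (i in I, j in J) individual pairs,
#' divided by the number of pairs: `n * m` across populations, or
#' `n (n - 1) / 2` within a population. Larger values mean more recent
#' shared ancestry.
#'
#' @param segments IBD table from [detect_ibd_segments()] (or imported from
#'   an external matcher; columns `sample_i`, `sample_j`, `length_cm`).
#' @param popI,popJ population labels.
#' @param labels data frame with columns `id`, `pop` mapping samples to
#'   populations.
#' @return list with `sharing_cm` (average pairwise sharing in cM),
#'   `n_pairs`, `total_cm`.
#' @export
sharing_distance <- function(segments, popI, popJ, labels) {
  ids_i <- labels$id[labels$pop == popI]
  ids_j <- labels$id[labels$pop == popJ]
  if (!length(ids_i) || !length(ids_j))
    stop("empty population: ", if (!length(ids_i)) popI else popJ)
  in_i <- segments$sample_i %in% ids_i & segments$sample_j %in% ids_j
  in_j <- segments$sample_i %in% ids_j & segments$sample_j %in% ids_i
  tot <- sum(segments$length_cm[in_i | in_j])
  n_pairs <- if (popI == popJ) {
    length(ids_i) * (length(ids_i) - 1) / 2
  } else {
    length(ids_i) * length(ids_j)
  }
  if (n_pairs == 0) stop("no individual pairs for ", popI, "-", popJ)
  list(sharing_cm = tot / n_pairs, n_pairs = n_pairs, total_cm = tot)
}

#' Full population-pair sharing matrix
#'
#' @inheritParams sharing_distance
#' @param pops populations to include (default: all in `labels`).
#' @return symmetric matrix of average pairwise sharing (cM).
#' @export
sharing_matrix_table <- function(segments, labels, pops = NULL) {
  if (is.null(pops)) pops <- unique(labels$pop)
  M <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (a in seq_along(pops)) for (b in a:length(pops)) {
    v <- sharing_distance(segments, pops[a], pops[b], labels)$sharing_cm
    M[a, b] <- M[b, a] <- v
  }
  M
}

#' Bootstrap the sharing statistic over capped group sizes
#'
#' Controls for unequal group sizes: in each replicate, up to `cap`
#' individuals are drawn without replacement from every group (groups at or
#' under the cap enter whole) and the average pairwise sharing between
#' `target_pop` and each other group is recomputed. Groups never resampled
#' (size <= cap, and the target itself) have zero bootstrap variance; their
#' SE is reported as `NA`.
#'
#' @inheritParams sharing_distance
#' @param target_pop the focal population.
#' @param cap maximum individuals per group per replicate (default 30).
#' @param reps number of replicates (default 100).
#' @param seed integer seed.
#' @return data frame with `pop`, `mean_cm`, `se_cm` (`NA` where no
#'   resampling occurred), `resampled`.
#' @export
bootstrap_sharing <- function(segments, labels, target_pop, cap = 30L,
                              reps = 100L, seed = 1L) {
  stopifnot(reps >= 2L)
  set.seed(seed)
  pops <- setdiff(unique(labels$pop), target_pop)
  res <- matrix(NA_real_, reps, length(pops), dimnames = list(NULL, pops))
  for (r in seq_len(reps)) {
    lab_r <- do.call(rbind, lapply(unique(labels$pop), function(p) {
      ids <- labels$id[labels$pop == p]
      if (p != target_pop && length(ids) > cap)
        ids <- sample(ids, cap)
      data.frame(id = ids, pop = p)
    }))
    for (p in pops)
      res[r, p] <- sharing_distance(segments, target_pop, p,
                                    lab_r)$sharing_cm
  }
  sizes <- table(labels$pop)
  resampled <- as.integer(sizes[pops]) > cap
  data.frame(pop = pops,
             mean_cm = colMeans(res),
             se_cm = ifelse(resampled, apply(res, 2L, stats::sd), NA_real_),
             resampled = resampled, row.names = NULL)
}

#' Ancestry-residualized IBD sharing
#'
#' Regresses per-individual-pair sharing on the pair's mean ancestry
#' proportion (alternatives: product or minimum, via `covariate`) and
#' re-aggregates the residuals by population pair, removing the component
#' of sharing explained by shared ancestry proportion alone.
#'
#' @param segments IBD table (columns `sample_i`, `sample_j`, `length_cm`).
#' @param labels data frame `id`, `pop`.
#' @param ancestry named numeric vector of per-individual ancestry
#'   proportions.
#' @param target_pop focal population; corrected sharing is reported
#'   between it and every other population.
#' @param covariate `"mean"` (default), `"product"` or `"min"` combination
#'   of the pair's two ancestry values.
#' @return data frame with `pop`, `sharing_cm` (uncorrected),
#'   `corrected_cm` (mean residual, recentred at the grand mean so units
#'   stay cM), plus the fitted `slope`.
#' @export
ancestry_corrected_sharing <- function(segments, labels, ancestry,
                                       target_pop,
                                       covariate = c("mean", "product",
                                                     "min")) {
  covariate <- match.arg(covariate)
  pops <- setdiff(unique(labels$pop), target_pop)
  ids_t <- labels$id[labels$pop == target_pop]
  rows <- list()
  for (p in pops) {
    ids_p <- labels$id[labels$pop == p]
    for (i in ids_t) for (j in ids_p) {
      in_ij <- (segments$sample_i == i & segments$sample_j == j) |
               (segments$sample_i == j & segments$sample_j == i)
      anc <- switch(covariate,
                    mean = (ancestry[[i]] + ancestry[[j]]) / 2,
                    product = ancestry[[i]] * ancestry[[j]],
                    min = min(ancestry[[i]], ancestry[[j]]))
      rows[[length(rows) + 1L]] <- data.frame(
        pop = p, share = sum(segments$length_cm[in_ij]), anc = anc)
    }
  }
  df <- do.call(rbind, rows)
  if (stats::sd(df$anc) == 0)
    stop("ancestry covariate is constant across pairs; cannot regress")
  fit <- stats::lm(share ~ anc, data = df)
  df$resid <- stats::residuals(fit) + mean(df$share)
  agg_u <- tapply(df$share, df$pop, mean)
  agg_c <- tapply(df$resid, df$pop, mean)
  data.frame(pop = names(agg_u), sharing_cm = as.numeric(agg_u),
             corrected_cm = as.numeric(agg_c[names(agg_u)]),
             slope = unname(stats::coef(fit)[2]), row.names = NULL)
}
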