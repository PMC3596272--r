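#' Scenario configuration for the synthetic admixed-genome generator
#'
#' Bundles everything needed to simulate an admixed population with known
#' truth: two Balding-Nichols ancestral pools at differentiation `F`, one or
#' two admixture pulses, an optional post-admixture founder event, a uniform
#' multi-chromosome genetic map, and sample sizes.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_m map length of each chromosome in Morgans.
#' @param n_snps total SNP count, spread evenly over chromosomes.
#' @param F Balding-Nichols differentiation between the two ancestral pools
#'   (default 0.1, approximating continental-scale divergence).
#' @param pulses data frame with columns `time` (generations before present,
#'   strictly decreasing) and `prop` in `(0, 1]` (`1` = degenerate
#'   single-ancestry case, useful for nulls). For the first (oldest) pulse `prop` is
#'   the fraction of ancestry drawn from pool A at founding of the admixed
#'   population; for each later pulse it is the fraction of lineages replaced
#'   by new pool-A lineages at that time.
#' @param founder_event `NULL`, or `list(time =, n_founders =, n_after =)`
#'   describing a founder event `time` generations ago from which
#'   `n_founders` individuals repopulate at constant size `n_after`
#'   (default 1000 diploids, see [apply_founder_event()]).
#' @param n_admixed number of admixed diploid samples to output.
#' @param n_ref number of diploid reference samples drawn from each
#'   ancestral pool.
#' @param missing_rate genotype dropout rate applied when collapsing to
#'   dosages.
#' @param seed integer seed controlling every random draw.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_chromosomes = 20L, chrom_length_m = 1,
                            n_snps = 2e5, F = 0.1,
                            pulses = data.frame(time = 30, prop = 0.8),
                            founder_event = NULL,
                            n_admixed = 27L, n_ref = 25L,
                            missing_rate = 0, seed = 1L) {
  pulses <- as.data.frame(pulses)
  stopifnot(all(c("time", "prop") %in% names(pulses)),
            nrow(pulses) >= 1L,
            all(pulses$prop > 0), all(pulses$prop <= 1),
            all(pulses$time >= 1),
            !is.unsorted(rev(pulses$time), strictly = TRUE),
            F > 0, F < 1,
            n_chromosomes >= 1L, chrom_length_m > 0, n_snps >= 2L,
            n_admixed >= 1L, n_ref >= 1L,
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(founder_event)) {
    stopifnot(founder_event$time >= 1, founder_event$n_founders >= 2L)
    if (is.null(founder_event$n_after))
      founder_event$n_after <- 1000L
  }
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_m = chrom_length_m, n_snps = as.integer(n_snps),
                 F = F, pulses = pulses, founder_event = founder_event,
                 n_admixed = as.integer(n_admixed), n_ref = as.integer(n_ref),
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "scenario_config")
}

# Uniform SNP map: n_snps spread evenly over the chromosomes, random
# positions sorted within each chromosome.
make_uniform_map <- function(n_snps, n_chromosomes, chrom_length_m) {
  per <- diff(round(seq(0, n_snps, length.out = n_chromosomes + 1L)))
  chrom <- rep(paste0("chr", seq_len(n_chromosomes)), per)
  gpos <- unlist(lapply(per, function(m) sort(stats::runif(m, 0, chrom_length_m))),
                 use.names = FALSE)
  data.frame(id = paste0("snp", seq_len(n_snps)), chrom = chrom,
             gpos = gpos, ppos = round(gpos * 1e8) + 1,
             ref = "A", alt = "C")
}

#' Simulate ancestral allele frequencies under the Balding-Nichols model
#'
#' A base frequency `p0` is drawn uniformly on `[0.05, 0.95]` per SNP; pool A
#' and pool B frequencies are then drawn independently from
#' `Beta(p0 (1 - F) / F, (1 - p0)(1 - F) / F)`, so each pool has mean `p0`
#' and variance `F p0 (1 - p0)`.
#'
#' @param n_snps number of SNPs.
#' @param F differentiation parameter in (0, 1).
#' @param seed integer seed.
#' @param snp optional SNP map to attach (defaults to a single 1-Morgan
#'   chromosome).
#' @return An `allele_freq_table` with populations `"A"`, `"B"` and the base
#'   frequency `"anc"`. Counts are set to `Inf` (population frequencies, not
#'   sample estimates).
#' @export
simulate_ancestral_freqs <- function(n_snps, F = 0.1, seed = 1L, snp = NULL) {
  if (!(F > 0 && F < 1)) stop("F must be in (0, 1)")
  set.seed(seed)
  p0 <- stats::runif(n_snps, 0.05, 0.95)
  a <- p0 * (1 - F) / F
  b <- (1 - p0) * (1 - F) / F
  pA <- stats::rbeta(n_snps, a, b)
  pB <- stats::rbeta(n_snps, a, b)
  if (is.null(snp)) snp <- make_uniform_map(n_snps, 1L, 1)
  freq <- cbind(A = pA, B = pB, anc = p0)
  rownames(freq) <- snp$id
  structure(list(freq = freq,
                 count = matrix(Inf, n_snps, 3L,
                                dimnames = list(snp$id, c("A", "B", "anc"))),
                 snp = snp, pops = c("A", "B", "anc"),
                 all_missing = rep(FALSE, n_snps)),
            class = "allele_freq_table")
}

# Ancestry process along one chromosome for one haplotype: breakpoints at
# Poisson rate `t` per Morgan; the state after each breakpoint (and at the
# chromosome start) is drawn from the stationary mix (alpha, 1 - alpha).
# Returns list(bp = breakpoint positions, state = state per segment,
# labels = per-SNP state for SNP positions `pos`).
ancestry_segments <- function(length_m, t, alpha) {
  n_bp <- stats::rpois(1L, t * length_m)
  bp <- sort(stats::runif(n_bp, 0, length_m))
  state <- ifelse(stats::runif(n_bp + 1L) < alpha, 1L, 2L)  # 1 = A, 2 = B
  list(bp = bp, state = state)
}

segment_labels <- function(seg, pos) {
  seg$state[findInterval(pos, seg$bp) + 1L]
}

#' Simulate admixed haplotypes with a known local-ancestry truth track
#'
#' Ancestry along each haplotype follows a two-state Markov process on the
#' genetic map: for a single pulse `t` generations ago with pool-A fraction
#' `alpha`, breakpoints occur at Poisson rate `t` per Morgan and the state
#' after each breakpoint is drawn from the stationary mix `(alpha, 1-alpha)`,
#' giving ancestry autocovariance `alpha (1 - alpha) exp(-t d)`. A second,
#' more recent pulse at time `t2` overlays a rate-`t2` process that replaces
#' a fraction `prop2` of lineage blocks with unadmixed pool-A blocks.
#' Conditional on local ancestry, alleles are drawn independently per SNP
#' from the ancestral pool frequencies (no background LD within pools).
#'
#' @param config a [scenario_config()].
#' @return list with components `haps` (a [haplotype_dataset()] of the
#'   admixed samples), `ref` (a [haplotype_dataset()] of `n_ref` pool-A plus
#'   `n_ref` pool-B reference samples, populations `"A"` and `"B"`),
#'   `truth` (per-SNP ancestry matrix, 1 = A, 2 = B, one column per admixed
#'   haplotype), `freqs` (the ancestral `allele_freq_table`) and
#'   `n_breakpoints` (Poisson breakpoint count per admixed haplotype).
#' @export
simulate_admixed_haplotypes <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  map <- make_uniform_map(config$n_snps, config$n_chromosomes,
                          config$chrom_length_m)
  freqs <- simulate_ancestral_freqs(config$n_snps, config$F,
                                    seed = config$seed + 1L, snp = map)
  pulses <- config$pulses[order(-config$pulses$time), , drop = FALSE]
  n_hap <- 2L * config$n_admixed
  chroms <- unique(map$chrom)

  truth <- matrix(1L, config$n_snps, n_hap)
  n_bp <- integer(n_hap)
  for (h in seq_len(n_hap)) {
    for (ch in chroms) {
      sel <- map$chrom == ch
      pos <- map$gpos[sel]
      seg <- ancestry_segments(config$chrom_length_m,
                               pulses$time[1], pulses$prop[1])
      lab <- segment_labels(seg, pos)
      n_bp[h] <- n_bp[h] + length(seg$bp)
      if (nrow(pulses) > 1L) {
        for (k in 2:nrow(pulses)) {
          ov <- ancestry_segments(config$chrom_length_m,
                                  pulses$time[k], pulses$prop[k])
          # state 1 blocks = lineages replaced by fresh pool-A ancestry
          new_a <- segment_labels(ov, pos) == 1L
          lab[new_a] <- 1L
          n_bp[h] <- n_bp[h] + length(ov$bp)
        }
      }
      truth[sel, h] <- lab
    }
  }

  pmat <- cbind(freqs$freq[, "A"], freqs$freq[, "B"])
  draw <- matrix(stats::runif(config$n_snps * n_hap), config$n_snps, n_hap)
  haps <- matrix(0L, config$n_snps, n_hap)
  haps[draw < pmat[cbind(rep(seq_len(config$n_snps), n_hap),
                         as.vector(truth))]] <- 1L

  ind <- data.frame(id = sprintf("adm%03d", seq_len(config$n_admixed)),
                    sex = "U", pop = "ADMIXED")
  hd <- haplotype_dataset(haps, map, ind)

  n_ref_hap <- 2L * config$n_ref
  ref_haps <- matrix(0L, config$n_snps, 2L * n_ref_hap)
  for (pool in 1:2) {
    drawr <- matrix(stats::runif(config$n_snps * n_ref_hap),
                    config$n_snps, n_ref_hap)
    cols <- (pool - 1L) * n_ref_hap + seq_len(n_ref_hap)
    ref_haps[, cols][drawr < pmat[, pool]] <- 1L
  }
  ref_ind <- data.frame(
    id = c(sprintf("refA%03d", seq_len(config$n_ref)),
           sprintf("refB%03d", seq_len(config$n_ref))),
    sex = "U", pop = rep(c("A", "B"), each = config$n_ref))
  rd <- haplotype_dataset(ref_haps, map, ref_ind)

  list(haps = hd, ref = rd, truth = truth, freqs = freqs,
       n_breakpoints = n_bp)
}

#' Apply a post-admixture founder event
#'
#' Draws `n_founders` individuals from the input sample, then simulates
#' `time` generations of random mating with recombination (crossovers at
#' Poisson rate 1 per Morgan per chromosome per meiosis, free recombination
#' between chromosomes) at a constant population size of `n_after` diploids,
#' and finally returns `n_out` sampled individuals. `n_after` defaults to
#' 1000, large enough that coalescence during the post-founding generations
#' is negligible next to the founder-event signal itself; small values
#' superimpose continuous recent drift on the single founding pulse.
#'
#' @param haps a [haplotype_dataset()].
#' @param time generations since the founder event (>= 1).
#' @param n_founders number of founding diploids (>= 2, at most the input
#'   sample size).
#' @param n_after constant diploid population size maintained after founding
#'   (default 1000).
#' @param n_out number of diploid samples to return (default: input sample
#'   count, capped at `n_after`).
#' @param seed integer seed.
#' @return A [haplotype_dataset()] of the post-event sample.
#' @export
apply_founder_event <- function(haps, time, n_founders, n_after = NULL,
                                n_out = NULL, seed = 1L) {
  stopifnot(inherits(haps, "haplotype_dataset"), time >= 1)
  n_in <- nrow(haps$ind)
  if (n_founders < 2L) stop("n_founders must be >= 2")
  if (n_founders > n_in) stop("n_founders exceeds sample size")
  if (is.null(n_after)) n_after <- 1000L
  if (is.null(n_out)) n_out <- min(n_in, n_after)
  set.seed(seed)

  r <- rle(haps$snp$chrom)               # contiguous chromosome blocks
  if (length(r$values) != length(unique(haps$snp$chrom)))
    stop("SNP map must be grouped by chromosome")
  chrom_start <- c(0L, cumsum(r$lengths))

  founders <- sample.int(n_in, n_founders)
  cur <- haps$haps[, as.vector(rbind(2L * founders - 1L, 2L * founders)),
                   drop = FALSE]
  n_cur <- n_founders
  for (g in seq_len(time)) {
    parents <- vapply(seq_len(n_after),
                      function(i) sample.int(n_cur, 2L), integer(2))
    cur <- cpp_mate_generation(cur, haps$snp$gpos, as.integer(chrom_start),
                               parents - 1L)
    n_cur <- n_after
  }
  keep <- sample.int(n_cur, n_out)
  out <- cur[, as.vector(rbind(2L * keep - 1L, 2L * keep)), drop = FALSE]
  ind <- data.frame(id = sprintf("fnd%03d", seq_len(n_out)), sex = "U",
                    pop = haps$ind$pop[1])
  haplotype_dataset(out, haps$snp, ind)
}

#' Run a full synthetic scenario
#'
#' Convenience wrapper: simulates admixed haplotypes per the config, applies
#' the founder event if configured, and collapses to genotypes with the
#' configured missing rate. Reference pools are appended as additional
#' populations `"A"` and `"B"`. Pulse times are interpreted as generations
#' before present: when a founder event is configured, its `time`
#' generations of explicit random mating supply that much of the ancestry-
#' block fragmentation, and the pre-founding pulse process carries only the
#' remainder, so the dating statistics see the configured age.
#'
#' @param config a [scenario_config()].
#' @return list with `data` (combined [genotype_dataset()] of admixed +
#'   reference samples), `haps` (admixed [haplotype_dataset()], post founder
#'   event if any), `ref_haps`, `truth`, `freqs`, `n_breakpoints`.
#' @export
simulate_scenario <- function(config) {
  pre_config <- config
  if (!is.null(config$founder_event)) {
    # pulse times are generations before present; the founder-event mating
    # itself contributes `time` generations of recombination, so the
    # pre-founding ancestry process only carries the remainder
    fe <- config$founder_event
    if (any(config$pulses$time <= fe$time))
      stop("admixture pulses must predate the founder event")
    pre_config$pulses$time <- config$pulses$time - fe$time
  }
  sim <- simulate_admixed_haplotypes(pre_config)
  adm <- sim$haps
  if (!is.null(config$founder_event)) {
    fe <- config$founder_event
    adm <- apply_founder_event(sim$haps, fe$time, fe$n_founders,
                               n_after = fe$n_after,
                               n_out = config$n_admixed,
                               seed = config$seed + 2L)
  }
  g_adm <- genotypes_from_haplotypes(adm, config$missing_rate,
                                     seed = config$seed + 3L)
  g_ref <- genotypes_from_haplotypes(sim$ref, config$missing_rate,
                                     seed = config$seed + 4L)
  data <- genotype_dataset(cbind(g_adm$geno, g_ref$geno), g_adm$snp,
                           rbind(g_adm$ind, g_ref$ind))
  list(data = data, haps = adm, ref_haps = sim$ref, truth = sim$truth,
       freqs = sim$freqs, n_breakpoints = sim$n_breakpoints)
}

#' Write a local-ancestry truth track as TSV
#'
#' One row per constant-ancestry run per haplotype: columns `haplotype`,
#' `chrom`, `start_M`, `end_M` (half-open genetic interval), `ancestry`.
#'
#' @param truth truth matrix from [simulate_admixed_haplotypes()].
#' @param snp the matching SNP map.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_truth_track <- function(truth, snp, path) {
  rows <- list()
  for (h in seq_len(ncol(truth))) {
    for (ch in unique(snp$chrom)) {
      sel <- snp$chrom == ch
      lab <- truth[sel, h]
      pos <- snp$gpos[sel]
      r <- rle(lab)
      ends <- cumsum(r$lengths)
      starts <- c(1L, utils::head(ends, -1L) + 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        haplotype = h, chrom = ch, start_M = pos[starts], end_M = pos[ends],
        ancestry = c("A", "B")[r$values])
    }
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a five-population phylogeny with one admixed leaf
#'
#' Builds the reference panel layout used for ratio-of-f4 ancestry
#' estimation: an outgroup `Out`, a reference `Ref` splitting from the
#' west-Eurasian-like lineage, a clade population `W` on that lineage, a
#' clade population `S` on the diverged south-Asian-like lineage, and an
#' admixed population `X` drawing a fraction `p_admix` of its ancestry from
#' a sister of `W` and the rest from a sister of `S`. Genotypes for `X` are
#' generated with pulse admixture `t_admix` generations ago so the panel
#' also carries admixture LD.
#'
#' @param n_snps SNP count.
#' @param p_admix true W-side ancestry fraction of `X`.
#' @param t_admix admixture time in generations (default 30).
#' @param n_per_pop diploid samples per reference population.
#' @param n_x diploid samples in `X`.
#' @param n_chromosomes,chrom_length_m map layout.
#' @param seed integer seed.
#' @return A [genotype_dataset()] with populations `Out`, `Ref`, `W`, `S`,
#'   `X`.
#' @export
simulate_f4_scenario <- function(n_snps = 5e4, p_admix = 0.8, t_admix = 30,
                                 n_per_pop = 25L, n_x = 27L,
                                 n_chromosomes = 20L, chrom_length_m = 1,
                                 seed = 1L) {
  set.seed(seed)
  map <- make_uniform_map(n_snps, n_chromosomes, chrom_length_m)
  bn <- function(p, F) {
    p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
    stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }
  p0 <- stats::runif(n_snps, 0.05, 0.95)
  p_out <- bn(p0, 0.15)
  p_we <- bn(p0, 0.05)        # west-Eurasian ancestor
  p_ref <- bn(p_we, 0.05)
  p_wanc <- bn(p_we, 0.02)    # ancestor of W and X's W-side source
  p_w <- bn(p_wanc, 0.02)
  p_xw <- bn(p_wanc, 0.02)
  p_sanc <- bn(p0, 0.12)      # south-Asian ancestor
  p_s <- bn(p_sanc, 0.04)
  p_xs <- bn(p_sanc, 0.04)

  draw_pop <- function(p, n) {
    matrix(stats::rbinom(length(p) * n, 2L, rep(p, n)), length(p), n)
  }
  g_out <- draw_pop(p_out, n_per_pop)
  g_ref <- draw_pop(p_ref, n_per_pop)
  g_w <- draw_pop(p_w, n_per_pop)
  g_s <- draw_pop(p_s, n_per_pop)

  # X: pulse admixture between the two source sisters
  n_hap <- 2L * n_x
  g_x <- matrix(0L, n_snps, n_x)
  hx <- matrix(0L, n_snps, n_hap)
  chroms <- unique(map$chrom)
  for (h in seq_len(n_hap)) {
    lab <- integer(n_snps)
    for (ch in chroms) {
      sel <- map$chrom == ch
      seg <- ancestry_segments(chrom_length_m, t_admix, p_admix)
      lab[sel] <- segment_labels(seg, map$gpos[sel])
    }
    p_h <- ifelse(lab == 1L, p_xw, p_xs)
    hx[, h] <- as.integer(stats::runif(n_snps) < p_h)
  }
  g_x <- hx[, 2L * seq_len(n_x) - 1L] + hx[, 2L * seq_len(n_x)]

  geno <- cbind(g_out, g_ref, g_w, g_s, g_x)
  ind <- data.frame(
    id = c(sprintf("out%02d", 1:n_per_pop), sprintf("ref%02d", 1:n_per_pop),
           sprintf("w%02d", 1:n_per_pop), sprintf("s%02d", 1:n_per_pop),
           sprintf("x%02d", 1:n_x)),
    sex = "U",
    pop = c(rep(c("Out", "Ref", "W", "S"), each = n_per_pop),
            rep("X", n_x)))
  genotype_dataset(geno, map, ind)
}
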