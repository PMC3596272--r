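test_that("Balding-Nichols pool frequencies behave as parameterized", {
  # F -> 0 limit: pool frequencies collapse onto the base frequency
  fr0 <- simulate_ancestral_freqs(500, F = 1e-6, seed = 1)
  expect_lt(max(abs(fr0$freq[, "A"] - fr0$freq[, "anc"])), 0.01)

  # Beta mean identity: E[pA] = p0
  fr <- simulate_ancestral_freqs(1e4, F = 0.2, seed = 2)
  se <- sd(fr$freq[, "A"]) / sqrt(1e4)
  expect_lt(abs(mean(fr$freq[, "A"]) - mean(fr$freq[, "anc"])), 3 * se)
  # and the cross-pool variance matches F p0 (1-p0) on average
  v_obs <- mean((fr$freq[, "A"] - fr$freq[, "anc"])^2)
  v_exp <- 0.2 * mean(fr$freq[, "anc"] * (1 - fr$freq[, "anc"]))
  expect_equal(v_obs, v_exp, tolerance = 0.05)

  expect_error(simulate_ancestral_freqs(10, F = 0), "F must be")
  # determinism
  fr2 <- simulate_ancestral_freqs(100, F = 0.2, seed = 7)
  fr3 <- simulate_ancestral_freqs(100, F = 0.2, seed = 7)
  expect_identical(fr2$freq, fr3$freq)
})

test_that("ancestry process has Poisson breakpoints and exponential segments", {
  cfg <- scenario_config(n_chromosomes = 1L, n_snps = 500,
                         pulses = data.frame(time = 30, prop = 0.5),
                         n_admixed = 100L, n_ref = 2L, seed = 3)
  sim <- simulate_admixed_haplotypes(cfg)
  # 200 haplotypes on a 1-Morgan chromosome: mean breakpoint count ~ 30
  m <- mean(sim$n_breakpoints)
  expect_lt(abs(m - 30), 3 * sqrt(30 / 200))

  # raw inter-breakpoint distances are Exp(t): mean 1/t
  set.seed(9)
  gaps <- unlist(lapply(1:300, function(i) {
    seg <- admixdate:::ancestry_segments(1, 30, 0.5)
    diff(c(0, seg$bp))
  }))
  expect_equal(mean(gaps), 1 / 30, tolerance = 0.05)
  expect_equal(sd(gaps), 1 / 30, tolerance = 0.1)  # exponential: sd = mean

  # stationarity: mean ancestry fraction ~ alpha (ancestry is correlated
  # along chromosomes, so the effective sample size is modest)
  expect_lt(abs(mean(sim$truth == 1L) - 0.5), 0.03)
})

test_that("degenerate single-ancestry pulse yields an all-A truth track", {
  cfg <- scenario_config(n_chromosomes = 2L, n_snps = 200,
                         pulses = data.frame(time = 10, prop = 1),
                         n_admixed = 4L, n_ref = 2L, seed = 5)
  sim <- simulate_admixed_haplotypes(cfg)
  expect_true(all(sim$truth == 1L))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- scenario_config(n_chromosomes = 2L, n_snps = 300, n_admixed = 5L,
                         n_ref = 3L, seed = 11)
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(s1$data$geno, s2$data$geno)
  expect_identical(s1$truth, s2$truth)
})

test_that("founder event: null case preserves frequencies, drift reduces diversity", {
  cfg <- scenario_config(n_chromosomes = 4L, n_snps = 2000,
                         pulses = data.frame(time = 20, prop = 0.5),
                         n_admixed = 40L, n_ref = 2L, seed = 13)
  sim <- simulate_admixed_haplotypes(cfg)

  # null event: every individual survives one generation of mating at the
  # same size -> frequencies move only by binomial noise
  null_ev <- apply_founder_event(sim$haps, time = 1, n_founders = 40L,
                                 n_after = 40L, n_out = 40L, seed = 1)
  f0 <- rowMeans(sim$haps$haps)
  f1 <- rowMeans(null_ev$haps)
  expect_equal(mean(f1), mean(f0), tolerance = 0.02)
  expect_lt(max(abs(f1 - f0)), 5 * sqrt(max(f0 * (1 - f0)) / 80) + 0.02)

  # a 10-founder bottleneck strictly reduces expected heterozygosity
  bott <- apply_founder_event(sim$haps, time = 5, n_founders = 10L,
                              n_after = 40L, n_out = 40L, seed = 2)
  het <- function(h) mean(2 * rowMeans(h$haps) * (1 - rowMeans(h$haps)))
  expect_lt(het(bott), het(sim$haps))

  # reproducibility
  again <- apply_founder_event(sim$haps, time = 5, n_founders = 10L,
                               n_after = 40L, n_out = 40L, seed = 2)
  expect_identical(bott$haps, again$haps)

  expect_error(apply_founder_event(sim$haps, 5, n_founders = 1L), ">= 2")
})

test_that("haplotype collapse sums pairs and masks at the requested rate", {
  snp <- make_snp_map(4)
  haps <- matrix(c(1L, 1L,  0L, 1L,  0L, 0L,  1L, 0L), 4, 2, byrow = TRUE)
  hd <- haplotype_dataset(haps, snp, make_ind(1))
  g <- genotypes_from_haplotypes(hd)
  expect_equal(unname(g$geno[, 1]), c(2L, 1L, 0L, 1L))
  expect_false(anyNA(g$geno))

  cfg <- scenario_config(n_chromosomes = 2L, n_snps = 5000, n_admixed = 10L,
                         n_ref = 2L, seed = 17)
  sim <- simulate_admixed_haplotypes(cfg)
  gm <- genotypes_from_haplotypes(sim$haps, missing_rate = 0.1, seed = 1)
  rate <- mean(is.na(gm$geno))
  expect_equal(rate, 0.1, tolerance = 0.05 * 3)  # binomial over 5e4 calls
})

test_that("truth track writes as half-open per-run intervals", {
  cfg <- scenario_config(n_chromosomes = 2L, n_snps = 400,
                         pulses = data.frame(time = 20, prop = 0.5),
                         n_admixed = 3L, n_ref = 2L, seed = 19)
  sim <- simulate_admixed_haplotypes(cfg)
  path <- file.path(tempdir(), "truth.tsv")
  write_truth_track(sim$truth, sim$haps$snp, path)
  tt <- read.delim(path)
  expect_setequal(unique(tt$ancestry), c("A", "B"))
  # runs reassemble the per-SNP labels for haplotype 1, chromosome 1
  sel <- sim$haps$snp$chrom == "chr1"
  r <- rle(sim$truth[sel, 1])
  expect_equal(sum(tt$haplotype == 1 & tt$chrom == "chr1"), length(r$lengths))
})
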