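test_that("f4 matches hand-computed means and symmetry identities", {
  P <- cbind(A = c(1, 0.5), B = c(0, 0.5), C = c(1, 0.2), D = c(0, 0.9))
  # products: (1-0)(1-0) = 1 and (0.5-0.5)(0.2-0.9) = 0 -> mean 0.5
  fr <- make_freq_table(P, gpos = c(0.01, 0.30))
  est <- f4(fr, "A", "B", "C", "D")
  expect_equal(est$estimate, 0.5)

  set.seed(1)
  P2 <- matrix(runif(4 * 200), 200, 4,
               dimnames = list(NULL, c("A", "B", "C", "D")))
  fr2 <- make_freq_table(P2, gpos = seq(0, 1.2, length.out = 200))
  # C = D gives exactly zero
  P3 <- P2; P3[, "D"] <- P3[, "C"]
  expect_equal(f4(make_freq_table(P3, gpos = fr2$snp$gpos),
                  "A", "B", "C", "D")$estimate, 0)
  # antisymmetry and pair-swap identity hold to machine precision
  expect_equal(f4(fr2, "A", "B", "C", "D")$estimate,
               -f4(fr2, "B", "A", "C", "D")$estimate)
  expect_equal(f4(fr2, "A", "B", "C", "D")$estimate,
               f4(fr2, "C", "D", "A", "B")$estimate)
})

test_that("weighted block jackknife reproduces closed-form small cases", {
  # two equal-weight blocks with distinct values
  v <- c(rep(2, 10), rep(6, 10))
  snp <- make_snp_map(20, gpos = c(seq(0, 0.04, length.out = 10),
                                   seq(0.31, 0.345, length.out = 10)))
  jk <- block_jackknife(v, snp, "5cM")
  expect_equal(jk$n_blocks, 2L)
  expect_equal(jk$estimate, 4)
  loo <- c(mean(v[11:20]), mean(v[1:10]))
  expect_equal(jk$se, oracle_weighted_jackknife_se(4, loo, c(10, 10)))

  # identical block means -> SE = 0
  jk0 <- block_jackknife(rep(3, 20), snp, "5cM")
  expect_equal(jk0$se, 0)

  # single block errors
  expect_error(block_jackknife(v, make_snp_map(20), "chromosome"),
               ">= 2")

  # jackknife SE of an iid mean shrinks ~ 1/sqrt(n)
  set.seed(4)
  ses <- sapply(c(400, 1600), function(n) {
    x <- rnorm(n)
    block_jackknife(x, make_snp_map(n, gpos = seq(0, 1, length.out = n)),
                    "5cM")$se
  })
  expect_equal(ses[1] / ses[2], 2, tolerance = 0.4)
})

test_that("4-population test separates admixed from tree-consistent data", {
  set.seed(2)
  n <- 4000
  gpos <- rep(seq(0, 1.2, length.out = n / 4), 4)
  chrom <- rep(paste0("chr", 1:4), each = n / 4)
  # tree-consistent: (A,B) and (C,D) drift independently
  p0 <- runif(n, 0.1, 0.9)
  drift <- function(p, f) pmin(pmax(p + rnorm(n, 0, sqrt(f * p * (1 - p))),
                                    1e-3), 1 - 1e-3)
  P <- cbind(A = drift(p0, 0.02), B = drift(p0, 0.02),
             C = drift(p0, 0.02), D = drift(p0, 0.02))
  fr <- make_freq_table(P, gpos = gpos, chrom = chrom)
  null_t <- four_population_test(fr, "A", "B", "C", "D")
  expect_lt(abs(null_t$Z), 4)

  # admixed D: 20% ancestry from the (A,B) side
  P2 <- P; P2[, "D"] <- 0.8 * drift(p0, 0.02) + 0.2 * P[, "A"]
  adm_t <- four_population_test(make_freq_table(P2, gpos = gpos,
                                                chrom = chrom),
                                "A", "B", "C", "D")
  expect_true(adm_t$reject)
  expect_gt(abs(adm_t$Z), 3)

  # orthogonalized difference vectors give exactly zero correlation
  x <- P[, "A"] - P[, "B"]
  y0 <- P[, "C"] - P[, "D"]
  y <- unname(residuals(lm(y0 ~ x)))     # orthogonal to x and the intercept
  Q <- cbind(A = x, B = 0, C = y, D = 0)
  ortho <- four_population_test(make_freq_table(Q, gpos = gpos,
                                                chrom = chrom),
                                "A", "B", "C", "D")
  expect_equal(ortho$correlation, 0, tolerance = 1e-12)

  # constant difference vector is an explicit error
  Pc <- P; Pc[, "B"] <- Pc[, "A"]
  expect_error(four_population_test(make_freq_table(Pc, gpos = gpos,
                                                    chrom = chrom),
                                    "A", "B", "C", "D"), "constant")
})

test_that("f4-ratio ancestry hits the pure-ancestry endpoints and 80/20", {
  d <- simulate_f4_scenario(n_snps = 2e4, p_admix = 0.8, seed = 31,
                            n_per_pop = 25, n_x = 27)
  fr <- allele_frequencies(d)

  # X copied from the cladeW population -> p = 1 (same frequency column)
  fr1 <- fr
  fr1$freq[, "X"] <- fr1$freq[, "W"]
  expect_equal(f4_ratio_ancestry(fr1, "Out", "Ref", "X", "W", "S")$estimate,
               1)
  fr0 <- fr
  fr0$freq[, "X"] <- fr0$freq[, "S"]
  expect_equal(f4_ratio_ancestry(fr0, "Out", "Ref", "X", "W", "S")$estimate,
               0)

  est <- f4_ratio_ancestry(fr, "Out", "Ref", "X", "W", "S")
  expect_lt(abs(est$estimate - 0.8), 3 * est$se)

  # near-zero denominator is refused: cladeW and cladeS both set to the
  # midpoint population removes the contrast
  frbad <- fr
  frbad$freq[, "W"] <- frbad$freq[, "S"]
  expect_error(f4_ratio_ancestry(frbad, "Out", "Ref", "X", "W", "S"),
               "denominator")
})

test_that("Hudson Fst recovers the generator differentiation and endpoints", {
  set.seed(6)
  n <- 2e4
  fr_pool <- simulate_ancestral_freqs(n, F = 0.1, seed = 8)
  # finite samples of 25 diploids per pool
  gA <- matrix(rbinom(n * 25, 2, rep(fr_pool$freq[, "A"], 25)), n, 25)
  gB <- matrix(rbinom(n * 25, 2, rep(fr_pool$freq[, "B"], 25)), n, 25)
  d <- genotype_dataset(cbind(gA, gB), fr_pool$snp,
                        make_ind(50, pop = rep(c("A", "B"), each = 25)))
  fr <- allele_frequencies(d)
  est <- fst_pairwise(fr, "A", "B")
  # both pools drift Var = F p0 q0 from the shared base frequency, so the
  # ratio-of-averages Hudson estimator has expectation F
  expect_lt(abs(est$estimate - 0.1), max(3 * est$se, 0.01))

  # same samples in both populations -> ~0; fixed differences -> 1
  # literally reusing the same samples leaves only the -1/(n-1) finite-
  # sample artefact of the correction term
  same <- fst_pairwise(fr, "A", "A")
  expect_lt(abs(same$estimate), 0.03)
  Pfix <- cbind(A = rep(c(1, 0), 50), B = rep(c(0, 1), 50))
  fix <- make_freq_table(Pfix, gpos = seq(0, 1, length.out = 100))
  expect_equal(fst_pairwise(fix, "A", "B")$estimate, 1)
})
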