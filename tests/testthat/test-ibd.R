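# Haplotype fixture with a planted shared segment between two individuals.
make_ibd_fixture <- function(n_snps = 4000, n_ind = 6, share_lo = 0.05,
                             share_hi = 0.15, seed = 71) {
  set.seed(seed)
  haps <- matrix(sample(0:1, n_snps * 2 * n_ind, replace = TRUE),
                 n_snps, 2 * n_ind)
  gpos <- sort(runif(n_snps, 0, 0.5))
  # individual 1 haplotype 1 copied into individual 2 haplotype 2 over the
  # planted window
  win <- which(gpos >= share_lo & gpos <= share_hi)
  haps[win, 4] <- haps[win, 1]
  hd <- haplotype_dataset(haps, make_snp_map(n_snps, gpos = gpos),
                          make_ind(n_ind))
  list(haps = hd, win = win, gpos = gpos)
}

test_that("a planted 10 cM shared haplotype is found as one segment", {
  fx <- make_ibd_fixture()
  segs <- detect_ibd_segments(fx$haps, seed_snps = 75, min_cm = 3)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$sample_i, "i1")
  expect_equal(segs$sample_j, "i2")
  expect_gte(segs$length_cm, 0.9 * 10)
  # the reported span stays inside the planted window plus chance extension
  expect_gte(segs$start_cm, 100 * min(fx$gpos[fx$win]) - 1)
  expect_lte(segs$end_cm, 100 * max(fx$gpos[fx$win]) + 1)
})

test_that("mutually random haplotypes yield no >= 3 cM segments", {
  set.seed(73)
  n <- 1e4
  haps <- matrix(sample(0:1, n * 8, replace = TRUE), n, 8)
  hd <- haplotype_dataset(haps, make_snp_map(n, gpos = sort(runif(n, 0, 1))),
                          make_ind(4))
  expect_equal(nrow(detect_ibd_segments(hd)), 0L)
})

test_that("an individual is never matched against itself", {
  set.seed(74)
  n <- 2000
  haps <- matrix(sample(0:1, n * 4, replace = TRUE), n, 4)
  haps[, 2] <- haps[, 1]                 # identical haplotype pair within i1
  hd <- haplotype_dataset(haps, make_snp_map(n, gpos = sort(runif(n, 0, 0.3))),
                          make_ind(2))
  segs <- detect_ibd_segments(hd)
  expect_false(any(segs$sample_i == segs$sample_j))
})

test_that("sharing distance reproduces the hand-computed average", {
  labels <- data.frame(id = c("i1", "i2", "j1"),
                       pop = c("I", "I", "J"))
  segs <- data.frame(sample_i = c("i1", "i1"), sample_j = c("j1", "j1"),
                     chrom = "chr1", start_cm = 0, end_cm = 0,
                     length_cm = c(4, 6))
  sd_ij <- sharing_distance(segs, "I", "J", labels)
  expect_equal(sd_ij$sharing_cm, 10 / (2 * 1))   # = 5.0 cM
  # symmetry
  expect_equal(sharing_distance(segs, "J", "I", labels)$sharing_cm,
               sd_ij$sharing_cm)
  # no segments -> 0
  expect_equal(sharing_distance(segs[0, ], "I", "J", labels)$sharing_cm, 0)
  # within-population uses n(n-1)/2 pairs
  segs2 <- data.frame(sample_i = "i1", sample_j = "i2", chrom = "chr1",
                      start_cm = 0, end_cm = 0, length_cm = 8)
  expect_equal(sharing_distance(segs2, "I", "I", labels)$sharing_cm, 8)
  expect_error(sharing_distance(segs, "I", "NOPE", labels), "empty")
})

test_that("bootstrap caps group sizes and flags unresampled groups", {
  set.seed(75)
  ids_t <- paste0("t", 1:5)
  ids_big <- paste0("b", 1:40)
  ids_small <- paste0("s", 1:4)
  labels <- data.frame(id = c(ids_t, ids_big, ids_small),
                       pop = rep(c("T", "BIG", "SMALL"),
                                 c(5, 40, 4)))
  segs <- data.frame(
    sample_i = rep(ids_t, times = 8),
    sample_j = sample(ids_big, 40, replace = TRUE),
    chrom = "chr1", start_cm = 0, end_cm = 0,
    length_cm = runif(40, 3, 8))
  bs <- bootstrap_sharing(segs, labels, "T", cap = 30, reps = 50, seed = 1)
  expect_true(is.na(bs$se_cm[bs$pop == "SMALL"]))   # under the cap
  expect_false(bs$resampled[bs$pop == "SMALL"])
  expect_true(bs$resampled[bs$pop == "BIG"])
  expect_gt(bs$se_cm[bs$pop == "BIG"], 0)
  # bootstrap mean consistent with the full-sample statistic
  full <- sharing_distance(segs, "T", "BIG", labels)$sharing_cm
  expect_lt(abs(bs$mean_cm[bs$pop == "BIG"] - full),
            max(3 * bs$se_cm[bs$pop == "BIG"], 0.3 * full))
  # cap covering every group reproduces the point estimate exactly
  bs2 <- bootstrap_sharing(segs, labels, "T", cap = 40, reps = 5, seed = 2)
  expect_equal(bs2$mean_cm[bs2$pop == "BIG"], full)
})

test_that("ancestry correction removes exactly the linear component", {
  set.seed(76)
  ids_t <- paste0("t", 1:6)
  pops <- rep(c("P1", "P2"), each = 5)
  ids_o <- paste0("o", 1:10)
  labels <- data.frame(id = c(ids_t, ids_o), pop = c(rep("T", 6), pops))
  anc <- setNames(runif(16, 0.2, 0.9), c(ids_t, ids_o))

  # sharing constructed as a pure linear function of pair-mean ancestry
  segs <- do.call(rbind, lapply(ids_t, function(i) {
    do.call(rbind, lapply(ids_o, function(j) {
      data.frame(sample_i = i, sample_j = j, chrom = "chr1",
                 start_cm = 0, end_cm = 0,
                 length_cm = 10 * (anc[[i]] + anc[[j]]) / 2)
    }))
  }))
  corr <- ancestry_corrected_sharing(segs, labels, anc, "T")
  expect_lt(max(abs(corr$corrected_cm - mean(segs$length_cm))), 1e-9)

  # ancestry uncorrelated with sharing: correction is a no-op
  segs2 <- segs
  set.seed(77)
  segs2$length_cm <- 5
  corr2 <- ancestry_corrected_sharing(segs2, labels, anc, "T")
  expect_equal(corr2$corrected_cm, corr2$sharing_cm, tolerance = 1e-9)

  # planted excess for P1 atop the ancestry gradient survives correction
  segs3 <- segs
  boost <- segs3$sample_j %in% ids_o[pops == "P1"]
  segs3$length_cm[boost] <- segs3$length_cm[boost] + 4
  corr3 <- ancestry_corrected_sharing(segs3, labels, anc, "T")
  expect_gt(corr3$corrected_cm[corr3$pop == "P1"],
            corr3$corrected_cm[corr3$pop == "P2"])

  expect_error(ancestry_corrected_sharing(segs, labels,
                                          setNames(rep(0.5, 16),
                                                   names(anc)), "T"),
               "constant")
})
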