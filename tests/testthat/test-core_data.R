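test_that("constructor enforces the dataset invariants", {
  snp <- make_snp_map(3)
  ind <- make_ind(2)
  g <- matrix(c(0L, 1L, 2L, NA, 0L, 1L), 3, 2)
  d <- genotype_dataset(g, snp, ind)
  expect_equal(dim(d), c(3L, 2L))

  expect_error(genotype_dataset(matrix(3L, 3, 2), snp, ind), "dosages")
  bad_map <- snp
  bad_map$gpos <- c(0.2, 0.1, 0.3)
  expect_error(genotype_dataset(g, bad_map, ind), "non-decreasing")
  expect_error(genotype_dataset(g[1:2, ], snp, ind), "rows")
})

test_that("EIGENSTRAT round-trip is lossless and maps 9 to missing", {
  d <- make_tiny_dataset(n_snps = 12, n_samples = 5, missing = 3,
                         chrom = rep(c("chr1", "chr2"), each = 6))
  prefix <- file.path(tempdir(), "rt")
  write_eigenstrat(d, prefix)
  d2 <- read_eigenstrat(prefix)
  expect_equal(unname(d2$geno), unname(d$geno))
  expect_equal(d2$snp$gpos, d$snp$gpos, tolerance = 1e-9)
  expect_equal(d2$ind$pop, d$ind$pop)

  # a written missing call appears as the character 9
  miss <- which(is.na(d$geno), arr.ind = TRUE)[1, ]
  line <- readLines(paste0(prefix, ".geno"))[miss["row"]]
  expect_equal(substr(line, miss["col"], miss["col"]), "9")

  # empty dataset writes zero-length files without crashing
  empty <- subset_dataset(d, snps = integer(0))
  write_eigenstrat(empty, file.path(tempdir(), "empty"))
  expect_length(readLines(file.path(tempdir(), "empty.geno")), 0)

  # row-count mismatch is rejected with a diagnostic
  writeLines(readLines(paste0(prefix, ".geno"))[-1], paste0(prefix, ".geno"))
  expect_error(read_eigenstrat(prefix), "mismatch")
})

test_that("PLINK text import agrees with the dosage representation", {
  map <- data.frame(chrom = "1", id = c("s1", "s2"), gpos = c(0.01, 0.02),
                    ppos = c(1000, 2000))
  ped <- rbind(
    c("FAM", "i1", "0", "0", "1", "-9", "A", "A", "C", "G"),
    c("FAM", "i2", "0", "0", "2", "-9", "A", "G", "0", "0"))
  prefix <- file.path(tempdir(), "pl")
  write.table(map, paste0(prefix, ".map"), row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  write.table(ped, paste0(prefix, ".ped"), row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  d <- read_plink_text(prefix)
  # first allele seen is REF: dosage counts the other allele
  expect_equal(unname(d$geno[1, ]), c(0L, 1L))
  expect_equal(unname(d$geno[2, ]), c(1L, NA_integer_))
  expect_equal(d$ind$sex, c("M", "F"))
})

test_that("allele frequencies match hand tallies and flag empty SNPs", {
  g <- matrix(c(0L, 1L, 2L,   2L, 2L, 1L,
                NA, NA, NA,   NA, NA, NA), 2, 6, byrow = TRUE)
  d <- genotype_dataset(g, make_snp_map(2),
                        make_ind(6, pop = rep(c("P1", "P2"), each = 3)))
  fr <- allele_frequencies(d)
  expect_equal(unname(fr$freq[1, ]), c(0.5, 5 / 6))   # hand tally
  expect_true(fr$all_missing[2])
  expect_equal(unname(fr$count[1, ]), c(6L, 6L))
  expect_error(allele_frequencies(d, "nope"), "unknown")
})

test_that("merged-population frequency is the count-weighted mean", {
  d <- make_tiny_dataset(n_snps = 20, n_samples = 9, missing = 5)
  d$ind$pop <- rep(c("P1", "P2"), c(4, 5))
  fr <- allele_frequencies(d, c("P1", "P2"))
  merged <- d
  merged$ind$pop <- "ALL"
  fm <- allele_frequencies(merged, "ALL")
  wmean <- (fr$freq[, 1] * fr$count[, 1] + fr$freq[, 2] * fr$count[, 2]) /
    (fr$count[, 1] + fr$count[, 2])
  expect_equal(unname(fm$freq[, 1]), unname(wmean))
})

test_that("missingness filter drops samples first, then SNPs, and is idempotent", {
  # 20 SNPs, 4 samples; sample 4 misses 10% of calls; SNP 1 missing in one
  # of the three surviving samples (rate 1/3 > 5%)
  g <- matrix(0L, 20, 4)
  g[1:2, 4] <- NA
  g[1, 2] <- NA
  d <- genotype_dataset(g, make_snp_map(20), make_ind(4))
  f <- filter_missingness(d, 0.05)
  expect_equal(nrow(f$ind), 3L)          # sample 4 dropped
  expect_equal(nrow(f$snp), 19L)         # then SNP 1 dropped
  expect_identical(f$snp$id, d$snp$id[-1])
  # fully observed data unchanged; second pass changes nothing
  expect_equal(dim(filter_missingness(f, 0.05)), dim(f))
  complete <- make_tiny_dataset(missing = 0)
  expect_equal(dim(filter_missingness(complete, 0.05)), dim(complete))
})

test_that("LD thinning removes the later member of correlated pairs", {
  set.seed(1)
  base <- matrix(sample(0:2, 60 * 40, replace = TRUE), 60, 40)
  base[7, ] <- base[3, ]                 # exact duplicate of SNP 3
  d <- genotype_dataset(base, make_snp_map(60), make_ind(40))
  thin <- ld_thin(d, r2_max = 0.1)
  expect_false("s7" %in% thin$snp$id)
  expect_true("s3" %in% thin$snp$id)     # lower index retained

  # survivor set equals an independent brute-force greedy pass
  keep <- rep(TRUE, 60)
  for (st in seq(1, 60, by = 5)) {
    idx <- st:min(st + 49, 60)
    for (a in idx) for (b in idx) {
      if (b <= a || !keep[a] || !keep[b]) next
      r2 <- suppressWarnings(
        cor(base[a, ], base[b, ], use = "pairwise.complete.obs"))^2
      if (!is.na(r2) && r2 > 0.1) keep[b] <- FALSE
    }
  }
  expect_identical(thin$snp$id, d$snp$id[keep])

  # idempotence needs enough samples that chance r2 never nears the
  # threshold; plant a correlated block on 400 samples
  set.seed(2)
  lat <- sample(0:2, 400, replace = TRUE)
  big <- matrix(sample(0:2, 30 * 400, replace = TRUE), 30, 400)
  for (j in 10:14)                       # correlated block around the latent
    big[j, ] <- ifelse(runif(400) < 0.9, lat, sample(0:2, 400, TRUE))
  d2 <- genotype_dataset(big, make_snp_map(30), make_ind(400))
  t1 <- ld_thin(d2, 0.1)
  expect_lt(nrow(t1$snp), 30L)
  expect_identical(ld_thin(t1, 0.1)$snp$id, t1$snp$id)

  # mutually independent SNPs survive untouched
  d3 <- genotype_dataset(big[1:9, ], make_snp_map(9), make_ind(400))
  expect_equal(nrow(ld_thin(d3, 0.1)$snp), 9L)
})
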