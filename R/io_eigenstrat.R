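#' Read an EIGENSTRAT geno/snp/ind triplet
#'
#' @param prefix path prefix; `<prefix>.geno`, `<prefix>.snp` and
#'   `<prefix>.ind` must exist. The `.geno` file holds one row per SNP with
#'   one character per sample in `{0,1,2,9}`; `9` is mapped to missing. The
#'   `.snp` file columns are SNP id, chromosome, genetic position and
#'   physical position (plus optional alleles); the `.ind` file columns are
#'   sample id, sex and population.
#' @param gpos_unit `"morgan"` (default) or `"cM"`; centimorgan input is
#'   converted to Morgans on read.
#' @return A [genotype_dataset()].
#' @export
read_eigenstrat <- function(prefix, gpos_unit = c("morgan", "cM")) {
  gpos_unit <- match.arg(gpos_unit)
  files <- paste0(prefix, c(".geno", ".snp", ".ind"))
  missing_f <- files[!file.exists(files)]
  if (length(missing_f))
    stop("missing file(s): ", paste(missing_f, collapse = ", "))

  ind_raw <- utils::read.table(files[3], header = FALSE,
                               col.names = c("id", "sex", "pop"),
                               colClasses = "character")
  snp_raw <- utils::read.table(files[2], header = FALSE,
                               colClasses = "character")
  nc <- ncol(snp_raw)
  names(snp_raw)[1:4] <- c("id", "chrom", "gpos", "ppos")
  snp_raw$gpos <- as.numeric(snp_raw$gpos)
  snp_raw$ppos <- as.numeric(snp_raw$ppos)
  snp_raw$ref <- if (nc >= 5) snp_raw[[5]] else "A"
  snp_raw$alt <- if (nc >= 6) snp_raw[[6]] else "C"
  snp <- snp_raw[c("id", "chrom", "gpos", "ppos", "ref", "alt")]
  if (gpos_unit == "cM") snp$gpos <- snp$gpos / 100

  lines <- readLines(files[1])
  lines <- lines[nzchar(lines)]
  if (length(lines) != nrow(snp))
    stop("row-count mismatch: ", length(lines), " geno rows vs ",
         nrow(snp), " snp rows")
  if (length(lines) && any(nchar(lines) != nrow(ind_raw)))
    stop("geno row width differs from sample count (", nrow(ind_raw), ")")
  geno <- matrix(NA_integer_, length(lines), nrow(ind_raw))
  if (length(lines)) {
    codes <- vapply(strsplit(lines, "", fixed = TRUE), as.integer,
                    integer(nrow(ind_raw)))
    geno <- if (is.matrix(codes)) t(codes) else matrix(codes, nrow = 1L)
    geno[geno == 9L] <- NA_integer_
  }
  genotype_dataset(geno, snp, ind_raw)
}

#' Write an EIGENSTRAT geno/snp/ind triplet
#'
#' Inverse of [read_eigenstrat()]: missing dosages are written as `9`,
#' genetic positions are written in Morgans.
#'
#' @param data a [genotype_dataset()].
#' @param prefix output path prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_eigenstrat <- function(data, prefix) {
  stopifnot(inherits(data, "genotype_dataset"))
  files <- paste0(prefix, c(".geno", ".snp", ".ind"))
  g <- data$geno
  g[is.na(g)] <- 9L
  lines <- if (nrow(g)) apply(g, 1L, paste, collapse = "") else character()
  writeLines(lines, files[1])
  utils::write.table(
    data.frame(data$snp$id, data$snp$chrom,
               format(data$snp$gpos, digits = 10, scientific = FALSE,
                      trim = TRUE),
               data$snp$ppos, data$snp$ref, data$snp$alt),
    files[2], quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(data$ind$id, data$ind$sex, data$ind$pop),
    files[3], quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(files)
}

#' Read PLINK text ped/map files
#'
#' Minimal import path for transposing PLINK text data into the package's
#' dosage representation. The first allele observed at a SNP (scanning
#' samples in order) is taken as the reference; dosage counts the other
#' allele. `0` allele codes are missing.
#'
#' @param prefix path prefix; `<prefix>.ped` and `<prefix>.map` must exist.
#' @param map_unit unit of the map file's third column (`"morgan"` or
#'   `"cM"`).
#' @return A [genotype_dataset()].
#' @export
read_plink_text <- function(prefix, map_unit = c("morgan", "cM")) {
  map_unit <- match.arg(map_unit)
  ped_f <- paste0(prefix, ".ped")
  map_f <- paste0(prefix, ".map")
  if (!file.exists(ped_f) || !file.exists(map_f))
    stop("missing ", ped_f, " or ", map_f)
  map <- utils::read.table(map_f, header = FALSE,
                           col.names = c("chrom", "id", "gpos", "ppos"),
                           colClasses = c("character", "character",
                                          "numeric", "numeric"))
  if (map_unit == "cM") map$gpos <- map$gpos / 100
  ped <- utils::read.table(ped_f, header = FALSE, colClasses = "character")
  n_snp <- nrow(map)
  if (ncol(ped) != 6L + 2L * n_snp)
    stop("ped column count inconsistent with map (", n_snp, " SNPs)")
  a1 <- as.matrix(ped[, 6L + 2L * seq_len(n_snp) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(n_snp), drop = FALSE])
  geno <- matrix(NA_integer_, n_snp, nrow(ped))
  ref <- alt <- character(n_snp)
  for (j in seq_len(n_snp)) {
    al <- c(a1[, j], a2[, j])
    obs <- setdiff(unique(al), "0")
    if (length(obs) > 2L)
      stop("SNP ", map$id[j], " has >2 alleles")
    ref[j] <- if (length(obs)) obs[1] else "A"
    alt[j] <- if (length(obs) >= 2L) obs[2] else "C"
    d <- (a1[, j] == alt[j]) + (a2[, j] == alt[j])
    d[a1[, j] == "0" | a2[, j] == "0"] <- NA_integer_
    geno[j, ] <- d
  }
  sex <- c(`1` = "M", `2` = "F")[ped[[5]]]
  sex[is.na(sex)] <- "U"
  ind <- data.frame(id = ped[[2]], sex = sex, pop = ped[[1]])
  genotype_dataset(geno, data.frame(id = map$id, chrom = map$chrom,
                                    gpos = map$gpos, ppos = map$ppos,
                                    ref = ref, alt = alt), ind)
}
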