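Package: admixdate
Title: Dating Admixture and Founder Events from Genome-Wide SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inference of admixture history from genotype data with a genetic
    map: weighted-LD decay curves in covariance form with single- and two-pulse
    exponential dating, f4 statistics, the 4-population test and F4 Ratio
    Estimation of ancestry proportions with 5 cM block jackknife standard
    errors, founder-event dating from the decay of allele-sharing
    autocorrelation, runs-of-homozygosity detection, identity-by-descent
    sharing statistics with regional bootstrap and ancestry-residualized
    sharing, and a synthetic admixed-genome generator (Balding-Nichols
    ancestral pools, pulse admixture, post-admixture founder events) so that
    every estimator can be validated by parameter recovery. EIGENSTRAT and
    PLINK text formats are supported.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
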