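---
title: "Dating admixture and founder events from weighted LD and allele sharing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating admixture and founder events from weighted LD and allele sharing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

When two diverged populations mix in a pulse `n` generations ago, chromosomes
in the admixed population are mosaics of ancestry blocks whose boundaries
accumulate at one crossover per Morgan per generation. Two loci separated by
`d` Morgans therefore sit on the same ancestry block with probability
`exp(-n d)`, and the covariance of their local ancestries is
`alpha (1 - alpha) exp(-n d)` for mixture fraction `alpha`. Because allele
frequencies differ between the source populations, ancestry covariance shows
up as linkage disequilibrium, and its decay rate in genetic distance *is* the
age of the mixture.

`admixdate` measures this with the weighted-LD statistic in covariance form:
for every same-chromosome SNP pair `(x, y)` at distance `d`,

```
R(d) = mean over pairs in bin d of  cov(x, y) * w(x) * w(y)
```

where `cov` is the sample covariance of dosages across the admixed
individuals and `w` is a per-SNP weight carrying the direction of ancestral
differentiation — either the allele-frequency difference between surrogate
source populations (`freq_difference_weights()`) or the SNP loadings of a
reference-panel principal component (`pca_loadings()`), for the common case
where no clean source surrogates exist. The curve is fit with
`A * exp(-n d) + c` (`fit_single_exponential()`); the affine term `c` absorbs
distance-independent covariance. A sum of two exponentials
(`fit_two_pulse()`) dates two pulses, reported as `n1 > n2`. Standard errors
come from a delete-one-chromosome weighted jackknife (`jackknife_date()`).

The covariance form matters: the original correlation-coefficient
formulation normalizes each bin by a term that itself decays exponentially
when the population underwent a strong founder event after admixture (at a
rate about twice the event's age), dragging the fitted date toward the
present. `legacy_correlation_curve()` reconstructs that statistic and its
squared normalization term as a diagnostic; the covariance form is the
estimator.

Ancestry *proportions* come from ratios of f4 statistics
(`f4_ratio_ancestry()`): with an outgroup and a reference population spanning
a drift edge, and two populations forming clades with the admixed group's two
sources, `f4(Out, Ref; X, S) / f4(Out, Ref; W, S)` estimates the W-side
ancestry fraction without any unadmixed source sample. The 4-population test
(`four_population_test()`) supplies the preceding model check: under the tree
`((A, B), (C, D))` the correlation of frequency differences `A - B` and
`C - D` is zero, and `|Z| > 3` (block jackknife) rejects treeness.

Founder events are dated from allele sharing (`allele_sharing_
autocorrelation()`): two genotypes share 0, 1/2 or 1 of their alleles
identical in state; for SNP pairs at distance `D` the Pearson correlation of
sharing across individual pairs measures excess identity-by-descent, which
for an event `t` generations ago decays as `exp(-2 t D)` — both lineages of
a pair accumulate recombination, hence the factor 2 in
`fit_founder_date()`'s model `A * exp(-2 t D) + c` (a `rate_factor` flag
exposes the single-lineage convention). Subtracting the (target, reference)
cross-population curve removes sharing inherited from the common ancestral
population. Runs of homozygosity (`detect_roh()`) and IBD segment sharing
(`detect_ibd_segments()`, `sharing_distance()`) complete the founder-event
picture.

## Tunable parameters

* `bin_width` (Morgans, default 0.001 = 0.1 cM) — curve resolution; only
  amplitude, not the fitted rate, depends on it.
* fit window `d_min`–`d_max` (default 0.005–0.3 M, i.e. 0.5–30 cM). The
  0.5 cM floor excludes the range where background LD within the source
  populations contaminates admixture LD in real data. For very old pulses
  (hundreds of generations) the signal lives below 0.5 cM, so the window
  must be moved down — legitimate on array data only after verifying
  background LD is controlled, and always legitimate on this package's
  synthetic data, which has none. `d_max` should cover several e-foldings
  of the slowest decay of interest (we use `min(0.3, 6/n)` in sweeps).
* Multi-start grids: single-exponential fits start from
  `n in {5, 20, 50, 150, 400}`; two-pulse fits from an ordered grid of rate
  pairs; convergence tolerances 1e-12 (Levenberg–Marquardt via minpack.lm).
  The two-pulse fit declares degeneracy when `n1/n2 < 1.5` and falls back
  to the single-pulse model with a warning — below that ratio the two
  amplitudes trade off freely and the split is not identifiable.
* Block jackknife: 5 cM blocks on the genetic map per chromosome (the last
  partial block is kept), weighted delete-one-block formulas with block SNP
  counts as weights; dates use whole-chromosome blocks.
* ROH thresholds: >= 1 Mb, >= 100 SNPs, <= 1 heterozygous and <= 5 missing
  calls per segment; the scan emits the longest qualifying run greedily
  left-to-right, so reported segments never overlap and each satisfies all
  four limits.
* IBD matcher: exact seed windows of 75 SNPs, zero-mismatch extension,
  3 cM minimum reported length, phased input assumed.

## The synthetic-data generator

`scenario_config()` + `simulate_scenario()` generate the study conditions
every estimator is validated against:

* Two ancestral pools diverge under the Balding–Nichols model: a base
  frequency `p0 ~ U[0.05, 0.95]` per SNP and pool frequencies
  `Beta(p0(1-F)/F, (1-p0)(1-F)/F)` with `F = 0.1` by default, a
  continental-scale differentiation chosen to stand in for the
  European/South-Asian contrast.
* Pulse admixture: ancestry along each haplotype is a Markov process with
  Poisson breakpoints at rate `t` per Morgan and stationary mix
  `(alpha, 1-alpha)`; a second, younger pulse overlays replacement by fresh
  pool-A lineage blocks. Pulse times always mean generations before
  present: when a founder event at `t_f` is configured, the explicit mating
  contributes `t_f` generations of fragmentation and the pre-founding
  process carries only `t - t_f`.
* Founder events: `n_founders` individuals drawn, then `time` generations
  of random mating with recombination at constant size `n_after`
  (default 1000). The constant size is deliberately large: a small
  post-founding population keeps generating new coalescences, which
  superimposes a continuum of younger dates on the founding pulse and
  biases the fitted event age down. Our founder-event validation scenarios
  use `n_after = 4000`, mirroring a severe founder event followed by rapid
  expansion — the regime the method targets. Holding the population small
  instead is a different demography (continuous endogamy), and the fitted
  date then honestly reflects a mixture of event ages.
* Genotypes are haplotype sums with optional independent dropout; the
  per-SNP, per-haplotype local-ancestry truth is returned and can be
  written as a TSV sidecar (`write_truth_track()`).

What the generator does *not* emulate: background LD within the ancestral
pools (alleles are independent given local ancestry), mutation, realistic
variable recombination maps (uniform per chromosome), genotyping error
modes beyond random dropout, and coalescent depth within pools. Passing
recovery tests here therefore demonstrates the estimators' correctness
under their own model assumptions — it does not certify performance against
background-LD confounding below ~0.5 cM on real array data, which is
exactly why the default fit window starts at 0.5 cM.

`simulate_f4_scenario()` builds the five-population layout for ratio-of-f4
validation: an outgroup, a reference on the W-side lineage, clade partners
for both sources, and an admixed leaf with a known mixture fraction.

## Numerical and design choices

* Bin values are pair-count-normalized sums; fits are weighted by pair
  counts. Normalization affects `A`, never `n`.
* Covariances use pairwise-complete observations; SNPs with any missing
  call take a slower exact path, fully-observed SNPs a centered-dot-product
  fast path (identical results, tested to 1e-12 against a brute-force
  double loop).
* Monomorphic SNPs are dropped before PCA; loadings are unit-normalized
  (scale cancels in date fits); the PCA axis defaults to the one whose
  scores best separate the reference population labels, overridable.
* The allele-sharing autocorrelation centers and normalizes each SNP's
  sharing vector across individual pairs, so each SNP pair contributes a
  Pearson correlation; monomorphic-sharing SNPs are skipped. Absolute
  amplitudes depend on this centering convention; decay rates — the dated
  quantity — do not.
* The no-event verdict of `fit_founder_date()` triggers on non-positive
  amplitude or amplitude within twice the residual noise.
* Sample-first, SNP-second order in the missingness filter is fixed for
  reproducibility. LD thinning keeps the lower-index SNP of any offending
  pair and slides windows over the stored SNP order.
* All generators consume one integer seed; every simulation in the tests
  and the acceptance script is reproducible from it.

## Validation scale

The recovery suites run single pulses at 30/100/300 generations (100K–300K
SNPs over 20 chromosomes of 1 Morgan, 25–27 diploid samples), a 500K-SNP
age sweep from 10 to 300 generations at 20% ancestry, an 80/20 ratio-of-f4
panel, a 25-founder event 27 generations ago, and the two-pulse 37 + 4
generation design. These sizes keep each scenario within minutes on one
core while leaving the Monte Carlo error of each fitted date well inside
the tolerance being asserted (10% for single-pulse dates, 15% for the
two-pulse older date and founder events).

## Known limitations

* Weighted-LD dating assumes pulse admixture; continuous gene flow yields
  an average date (two-pulse fits partially relax this).
* The f4-ratio requires the stated clade structure; violations bias the
  proportion, and the denominator guard only catches the degenerate case.
* The IBD matcher is error-intolerant by design (zero mismatches), so
  genotyping error fragments real segments; it is a stand-in for
  error-aware matchers, not a replacement.
* Two-pulse fits need the pulse ages separated by at least ~1.5x and a
  curve long enough to constrain the slow component; closely spaced pulses
  collapse to their average.
* Founder-event dates on populations that remained small after founding
  reflect the full distribution of coalescence times, not a single event.
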