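---
title: "Estimating the fetal DNA fraction from shallow-depth plasma sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the fetal DNA fraction from shallow-depth plasma sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmaFF)
```

## The measurement model

Cell-free DNA in a pregnant woman's plasma is a mixture of maternal and
fetal molecules; the fetal share is the *fetal DNA fraction* `F` (percent).
Consider a SNP where the mother is homozygous. Every plasma base sequenced
there should match her allele, except

* paternally inherited fetal alleles, at loci where the fetus is
  heterozygous, and
* sequencing or genotyping errors.

Let `pi` be the fraction of maternal-homozygous loci at which the fetus is
heterozygous for the other array allele, and let `epsilon` (percent) be the
baseline rate at which sequencing error produces a non-maternal base. A
fetus heterozygous at a locus transmits its non-maternal allele on half of
its molecules, so a plasma base drawn at a random panel locus is
non-maternal with probability

    E[X] = pi * F / 2 + epsilon        (all terms in percent)

where `X` is the percentage of non-maternal bases pooled over the whole
panel. Inverting this relationship gives the calibration line that the
package fits by ordinary least squares:

    F_hat = a * X + b,   with population values  a = 2 / pi,  b = -a * epsilon.

Two assumptions carry all the weight: the error rate is (approximately)
constant across samples on a fixed platform, and the informative-locus rate
`pi` is a property of the genotyping array and the population rather than of
the individual sample. Both are platform-specific, which is why
`reference_model()` (slope 18.9, intercept -6.6) is shipped as a
convenience, not a universal constant: changing the array or the sequencer
requires retraining with `fit_ff_model()`.

Because `X` is a *pooled* ratio over ~2 million loci, the estimator remains
precise at very shallow depth: at 0.03-fold coverage a 1.94M-locus panel
still collects ~60,000 informative bases, and the binomial noise on `X`
translates (through the slope) into a sub-percent error on `F`.

## The gold standard

Accuracy is always judged against the fraction computed from known maternal
*and* fetal genotypes. At loci where the mother is homozygous (genotype AA)
and the fetus heterozygous (AB), with `p` the number of plasma bases
carrying the fetal-specific B allele and `q` the number carrying the shared
A allele,

    F = 2p / (p + q) * 100.

`compute_actual_fraction()` implements this; bases matching neither array
allele are ignored. This is the `F_actual` column that calibrations are
fitted against.

## Tunable parameters

| parameter | where | default | meaning |
|---|---|---|---|
| `min_base_quality` | `count_alleles()` | 20 | Phred floor per counted base |
| `min_mapq` | `count_alleles()` | 20 | mapping-quality floor per read |
| `dedup` | `count_alleles()` | `TRUE` | drop duplicate-flagged records |
| `include_sex_chroms` | `select_homozygous()` | `FALSE` | keep X/Y panel loci |
| `n_loci` | `sim_config()` | 1,940,000 | panel size |
| `pi_informative` | `sim_config()` | 2/18.9 | informative-locus probability |
| `epsilon_pct` | `sim_config()` | 6.6/18.9 | baseline error rate (%) |
| `coverage` | `sim_config()` | 4.5 | fold coverage (1M pairs = 0.032) |
| `reps` | `grid_evaluate()` | 20 | downsampling replicates per cell |

The quality thresholds deserve a comment: the method's linearity only
requires the error rate to be *constant*, not small, so the defaults (Q20 on
both axes) are deliberately mild. They suppress the worst alignment and
base-calling artefacts without discarding so much data that the
constant-error assumption starts depending on the sample's quality profile.
Counting rules: any A/C/G/T base differing from the maternal allele is
non-maternal (errors are folded into the intercept, so there is no reason to
restrict to the known alt allele); each aligned segment contributes at most
one base per locus; when both mates of a pair cover a locus, only the
higher-quality base is counted, so a single template molecule is never
counted twice; deletions, reference skips, `N` bases and sub-threshold bases
are tallied as discarded. Sex chromosomes are excluded from the panel by
default because chromosome-Y material in male-fetus pregnancies mimics the
non-maternal signal with a different, fetus-sex-dependent slope.

## What the synthetic generator emulates — and what it does not

Acceptance of this package cannot rest on the original cohort (the archived
sequencing data is access-controlled), so the package carries a generator,
`simulate_sample()` / `simulate_cohort()`, that realizes exactly the
measurement model above:

* **aggregate mode** draws the panel-wide base total
  `N ~ Poisson(n_loci * coverage)` and splits it multinomially into four
  disjoint categories: fetal-specific bases at informative loci
  (`pi * f/200`), shared maternal bases at informative loci
  (`pi * (1 - f/200)`), baseline-error non-maternal bases (`epsilon/100`)
  and ordinary maternal bases. The non-maternal total is then exactly
  `Binomial(N, pi * f/200 + epsilon/100)`, and the gold standard computed
  from the two informative categories is unbiased for the true fraction.
* **site_level mode** realizes the same per-base probabilities locus by
  locus (depth `Poisson(coverage)` per locus) and returns per-locus counts
  plus fetal genotypes, so the gold-standard path through
  `compute_actual_fraction()` is exercised. Error bases at non-informative
  loci hit the other array allele a third of the time; at informative loci
  they are booked as neither-allele bases (ignored by the gold standard),
  a simplification that biases `F_actual` there by at most
  `f * epsilon / 100` — about 0.04 percentage points at `f = 10`.
* **sam_emit mode** writes a SAM file, maternal and fetal VCFs and a panel
  TSV realizing a site-level draw, for end-to-end tests of the I/O and
  counting stack.

The defaults `pi = 2/18.9` and `epsilon = 6.6/18.9` percent are algebraic
back-derivations from the reference calibration — chosen so the simulated
population's true line is exactly `F = 18.9 X - 6.6` — not independently
measured biology. The default cohort preset (`"clearance_study"`) mirrors a
fetal-DNA clearance design: `ceiling(n/6)` predelivery-like samples with
`F ~ Uniform(8, 30)` percent and the remainder post-delivery-like with
`F ~ Uniform(0, 3)` percent, which gives calibration fits the wide dynamic
range (including near-zero) they need.

The generator deliberately omits GC bias, allele-specific copy-number
variation, locus-to-locus error-rate heterogeneity, fragment-size structure
and alignment artefacts. Tests passing on synthetic cohorts therefore
demonstrate the *statistical* correctness of the pipeline — counting,
calibration, cross-validation, downsampling arithmetic — under the method's
own model; they do not certify performance on real plasma libraries, where
the constant-error assumption must be re-validated per platform.

## Numerical and design choices

* **Empirical 95% CIs.** All "95% confidence intervals" of deviations are
  empirical 2.5th/97.5th percentiles with linear interpolation between
  order statistics (`stats::quantile()` type 7). No normality is assumed;
  with fewer than ~20 deviations a warning flags the interval as unstable.
* **Read downsampling.** With per-read data one would subsample templates;
  on aggregate counts the package thins each disjoint base category
  binomially with keep probability `n_target / n_available`, which has the
  same distribution when bases are independent — exactly the generator's
  regime. Restricting to a random locus subset is thinned the same way on
  aggregate samples (hypergeometric vs binomial differences are negligible
  at millions of loci).
* **Grid cells.** Deviations are pooled across all downsampling replicates
  of a cell before the percentiles are taken (pooling maximizes the sample
  behind the tail estimate); a cell whose target exceeds the available data
  is reported as missing rather than aborting the grid.
* **Cross-validation folds** come from one seeded shuffle followed by
  contiguous chunking; when `n` is not divisible by `k` the remainder goes
  one-per-fold from the first fold. Per-fold `r2` is the squared Pearson
  correlation of predicted versus actual fractions on the held-out fold.
* **Negative estimates** (possible for essentially fetus-free samples,
  since the intercept is negative) are returned as-is with a warning;
  `clip_zero = TRUE` floors them for end-user reports. Keeping the sign
  preserves the calibration diagnostics near `F = 0`.
* **Serialization.** Models round-trip through JSON with 17 significant
  digits, the shortest representation that reproduces IEEE doubles exactly.
* **Degenerate inputs** fail loudly: empty panels, zero counted bases,
  `p + q = 0`, all-equal training `X`, fold counts exceeding the sample
  count, and downsampling targets above the available data are all errors,
  not silent NAs.

## Problem sizes used by the shipped tests

The test suite and the acceptance script run entirely in aggregate or small
site-level configurations: cohorts of 23/47/70 samples on the full
1.94M-locus panel in aggregate mode (milliseconds per sample), site-level
panels of 2,000–50,000 loci, and SAM fixtures of tens to a few hundred
reads. These sizes make the whole suite run in well under a minute while
keeping every statistical check at the cohort sizes and depths the method
is designed for.

## Known limitations

* The calibration is platform-specific; the shipped reference line applies
  only to the array/sequencer combination it was trained on.
* Counting assumes biallelic SNVs; multi-allelic sites and indels are
  excluded at parse time rather than decomposed.
* The SAM/BAM counting path favours correctness over throughput (it walks
  CIGARs in R with per-template deduplication); for production-scale BAMs a
  pre-tabulated pileup TSV via `read_pileup_tsv()` is the intended route.
* Aggregate-mode downsampling inherits the independence assumption of
  binomial thinning; correlated bases (duplicated templates) would require
  the per-read path.
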