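# plasmaFF

Fetal DNA fraction estimation from **shallow-depth** whole-genome sequencing
of maternal plasma, for laboratories running (or studying) noninvasive
prenatal testing (NIPT). Plasma cell-free DNA of a pregnant woman is a
maternal/fetal mixture; the fetal share `F` gates the interpretation of
every plasma-based prenatal test, yet routine NIPT sequencing runs at
~0.03-fold genome coverage — far too shallow for per-locus genotype-based
estimators.

## The idea

At a SNP where the mother is homozygous, a plasma base that differs from her
allele is either a paternally inherited fetal allele or an error. Pooling
over a genome-wide panel of maternal-homozygous loci, the percentage of
non-maternal bases

```
X = 100 · (non-maternal bases) / (counted bases)
```

is linear in the fetal fraction: with `pi` the informative-locus rate of the
array and `epsilon` the constant platform error rate (both in the units
below), `E[X] = pi·F/2 + epsilon`, so an ordinary-least-squares calibration

```
F̂ = a·X + b        (a ≈ 2/pi,  b ≈ −a·epsilon)
```

fitted on samples with a known fraction turns `X` into an accurate estimate
even at 0.03×, because `X` pools millions of loci. The known fractions come
from the gold standard `F = 2p/(p+q) × 100`, computed where the mother is
homozygous (AA) and the fetus heterozygous (AB), with `p` the bases carrying
the fetal-specific B allele and `q` the shared A allele. A reference
calibration (`a = 18.9`, `b = −6.6`) is shipped as `reference_model()`; it
is platform-specific, so retrain for any other array/sequencer combination.

The package covers the full workflow: genotype/panel I/O (VCF, TSV),
SAM/BAM allele counting with quality filters and mate-overlap
deduplication, calibration fitting and prediction, k-fold cross-validation,
read/SNP downsampling, a sequencing-depth × SNP-count accuracy grid, and a
synthetic-data generator (`simulate_cohort()`) that emulates the method's
generative model so everything is testable without patient data.

## Worked example

Train on a deep-coverage synthetic cohort, then estimate 47 shallow
(1 million read pairs ≈ 0.032×) samples:

```r
library(plasmaFF)

train <- simulate_cohort(23, config = sim_config(coverage = 4.5), seed = 1)
model <- fit_ff_model(cohort_summary(train))
model
#> Fetal-fraction calibration: F_hat = 18.88 * X -6.583
#>   R^2 = 1.0000 on 23 training samples

valid <- simulate_cohort(47, config = sim_config(coverage = pairs_to_coverage(1e6)), seed = 2)
vs <- cohort_summary(valid, model = model)
head(vs[, c("sample_id", "f_true", "X", "F_hat")], 4)
#>   sample_id   f_true         X    F_hat
#> 1      S001 12.06741 0.9340747 11.05411
#> 2      S002 23.45223 1.6146931 23.90566
#> 3      S003 20.61318 1.4651838 21.08261
#> 4      S004 11.69714 0.9183165 10.75656

deviation_stats(vs$F_hat, vs$f_true)
#> Deviation statistics (n = 47)
#>   median |dev| = 0.453%  mean |dev| = 0.524%
#>   95% CI of deviations: [-1.400, 1.036]%
```

The fitted slope/intercept recover the population line of the simulated
world (18.9, −6.6); the median absolute error at 0.03× coverage is ~0.5
percentage points of fetal fraction. Sample `S001`'s `X = 0.934%` means
that of its ~63,000 counted panel bases, 0.934% were non-maternal, giving
`F̂ = 18.88·0.934 − 6.58 ≈ 11.1%` against a true 12.1%.

Applying the shipped reference calibration to a measured `X`:

```r
predict(reference_model(), X = 0.878)
#> [1] 9.9942
```

Real data enter through the same functions: `read_genotypes()` +
`select_homozygous()` build the panel from a maternal VCF, and
`count_alleles()` computes `X` from a coordinate-sorted BAM (or
`read_pileup_tsv()` from a pre-tabulated pileup). A command-line wrapper
with subcommands `panel | count | train | predict | simulate | evaluate`
is installed at `exec/plasmaff`.

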