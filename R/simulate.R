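# Synthetic-data generator. Emulates the generative structure the method
# assumes: a panel of maternal-homozygous SNPs, a fraction pi of which is
# informative (fetus heterozygous, carrying one non-maternal allele), plasma
# bases sampled at a given fold coverage, and a constant baseline
# non-maternal error rate epsilon. Under this model the expected
# non-maternal allele percentage is
#   E[X] = pi * f / 2 + epsilon   (percent, f = true fetal fraction in %),
# so the population calibration line is F = (2/pi) * (X - epsilon).

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is calibrated to
#' reproduce: a 1.94-million-locus maternal-homozygous panel and a
#' population whose calibration line is `F_hat = 18.9 X - 6.6`. The
#' informative-locus probability and baseline error rate are back-derived
#' from that line (`pi = 2/18.9`, `epsilon = 6.6/18.9` percent); they are
#' algebraic consequences of the published calibration, not independently
#' measured rates.
#'
#' @param n_loci panel size (default 1,940,000 loci).
#' @param pi_informative probability that a maternal-homozygous locus is
#'   informative, i.e. the fetus is heterozygous there (default `2/18.9`,
#'   about 0.10582).
#' @param epsilon_pct baseline non-maternal error rate, in percent of
#'   counted bases (default `6.6/18.9`, about 0.34921).
#' @param coverage mean fold coverage of the genome (default 4.5, roughly
#'   140 million read pairs; shallow NIPT-style runs are ~0.032, i.e. 1
#'   million pairs).
#' @param f_true_pct true fetal DNA fraction in percent (default 10).
#' @param seed RNG seed for the sample, or `NULL`.
#' @param mode `"aggregate"` (genome-wide base totals only; fast, used for
#'   cohort-level work), `"site_level"` (per-locus counts plus fetal
#'   genotypes), or `"sam_emit"` (writes SAM/VCF/TSV files realizing a
#'   site-level draw, for end-to-end I/O tests).
#' @return a list of class `ff_sim_config`.
#' @export
sim_config <- function(n_loci = 1940000, pi_informative = 2 / 18.9,
                       epsilon_pct = 6.6 / 18.9, coverage = 4.5,
                       f_true_pct = 10, seed = NULL,
                       mode = c("aggregate", "site_level", "sam_emit")) {
  mode <- match.arg(mode)
  cfg <- list(n_loci = n_loci, pi_informative = pi_informative,
              epsilon_pct = epsilon_pct, coverage = coverage,
              f_true_pct = f_true_pct, seed = seed, mode = mode)
  .validate_config(cfg)
  structure(cfg, class = "ff_sim_config")
}

.validate_config <- function(cfg) {
  with(cfg, {
    if (n_loci < 1) stopf("n_loci must be positive")
    if (pi_informative < 0 || pi_informative > 1) stopf("pi_informative must be in [0, 1]")
    if (epsilon_pct < 0) stopf("epsilon_pct must be non-negative")
    if (coverage <= 0) stopf("coverage must be positive")
    if (f_true_pct < 0 || f_true_pct > 100) stopf("f_true_pct must be in [0, 100]")
    p_b <- pi_informative * f_true_pct / 200
    p_a <- pi_informative * (1 - f_true_pct / 200)
    p_e <- epsilon_pct / 100
    if (p_b + p_a + p_e > 1) stopf("invalid config: base-category probabilities exceed 1")
  })
  invisible(cfg)
}

#' Simulate one plasma sample
#'
#' Draws the total number of bases landing on panel loci as
#' `N ~ Poisson(n_loci * coverage)` and splits it multinomially into four
#' disjoint categories: fetal-specific bases at informative loci
#' (probability `pi * f/200`), shared maternal bases at informative loci
#' (`pi * (1 - f/200)`), baseline-error non-maternal bases (`epsilon/100`),
#' and ordinary maternal bases (the remainder). The non-maternal total is
#' therefore `Binomial(N, pi * f/200 + epsilon/100)`, and the gold-standard
#' fraction computed from the informative-locus categories is unbiased for
#' the true fraction. `site_level` mode realizes the same per-base
#' probabilities locus by locus (depth `Poisson(coverage)` per locus) and
#' also returns fetal genotypes; `sam_emit` additionally writes SAM and VCF
#' files (see `out_dir`).
#'
#' @param config an [sim_config()] object.
#' @param sample_id identifier stored in the result.
#' @param out_dir output directory, used by `sam_emit` mode only.
#' @return a list of class `ff_sample`. Aggregate mode carries the category
#'   totals in `$bases`; `site_level` carries `$counts` (an `ff_counts`
#'   data frame) and `$fetal_genotypes`; `sam_emit` adds `$files` with paths
#'   to `plasma.sam`, `maternal.vcf`, `fetal.vcf` and `panel.tsv`.
#' @export
simulate_sample <- function(config, sample_id = "S1", out_dir = NULL) {
  .validate_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  switch(config$mode,
    aggregate = .simulate_aggregate(config, sample_id),
    site_level = .simulate_site_level(config, sample_id),
    sam_emit = .simulate_sam_emit(config, sample_id, out_dir))
}

.category_probs <- function(cfg) {
  f <- cfg$f_true_pct
  c(inf_fetal = cfg$pi_informative * f / 200,
    inf_shared = cfg$pi_informative * (1 - f / 200),
    err = cfg$epsilon_pct / 100)
}

.simulate_aggregate <- function(cfg, sample_id) {
  N <- rpois(1, cfg$n_loci * cfg$coverage)
  pr <- .category_probs(cfg)
  pr <- c(pr, maternal = 1 - sum(pr))
  bases <- if (N > 0) drop(rmultinom(1, N, pr)) else setNames(rep(0L, 4), names(pr))
  structure(list(
    sample_id = sample_id, mode = "aggregate", f_true = cfg$f_true_pct,
    n_loci = cfg$n_loci, coverage = cfg$coverage,
    n_pairs = coverage_to_pairs(cfg$coverage),
    bases = bases), class = "ff_sample")
}

.simulate_site_level <- function(cfg, sample_id) {
  n <- cfg$n_loci
  f <- cfg$f_true_pct
  e <- cfg$epsilon_pct / 100
  # alternate ref/alt pairs deterministically; positions spaced 1 kb
  refs <- rep(c("A", "C", "G", "T"), length.out = n)
  alts <- rep(c("G", "T", "A", "C"), length.out = n)
  chrom <- rep("1", n)
  pos <- seq_len(n) * 1000L
  maternal_is_ref <- runif(n) < 0.5
  maternal <- ifelse(maternal_is_ref, refs, alts)
  informative <- runif(n) < cfg$pi_informative
  depth <- rpois(n, cfg$coverage)
  # informative loci: fetal-specific base w.p. f/200, error base w.p. e
  n_fetal <- integer(n)
  n_fetal[informative] <- rbinom(sum(informative), depth[informative], f / 200)
  rest <- depth - n_fetal
  n_err <- rbinom(n, rest, e / (1 - ifelse(informative, f / 200, 0)))
  # error bases: at informative loci they are assigned to the two bases that
  # are neither array allele; elsewhere one third hit the other array allele
  n_other_err <- integer(n)
  n_other_err[!informative] <- rbinom(sum(!informative), n_err[!informative], 1 / 3)
  n_other <- n_fetal + n_other_err
  counts <- data.frame(
    chrom = chrom, pos = pos, ref = refs, alt = alts,
    maternal_allele = maternal,
    n_maternal = depth - n_fetal - n_err,
    n_nonmaternal = n_fetal + n_err,
    n_other = n_other,
    n_discarded = 0L, stringsAsFactors = FALSE)
  class(counts) <- c("ff_counts", "data.frame")
  fetal_geno <- data.frame(
    chrom = chrom, pos = pos, ref = refs, alt = alts,
    genotype = ifelse(informative, "AB",
                      ifelse(maternal_is_ref, "AA", "BB")),
    alt_freq = NA_real_, stringsAsFactors = FALSE)
  class(fetal_geno) <- c("ff_genotypes", "data.frame")
  structure(list(
    sample_id = sample_id, mode = "site_level", f_true = f,
    n_loci = n, coverage = cfg$coverage,
    n_pairs = coverage_to_pairs(cfg$coverage),
    counts = counts, fetal_genotypes = fetal_geno,
    informative = informative), class = "ff_sample")
}

.simulate_sam_emit <- function(cfg, sample_id, out_dir) {
  if (is.null(out_dir)) stopf("sam_emit mode requires out_dir")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  site_cfg <- cfg
  site_cfg$mode <- "site_level"
  site_cfg$seed <- NULL # RNG already seeded by simulate_sample()
  s <- .simulate_site_level(site_cfg, sample_id)
  cn <- s$counts
  read_len <- 50L
  chrom_len <- max(cn$pos) + 1000L

  sam_path <- file.path(out_dir, "plasma.sam")
  con <- file(sam_path, "w")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:chr%s\tLN:%d", "1", chrom_len)), con)
  qual <- strrep("I", read_len)
  rid <- 0L
  for (i in seq_len(nrow(cn))) {
    d <- cn$n_maternal[i] + cn$n_nonmaternal[i]
    if (d == 0) next
    other <- if (cn$maternal_allele[i] == cn$ref[i]) cn$alt[i] else cn$ref[i]
    third <- setdiff(.base_set, c(cn$maternal_allele[i], other))[1]
    bases <- c(rep(cn$maternal_allele[i], cn$n_maternal[i]),
               rep(other, cn$n_other[i]),
               rep(third, cn$n_nonmaternal[i] - cn$n_other[i]))
    offsets <- sample.int(read_len, d, replace = TRUE) - 1L
    starts <- pmax(1L, cn$pos[i] - offsets)
    for (k in seq_len(d)) {
      rid <- rid + 1L
      seq <- strrep("A", read_len)
      substr(seq, cn$pos[i] - starts[k] + 1L, cn$pos[i] - starts[k] + 1L) <- bases[k]
      writeLines(sprintf("r%06d\t0\tchr1\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                         rid, starts[k], read_len, seq, qual), con)
    }
  }
  close(con)

  maternal_geno <- data.frame(
    chrom = cn$chrom, pos = cn$pos, ref = cn$ref, alt = cn$alt,
    genotype = ifelse(cn$maternal_allele == cn$ref, "AA", "BB"),
    stringsAsFactors = FALSE)
  maternal_vcf <- file.path(out_dir, "maternal.vcf")
  fetal_vcf <- file.path(out_dir, "fetal.vcf")
  .write_vcf(maternal_geno, maternal_vcf, sample_name = "MOTHER")
  .write_vcf(s$fetal_genotypes, fetal_vcf, sample_name = "FETUS")
  panel_path <- file.path(out_dir, "panel.tsv")
  write_panel(select_homozygous(read_genotypes(maternal_vcf, "vcf")), panel_path)

  s$files <- list(sam = sam_path, maternal_vcf = maternal_vcf,
                  fetal_vcf = fetal_vcf, panel = panel_path)
  s$mode <- "sam_emit"
  s
}

# Minimal single-sample VCF writer used by the simulator.
.write_vcf <- function(geno, path, sample_name = "SAMPLE") {
  gt <- c(AA = "0/0", AB = "0/1", BB = "1/1", missing = "./.")[geno$genotype]
  chrom <- ifelse(grepl("^chr", geno$chrom), geno$chrom, paste0("chr", geno$chrom))
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_name),
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
            chrom, geno$pos, geno$ref, geno$alt, gt))
  writeLines(lines, path)
  invisible(path)
}

#' @exportS3Method print ff_sample
print.ff_sample <- function(x, ...) {
  cat(sprintf("Simulated plasma sample %s (%s mode)\n  true F = %.3f%%, %s loci, coverage %.4gx\n",
      x$sample_id, x$mode, x$f_true, format(x$n_loci, big.mark = ","), x$coverage))
  invisible(x)
}

#' @export
summarize_nonmaternal.ff_sample <- function(x, ...) {
  if (x$mode == "aggregate") {
    total <- sum(x$bases)
    if (total == 0) stopf("no counted bases; cannot compute the non-maternal fraction")
    nonmat <- x$bases[["inf_fetal"]] + x$bases[["err"]]
    return(.new_summary(total, nonmat, NA_integer_))
  }
  summarize_nonmaternal(x$counts)
}

#' @export
compute_actual_fraction.ff_sample <- function(x, fetal_genotypes = NULL, ...) {
  if (x$mode == "aggregate") {
    p <- x$bases[["inf_fetal"]]
    q <- x$bases[["inf_shared"]]
    if (p + q == 0) stopf("no informative bases (p + q = 0); cannot compute the actual fraction")
    return(structure(list(p = p, q = q, F = 200 * p / (p + q),
                          n_informative = NA_integer_), class = "ff_actual"))
  }
  if (is.null(fetal_genotypes)) fetal_genotypes <- x$fetal_genotypes
  compute_actual_fraction(x$counts, fetal_genotypes)
}

#' Simulate a cohort of plasma samples
#'
#' The default `"clearance_study"` preset mirrors a fetal-DNA clearance
#' cohort that mixes pregnant (predelivery) samples with serial
#' post-delivery samples: `ceiling(n/6)` samples draw their true fraction
#' from Uniform(8, 30) percent and the remainder from Uniform(0, 3) percent,
#' giving the wide fraction range (including near-zero) a calibration needs.
#' Per-sample seeds are derived deterministically from `seed`.
#'
#' @param n_samples number of samples.
#' @param f either a preset name (currently `"clearance_study"`) or an
#'   explicit numeric vector of `n_samples` true fractions in percent.
#' @param config an [sim_config()] used as the template for every sample
#'   (its `f_true_pct` and `seed` are overridden per sample).
#' @param seed cohort seed.
#' @return a list of `ff_sample` objects, of class `ff_cohort`.
#' @export
simulate_cohort <- function(n_samples, f = "clearance_study",
                            config = sim_config(), seed = 1) {
  set.seed(seed)
  if (is.character(f)) {
    if (!identical(f, "clearance_study")) stopf("unknown fraction preset: %s", f)
    n_high <- ceiling(n_samples / 6)
    f <- c(runif(n_high, 8, 30), runif(n_samples - n_high, 0, 3))
  }
  if (length(f) != n_samples) stopf("f must have one true fraction per sample")
  seeds <- sample.int(.Machine$integer.max, n_samples)
  samples <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    cfg_i <- config
    cfg_i$f_true_pct <- f[i]
    cfg_i$seed <- seeds[i]
    samples[[i]] <- simulate_sample(cfg_i, sample_id = sprintf("S%03d", i))
  }
  structure(samples, class = "ff_cohort", seed = seed)
}

#' Per-sample summary table for a cohort
#'
#' Computes, for every sample, the non-maternal allele percentage `X`, the
#' gold-standard fraction `F_actual` (from the simulated informative-locus
#' counts), the true fraction used by the generator, and optionally the
#' model estimate `F_hat`.
#'
#' @param cohort an `ff_cohort` (or plain list of `ff_sample`s).
#' @param model optional `ff_model` used to add an `F_hat` column.
#' @return a data frame with columns `sample_id`, `f_true`, `total_bases`,
#'   `X`, `F_actual` and (if `model` is given) `F_hat`.
#' @export
cohort_summary <- function(cohort, model = NULL) {
  rows <- lapply(cohort, function(s) {
    sm <- summarize_nonmaternal(s)
    fa <- tryCatch(compute_actual_fraction(s)$F, error = function(e) NA_real_)
    data.frame(sample_id = s$sample_id, f_true = s$f_true,
               total_bases = sm$total_bases, X = sm$X, F_actual = fa,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(model)) out$F_hat <- suppressWarnings(predict(model, out$X))
  rownames(out) <- NULL
  out
}
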