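# Evaluation machinery: deviation summaries with empirical 95% confidence
# intervals, k-fold cross-validation of the calibration, read- and
# SNP-downsampling, and the depth x SNP-count accuracy grid.

#' Deviation statistics with an empirical 95% confidence interval
#'
#' Deviations are `F_hat - F_actual` in percent. The 95% interval is the
#' empirical 2.5th and 97.5th percentile of the signed deviations, computed
#' with linear interpolation between order statistics ([stats::quantile()]
#' type 7); no distributional assumption is made.
#'
#' @param f_hat numeric vector of estimated fractions (percent), or a
#'   2-column data frame / matrix of `(F_hat, F_actual)` pairs.
#' @param f_actual numeric vector of actual fractions (ignored when `f_hat`
#'   is two-column).
#' @return a list of class `ff_devstats` with `deviations`,
#'   `median_abs_dev`, `mean_abs_dev`, `ci_low`, `ci_high` and `n`.
#' @export
deviation_stats <- function(f_hat, f_actual = NULL) {
  if (is.data.frame(f_hat) || is.matrix(f_hat)) {
    f_actual <- f_hat[, 2]
    f_hat <- f_hat[, 1]
  }
  if (length(f_hat) == 0) stopf("no (F_hat, F_actual) pairs supplied")
  if (length(f_hat) != length(f_actual)) stopf("F_hat and F_actual lengths differ")
  dev <- as.numeric(f_hat) - as.numeric(f_actual)
  if (length(dev) < 20) {
    warnf("only %d pair(s): the empirical 95%% CI is unstable below ~20", length(dev))
  }
  ci <- quantile(dev, c(0.025, 0.975), type = 7, names = FALSE)
  structure(list(
    deviations = dev,
    median_abs_dev = median(abs(dev)),
    mean_abs_dev = mean(abs(dev)),
    ci_low = ci[1], ci_high = ci[2], n = length(dev)),
    class = "ff_devstats")
}

#' @exportS3Method print ff_devstats
print.ff_devstats <- function(x, ...) {
  cat(sprintf(
    "Deviation statistics (n = %d)\n  median |dev| = %.3f%%  mean |dev| = %.3f%%\n  95%% CI of deviations: [%.3f, %.3f]%%\n",
    x$n, x$median_abs_dev, x$mean_abs_dev, x$ci_low, x$ci_high))
  invisible(x)
}

#' k-fold cross-validation of the calibration line
#'
#' Samples are shuffled once (seeded) and split into `k` contiguous chunks;
#' when `n` is not divisible by `k` the remainder is distributed one per
#' fold starting from the first. Each fold in turn is held out, the
#' calibration is fitted on the rest, and held-out samples are predicted.
#' The per-fold `r2` is the squared Pearson correlation between predicted
#' and actual fractions on the validation fold.
#'
#' @param samples data frame with columns `X` and `F_actual` (e.g. from
#'   [cohort_summary()]).
#' @param k number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @return a list of class `ff_cv`: `folds` (per-fold data frame with
#'   `slope`, `intercept`, `r2`, `median_abs_dev`, `mean_abs_dev`, `ci_low`,
#'   `ci_high`), `assignments`, pooled held-out `deviations`, `mean_r2`,
#'   `mean_abs_dev` (mean of pooled absolute deviations),
#'   `median_abs_dev`, `mean_slope` and `mean_intercept`.
#' @export
kfold_cv <- function(samples, k = 5, seed = 1) {
  n <- nrow(samples)
  if (k < 2) stopf("k must be at least 2")
  if (k > n) stopf("k = %d exceeds the number of samples (%d)", k, n)
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k)
  rem <- n %% k
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  fold_of <- integer(n)
  fold_of[perm] <- rep(seq_len(k), times = sizes)

  fold_rows <- vector("list", k)
  pooled_dev <- numeric(0)
  for (fd in seq_len(k)) {
    val <- samples[fold_of == fd, , drop = FALSE]
    trn <- samples[fold_of != fd, , drop = FALSE]
    m <- fit_ff_model(trn)
    pred <- suppressWarnings(predict(m, val$X))
    dev <- pred - val$F_actual
    pooled_dev <- c(pooled_dev, dev)
    r2 <- if (nrow(val) >= 2) cor(pred, val$F_actual)^2 else NA_real_
    ci <- if (nrow(val) >= 2) {
      quantile(dev, c(0.025, 0.975), type = 7, names = FALSE)
    } else {
      warnf("fold %d has a single sample; CI suppressed", fd)
      c(NA_real_, NA_real_)
    }
    fold_rows[[fd]] <- data.frame(
      fold = fd, n_validation = nrow(val), slope = m$slope,
      intercept = m$intercept, r2 = r2,
      median_abs_dev = median(abs(dev)), mean_abs_dev = mean(abs(dev)),
      ci_low = ci[1], ci_high = ci[2])
  }
  folds <- do.call(rbind, fold_rows)
  structure(list(
    k = k, folds = folds, assignments = fold_of, deviations = pooled_dev,
    mean_r2 = mean(folds$r2, na.rm = TRUE),
    mean_abs_dev = mean(abs(pooled_dev)),
    median_abs_dev = median(abs(pooled_dev)),
    mean_slope = mean(folds$slope),
    mean_intercept = mean(folds$intercept)),
    class = "ff_cv")
}

#' @exportS3Method print ff_cv
print.ff_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n  mean R^2 = %.4f\n  mean |dev| = %.3f%%  median |dev| = %.3f%%\n  mean slope = %.3f  mean intercept = %.3f\n",
      x$k, x$mean_r2, x$mean_abs_dev, x$median_abs_dev,
      x$mean_slope, x$mean_intercept))
  invisible(x)
}

#' Downsample a sample to a target number of read pairs
#'
#' On aggregate samples the per-category base totals are binomially thinned
#' with keep probability `n_pairs / n_pairs_available`, which is
#' statistically equivalent to drawing a uniform subset of read pairs when
#' bases are independent. On site-level samples every per-locus count is
#' thinned the same way.
#'
#' @param x an `ff_sample`.
#' @param n_pairs target read-pair count; must not exceed what the sample
#'   represents (`coverage * 3.1e9 / 100` pairs).
#' @param seed optional seed.
#' @param ... unused.
#' @return a new `ff_sample` at the reduced depth.
#' @export
downsample_reads <- function(x, n_pairs, seed = NULL, ...) UseMethod("downsample_reads")

#' @export
downsample_reads.ff_sample <- function(x, n_pairs, seed = NULL, ...) {
  if (n_pairs > x$n_pairs) {
    stopf("target of %.3g pairs exceeds the %.3g pairs available", n_pairs, x$n_pairs)
  }
  if (n_pairs == x$n_pairs) return(x)
  frac <- n_pairs / x$n_pairs
  if (!is.null(seed)) set.seed(seed)
  if (x$mode == "aggregate") {
    x$bases <- setNames(rbinom(length(x$bases), x$bases, frac), names(x$bases))
  } else {
    x$counts <- .thin_counts(x$counts, frac)
  }
  x$n_pairs <- n_pairs
  x$coverage <- x$coverage * frac
  x
}

# Thin the disjoint count categories of a per-locus table.
.thin_counts <- function(counts, frac) {
  n_other <- rbinom(nrow(counts), counts$n_other, frac)
  n_nonmat_rest <- rbinom(nrow(counts), counts$n_nonmaternal - counts$n_other, frac)
  counts$n_maternal <- rbinom(nrow(counts), counts$n_maternal, frac)
  counts$n_discarded <- rbinom(nrow(counts), counts$n_discarded, frac)
  counts$n_other <- n_other
  counts$n_nonmaternal <- n_other + n_nonmat_rest
  counts
}

#' Downsample the SNP panel
#'
#' Draws a uniform subset of loci without replacement. On an aggregate
#' sample, where individual loci are not tracked, restricting to a random
#' locus subset is realized as binomial thinning of the base totals with
#' keep probability `n_snps / n_loci` (the hypergeometric locus draw and
#' the binomial thinning agree to within negligible error at these scales).
#'
#' @param x an `ff_panel`, or an `ff_sample`.
#' @param n_snps target number of loci; must not exceed the panel size.
#' @param seed optional seed.
#' @param ... unused.
#' @return object of the same class as `x`, reduced to `n_snps` loci.
#' @export
downsample_snps <- function(x, n_snps, seed = NULL, ...) UseMethod("downsample_snps")

#' @export
downsample_snps.ff_panel <- function(x, n_snps, seed = NULL, ...) {
  if (n_snps > nrow(x)) stopf("target of %d loci exceeds the %d in the panel", n_snps, nrow(x))
  if (n_snps == nrow(x)) return(x)
  if (!is.null(seed)) set.seed(seed)
  keep <- sort(sample.int(nrow(x), n_snps))
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(x)
  out
}

#' @export
downsample_snps.ff_sample <- function(x, n_snps, seed = NULL, ...) {
  if (n_snps > x$n_loci) stopf("target of %d loci exceeds the %d in the sample", n_snps, x$n_loci)
  if (n_snps == x$n_loci) return(x)
  if (!is.null(seed)) set.seed(seed)
  if (x$mode == "aggregate") {
    frac <- n_snps / x$n_loci
    x$bases <- setNames(rbinom(length(x$bases), x$bases, frac), names(x$bases))
  } else {
    keep <- sort(sample.int(x$n_loci, n_snps))
    x$counts <- x$counts[keep, , drop = FALSE]
    x$fetal_genotypes <- x$fetal_genotypes[keep, , drop = FALSE]
    x$informative <- x$informative[keep]
    rownames(x$counts) <- rownames(x$fetal_genotypes) <- NULL
  }
  x$n_loci <- n_snps
  x
}

#' Depth x SNP-count accuracy grid
#'
#' For every combination of a target read-pair count and a target panel
#' size, each cohort sample is downsampled on both axes and re-estimated
#' with `model`, and this is repeated `reps` times with fresh seeds.
#' Deviations from the true fraction are pooled across samples and
#' replicates before taking the empirical 95% CI, and the cell's accuracy
#' score is half the CI width.
#'
#' @param cohort an `ff_cohort` of simulated samples at full depth.
#' @param model an `ff_model` used for prediction.
#' @param read_grid numeric vector of read-pair targets.
#' @param snp_grid numeric vector of panel-size targets.
#' @param reps downsampling replicates per cell (default 20).
#' @param seed master seed; per-(cell, rep, sample) seeds are derived from
#'   it deterministically.
#' @return a data frame of class `ff_grid` with one row per cell:
#'   `n_reads`, `n_snps`, `ci_half_width`, `ci_low`, `ci_high`,
#'   `median_abs_dev`, `n_deviations`. Infeasible cells (a target exceeding
#'   what a sample holds) get `NA` statistics and a warning, and the run
#'   continues.
#' @export
grid_evaluate <- function(cohort, model, read_grid, snp_grid, reps = 20, seed = 1) {
  if (length(read_grid) == 0 || length(snp_grid) == 0) stopf("grids must be non-empty")
  if (reps < 1) stopf("reps must be at least 1")
  cells <- expand.grid(n_reads = read_grid, n_snps = snp_grid,
                       KEEP.OUT.ATTRS = FALSE)
  seeds <- matrix(derive_seeds(seed, nrow(cells) * reps), nrow = nrow(cells))
  rows <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    n_reads <- cells$n_reads[ci]
    n_snps <- cells$n_snps[ci]
    feasible <- all(vapply(cohort, function(s) {
      n_reads <= s$n_pairs && n_snps <= s$n_loci
    }, logical(1)))
    if (!feasible) {
      warnf("grid cell (%.3g reads, %.3g SNPs) exceeds the available data; marked missing",
            n_reads, n_snps)
      rows[[ci]] <- data.frame(n_reads = n_reads, n_snps = n_snps,
        ci_half_width = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        median_abs_dev = NA_real_, n_deviations = 0L)
      next
    }
    devs <- numeric(0)
    for (r in seq_len(reps)) {
      set.seed(seeds[ci, r])
      for (s in cohort) {
        s2 <- downsample_snps(downsample_reads(s, n_reads), n_snps)
        x_pct <- summarize_nonmaternal(s2)$X
        f_hat <- suppressWarnings(predict(model, x_pct))
        devs <- c(devs, f_hat - s$f_true)
      }
    }
    ci_b <- quantile(devs, c(0.025, 0.975), type = 7, names = FALSE)
    rows[[ci]] <- data.frame(n_reads = n_reads, n_snps = n_snps,
      ci_half_width = (ci_b[2] - ci_b[1]) / 2, ci_low = ci_b[1],
      ci_high = ci_b[2], median_abs_dev = median(abs(devs)),
      n_deviations = length(devs))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ff_grid", "data.frame")
  out
}

#' Heat-map of a depth x SNP accuracy grid
#'
#' @param x an `ff_grid` from [grid_evaluate()].
#' @param ... passed to [graphics::image()].
#' @exportS3Method plot ff_grid
plot.ff_grid <- function(x, ...) {
  reads <- sort(unique(x$n_reads))
  snps <- sort(unique(x$n_snps))
  z <- matrix(NA_real_, length(reads), length(snps))
  for (i in seq_len(nrow(x))) {
    z[match(x$n_reads[i], reads), match(x$n_snps[i], snps)] <- x$ci_half_width[i]
  }
  graphics::image(seq_along(reads), seq_along(snps), z, axes = FALSE,
    xlab = "read pairs", ylab = "SNPs",
    main = "95% CI half-width of deviations (%)", ...)
  graphics::axis(1, seq_along(reads), labels = format(reads, big.mark = ","))
  graphics::axis(2, seq_along(snps), labels = format(snps, big.mark = ","))
  for (i in seq_len(nrow(x))) {
    graphics::text(match(x$n_reads[i], reads), match(x$n_snps[i], snps),
                   sprintf("%.2f", x$ci_half_width[i]))
  }
  invisible(x)
}
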