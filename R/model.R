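# The linear calibration between the non-maternal allele percentage X and
# the fetal DNA fraction F: fitting, prediction, JSON serialization, and the
# shipped reference calibration.

#' Fit the fetal-fraction calibration line
#'
#' Ordinary least squares of the actual (gold-standard) fetal fraction on the
#' non-maternal allele percentage:
#' \deqn{\hat F = a \, X + b.}
#' The slope absorbs the informative-locus rate of the genotyping array and
#' the intercept absorbs the platform's constant non-maternal error rate,
#' which is why the calibration is platform-specific and must be retrained
#' when the sequencing or genotyping platform changes.
#'
#' @param samples a data frame with numeric columns `X` (percent non-maternal
#'   alleles) and `F_actual` (percent fetal DNA), one row per training
#'   sample; the output of [cohort_summary()] works directly.
#' @return an object of class `ff_model`: a list with `slope`, `intercept`,
#'   `r2`, `n_train`, and the OLS standard errors `slope_se`, `intercept_se`.
#' @examples
#' fit_ff_model(data.frame(X = c(0.5, 1, 1.5), F_actual = c(2.85, 12.3, 21.75)))
#' @export
fit_ff_model <- function(samples) {
  stopifnot(is.data.frame(samples))
  if (!all(c("X", "F_actual") %in% names(samples))) {
    stopf("training samples need columns X and F_actual")
  }
  ok <- is.finite(samples$X) & is.finite(samples$F_actual)
  samples <- samples[ok, , drop = FALSE]
  if (nrow(samples) < 2) stopf("at least 2 training samples are required")
  if (length(unique(samples$X)) < 2) stopf("degenerate training set: all X values are identical")
  fit <- lm(F_actual ~ X, data = samples)
  sm <- summary(fit)
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r2 = sm$r.squared,
    n_train = nrow(samples),
    slope_se = sm$coefficients["X", "Std. Error"],
    intercept_se = sm$coefficients["(Intercept)", "Std. Error"]),
    class = "ff_model")
}

#' Predict the fetal fraction from the non-maternal allele percentage
#'
#' Applies `F_hat = slope * X + intercept`. Estimates below zero can occur
#' for samples with essentially no fetal DNA (e.g. post-delivery plasma) and
#' are returned as-is with a warning so that calibration behaviour near zero
#' stays visible; set `clip_zero = TRUE` to floor them at 0 for reporting.
#'
#' @param object an `ff_model`.
#' @param X numeric vector of non-maternal allele percentages.
#' @param clip_zero floor negative estimates at zero (default `FALSE`).
#' @param ... unused.
#' @return numeric vector of estimated fetal fractions in percent.
#' @examples
#' predict(reference_model(), X = 0.878)
#' @export
predict.ff_model <- function(object, X, clip_zero = FALSE, ...) {
  stopifnot(is.numeric(X))
  if (any(X < 0, na.rm = TRUE)) stopf("X must be non-negative")
  f_hat <- object$slope * X + object$intercept
  if (any(f_hat < 0, na.rm = TRUE)) {
    if (clip_zero) {
      f_hat <- pmax(f_hat, 0)
    } else {
      warnf("%d estimate(s) below 0%%; the sample may contain no fetal DNA",
            sum(f_hat < 0, na.rm = TRUE))
    }
  }
  f_hat
}

#' @exportS3Method print ff_model
print.ff_model <- function(x, ...) {
  cat(sprintf("Fetal-fraction calibration: F_hat = %.4g * X %+.4g\n", x$slope, x$intercept))
  if (!is.null(x$r2) && is.finite(x$r2)) {
    cat(sprintf("  R^2 = %.4f on %d training samples\n", x$r2, x$n_train))
  }
  invisible(x)
}

#' The shipped reference calibration
#'
#' A calibration line of slope 18.9 and intercept -6.6 (percent fetal DNA
#' per percent non-maternal alleles), reported for a 23-sample training
#' cohort genotyped on an Illumina BeadChip array and sequenced on a HiSeq
#' 2000 in 50-cycle paired-end mode. It lets users apply the method without
#' their own training cohort, but being platform-specific it should be
#' retrained for any other genotyping array or sequencer.
#'
#' @return an `ff_model`.
#' @examples
#' predict(reference_model(), X = 1.0) # 12.3
#' @export
reference_model <- function() {
  structure(list(slope = 18.9, intercept = -6.6, r2 = 0.99, n_train = 23,
                 slope_se = NA_real_, intercept_se = NA_real_),
            class = "ff_model")
}

#' Save or load a calibration model as JSON
#'
#' All numeric fields round-trip at full double precision.
#'
#' @param model an `ff_model`.
#' @param path JSON file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns an
#'   `ff_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ff_model"))
  # 17 significant digits: the shortest representation that round-trips
  # IEEE doubles exactly
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stopf("cannot parse model file %s: %s", path, conditionMessage(e)))
  if (!is.list(obj) || !all(c("slope", "intercept") %in% names(obj)) ||
      !is.numeric(obj$slope) || !is.numeric(obj$intercept)) {
    stopf("%s is not a valid calibration model file", path)
  }
  defaults <- list(r2 = NA_real_, n_train = NA_integer_,
                   slope_se = NA_real_, intercept_se = NA_real_)
  obj <- modifyList(defaults, obj[!vapply(obj, is.null, logical(1))])
  structure(obj[c("slope", "intercept", "r2", "n_train", "slope_se", "intercept_se")],
            class = "ff_model")
}
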