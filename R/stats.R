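# Summary arithmetic for the quantification workflow: spike-in
# calibration linearity, replicate statistics and CVs, enrichment and
# normalization bookkeeping, method-comparison correlation, qPCR
# relative expression, and box-plot group summaries.

#' Build a calibration series
#'
#' @param levels Spike levels in fmol, strictly increasing.
#' @param ratios Measured area ratios (spiked heavy / endogenous
#'   light), one or more per level; either a vector parallel to
#'   `levels` or a list of replicate vectors.
#' @return A data frame with columns `level` and `ratio`.
#' @export
calibration_series <- function(levels, ratios) {
  stopifnot(all(diff(levels) > 0))
  if (is.list(ratios)) {
    stopifnot(length(ratios) == length(levels))
    data.frame(level = rep(levels, lengths(ratios)),
               ratio = unlist(ratios))
  } else {
    stopifnot(length(ratios) == length(levels))
    data.frame(level = levels, ratio = ratios)
  }
}

#' Fit spike-in calibration linearity
#'
#' Ordinary least squares of ratio against spike level, with the
#' Pearson correlation coefficient as the linearity figure of merit
#' (calibration curves in the low-fmol range should yield r of 0.997
#' or better).
#'
#' @param series A data frame from [calibration_series()] (columns
#'   `level`, `ratio`), fit on the raw points.
#' @return A list with `slope`, `intercept`, `r` (Pearson),
#'   `residuals`.
#' @export
fit_linearity <- function(series) {
  stopifnot(all(c("level", "ratio") %in% names(series)))
  if (length(unique(series$level)) < 3L)
    stop("need at least 3 distinct levels", call. = FALSE)
  fit <- stats::lm(ratio ~ level, data = series)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(series$level, series$ratio),
       residuals = unname(stats::residuals(fit)))
}

#' Replicate summary: mean, sample SD, CV
#'
#' @param values Numeric vector of replicate measurements.
#' @return A list with `n`, `mean`, `sd` (n-1 denominator; `NA` with a
#'   warning for n < 2) and `cv_percent` (100 * sd / mean).
#' @examples
#' replicate_summary(c(29.89, 24.95, 26.87))  # 27.23 +/- 2.49, CV 9.14%
#' @export
replicate_summary <- function(values) {
  n <- length(values)
  m <- mean(values)
  if (n < 2L) {
    warning("SD undefined for fewer than 2 values", call. = FALSE)
    s <- NA_real_
  } else {
    s <- stats::sd(values)
  }
  list(n = n, mean = m, sd = s,
       cv_percent = if (!is.na(s) && m > 0) 100 * s / m else NA_real_)
}

#' SD as a percentage of the mean
#'
#' @param sd Standard deviation.
#' @param mean Mean, positive.
#' @return `100 * sd / mean`.
#' @export
sd_percent_of_mean <- function(sd, mean) {
  if (mean <= 0) stop("mean must be positive", call. = FALSE)
  100 * sd / mean
}

#' Overall enrichment factor from depletion and recovery percentages
#'
#' In `"stated"` mode (the default), x percent depletion of
#' high-abundance proteins is equated with an x-fold enrichment of what
#' remains, and the overall factor is that fold scaled by the recovery
#' rate: 94.9% depletion at 97.6% recovery gives 92.62-fold. The
#' `"strict"` mode instead uses the dilution-factor form
#' `1 / (1 - depletion/100)`, which gives 19.61-fold at full recovery
#' of a 94.9% depletion; both are reported because the stated
#' equivalence is convenient bookkeeping rather than exact algebra.
#'
#' @param depletion_percent Depletion of high-abundance proteins, in
#'   `[0, 100]`.
#' @param recovery_percent Recovery of low-abundance proteins, in
#'   `[0, 100]`.
#' @param mode `"stated"` or `"strict"`.
#' @return Fold enrichment. Infinite (with a warning) at 100%
#'   depletion in strict mode.
#' @export
enrichment_factor <- function(depletion_percent, recovery_percent,
                              mode = c("stated", "strict")) {
  mode <- match.arg(mode)
  stopifnot(depletion_percent >= 0, depletion_percent <= 100,
            recovery_percent >= 0, recovery_percent <= 100)
  base <- if (mode == "stated") depletion_percent
    else {
      if (depletion_percent == 100) {
        warning("100% depletion gives an infinite strict factor",
                call. = FALSE)
        Inf
      } else 1 / (1 - depletion_percent / 100)
    }
  base * recovery_percent / 100
}

#' Rescale a value by a normalization factor
#'
#' Divides by the factor (e.g. scaling an off-range chromatogram trace
#' by the fold-reduction of its dominant protein: 2000 mAU normalized
#' by 14.52 is 137.74 mAU).
#'
#' @param value Value to normalize.
#' @param factor Positive normalization factor.
#' @return `value / factor`.
#' @export
apply_normalization <- function(value, factor) {
  if (any(factor <= 0)) stop("factor must be positive", call. = FALSE)
  value / factor
}

#' Relative expression from qPCR Ct values
#'
#' `2^(Ct_reference - Ct_target)`: expression of the target gene
#' relative to a housekeeping gene.
#'
#' @param ct_target Ct of the target gene.
#' @param ct_reference Ct of the housekeeping gene.
#' @return Relative expression.
#' @export
delta_ct_expression <- function(ct_target, ct_reference) {
  stopifnot(all(ct_target > 0), all(ct_reference > 0))
  2^(ct_reference - ct_target)
}

#' Correlate two measurement methods
#'
#' Spearman (default) or Pearson correlation with a two-sided p-value,
#' for comparing concentrations measured by two techniques on the same
#' samples.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @param method `"spearman"` or `"pearson"`.
#' @return A list with `r`, `p_value`, `n`, `method`.
#' @export
compare_methods <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, alternative = "two.sided",
                    exact = FALSE))
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       method = method)
}

#' Box-plot group summary
#'
#' Median, lower/upper quartiles (linear interpolation, quantile
#' type 7), mean, sample SD and mean +/- SD whisker bounds — the
#' statistics drawn in a mean-and-SD-whisker box plot.
#'
#' @param values Numeric vector, n >= 1.
#' @param quantile_type Quantile convention passed to
#'   [stats::quantile()] (default 7).
#' @return A list with `n`, `median`, `q1`, `q3`, `mean`, `sd`,
#'   `whisker_low`, `whisker_high`. SD is `NA` for n = 1.
#' @export
group_stats <- function(values, quantile_type = 7) {
  n <- length(values)
  stopifnot(n >= 1L)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = quantile_type,
                       names = FALSE)
  s <- if (n >= 2L) stats::sd(values) else NA_real_
  m <- mean(values)
  list(n = n, median = q[2], q1 = q[1], q3 = q[3], mean = m, sd = s,
       whisker_low = m - s, whisker_high = m + s)
}
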