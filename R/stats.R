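## Statistical layer: per-subject Pearson correlation between thickness
## and intensity profiles, Fisher-Z cohort averaging, per-eccentricity
## coefficients of variation, Mann-Whitney cohort comparisons, and the
## cohort summary.

#' Pearson correlation between two profiles
#'
#' @param x,y Numeric vectors of equal length >= 3, both non-constant.
#' @return Sample Pearson product-moment correlation.
#' @export
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length vectors of length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  stats::cor(x, y)
}

#' Fisher-Z average of correlation coefficients
#'
#' Individual R values are converted to z with `atanh`, averaged, and
#' back-transformed with `tanh`; the squared back-transform is the cohort
#' R-squared. Values with |r| = 1 have infinite z and are excluded with a
#' warning.
#'
#' @param r_values Correlations with |r| <= 1 (|r| = 1 excluded).
#' @return List with `mean_r` and `r_squared`.
#' @export
#' @examples
#' fisher_average(c(0.5, 0.8)) # mean_r ~ 0.677
fisher_average <- function(r_values) {
  r_values <- r_values[!is.na(r_values)]
  degenerate <- abs(r_values) >= 1
  if (any(degenerate)) {
    warning(sprintf("excluding %d correlation(s) with |r| = 1 (infinite z)",
                    sum(degenerate)))
    r_values <- r_values[!degenerate]
  }
  if (length(r_values) == 0) stop("no usable correlations")
  mean_r <- tanh(mean(atanh(r_values)))
  list(mean_r = mean_r, r_squared = mean_r^2)
}

#' Coefficient of variation (percent)
#'
#' `100 * sd / mean` with the n-1 sample SD; a scale-free measure of the
#' between-subject variability at one eccentric ring.
#'
#' @param values At least two values with positive mean.
#' @return CoV in percent.
#' @export
#' @examples
#' coefficient_of_variation(c(8, 12)) # 28.28
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stop("need at least two values")
  m <- mean(values)
  if (m <= 0) stop("coefficient of variation requires a positive mean")
  100 * stats::sd(values) / m
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided rank-sum test with midrank ties. The p-value is exact
#' (full permutation distribution) when `n_a * n_b <= 400` and there are
#' no ties, and otherwise uses the normal approximation with tie and
#' continuity corrections.
#'
#' @param a,b Non-empty numeric samples.
#' @return List with `U` (for sample `a`) and two-sided `p`.
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4)) # U = 0, p = 1/3
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  exact <- length(a) * length(b) <= 400 && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Per-subject result
#'
#' Pairs a subject's thickness and intensity profiles on the canonical
#' grid with their Pearson correlation and its Fisher z. A constant
#' profile (undefined correlation) yields `r = NA` with a warning; such
#' subjects are excluded from Fisher averaging downstream, not silently
#' dropped.
#'
#' @param subject_id Identifier.
#' @param thickness An [ecc_profile()] of kind `"thickness"`.
#' @param intensity An [ecc_profile()] of kind `"intensity"`.
#' @return An object of class `subject_result`.
#' @export
subject_result <- function(subject_id, thickness, intensity) {
  stopifnot(inherits(thickness, "ecc_profile"),
            inherits(intensity, "ecc_profile"),
            thickness$kind == "thickness", intensity$kind == "intensity")
  r <- tryCatch(pearson_r(thickness$values, intensity$values),
                error = function(e) {
                  warning(sprintf("subject %s: %s", subject_id,
                                  conditionMessage(e)))
                  NA_real_
                })
  structure(list(subject_id = subject_id, thickness = thickness,
                 intensity = intensity, r = r,
                 z = if (is.na(r) || abs(r) >= 1) NA_real_ else atanh(r)),
            class = "subject_result")
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("<subject_result %s: r = %s>\n", x$subject_id,
              format(round(x$r, 4))))
  invisible(x)
}

#' Summarize a cohort
#'
#' Pools all subjects x eccentricities for medians and quartiles
#' (linear-interpolation quantile rule) of thickness and intensity,
#' computes the between-subject coefficient of variation of intensity at
#' each canonical eccentricity, and Fisher-averages the per-subject
#' correlations into the cohort R and R-squared.
#'
#' @param results List of [subject_result()]s (>= 2).
#' @param label Cohort label.
#' @return An object of class `cohort_summary`.
#' @export
summarize_cohort <- function(results, label = "cohort") {
  if (length(results) < 2) stop("need at least two subjects")
  grid <- canonical_grid()
  thick <- vapply(results, function(s) s$thickness$values,
                  numeric(length(grid)))
  intens <- vapply(results, function(s) s$intensity$values,
                   numeric(length(grid)))
  q3 <- function(x) unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  tq <- q3(as.numeric(thick))
  iq <- q3(as.numeric(intens))
  cov_by_ecc <- apply(intens, 1, coefficient_of_variation)
  r_values <- vapply(results, function(s) s$r, numeric(1))
  fisher <- fisher_average(r_values)
  structure(list(
    label = label,
    n_subjects = length(results),
    thickness_median = tq[2], thickness_q25 = tq[1], thickness_q75 = tq[3],
    intensity_median = iq[2], intensity_q25 = iq[1], intensity_q75 = iq[3],
    cov_by_eccentricity = stats::setNames(cov_by_ecc, format(grid)),
    subject_r = r_values,
    mean_r = fisher$mean_r,
    r_squared = fisher$r_squared),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary %s: n = %d>\n", x$label, x$n_subjects))
  cat(sprintf("  thickness median [q25, q75]: %.2f [%.2f, %.2f] px\n",
              x$thickness_median, x$thickness_q25, x$thickness_q75))
  cat(sprintf("  intensity median [q25, q75]: %.2f [%.2f, %.2f]\n",
              x$intensity_median, x$intensity_q25, x$intensity_q75))
  cat(sprintf("  Fisher-averaged R = %.3f (R^2 = %.3f)\n",
              x$mean_r, x$r_squared))
  invisible(x)
}
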