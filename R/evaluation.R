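#' Performance evaluation and group statistics
#'
#' Sensitivity and specificity of affecting/non-affecting calls against
#' experimental labels, with 95% confidence limits from the Wilson score
#' interval with continuity correction, plus the nonparametric statistics
#' used for group comparisons: Mann-Whitney, Fisher's exact test and
#' Spearman rank correlation.
#'
#' @name evaluation
NULL

#' Confusion counts of predictions against labels
#'
#' Variants with an `unavailable` prediction or an `unknown` label are
#' excluded from the counts and reported separately.
#'
#' @param predicted character vector of calls (`affecting`,
#'   `non_affecting`, `unavailable`).
#' @param labels character vector of ground-truth labels.
#' @return list with `tp`, `fn`, `tn`, `fp`, `n_excluded`.
#' @export
confusion <- function(predicted, labels) {
  stopifnot(length(predicted) == length(labels))
  use <- predicted %in% c("affecting", "non_affecting") &
         labels %in% c("affecting", "non_affecting")
  if (!any(labels %in% c("affecting", "non_affecting")))
    stop("no labelled variants to evaluate")
  p <- predicted[use]; l <- labels[use]
  list(tp = sum(p == "affecting" & l == "affecting"),
       fn = sum(p == "non_affecting" & l == "affecting"),
       tn = sum(p == "non_affecting" & l == "non_affecting"),
       fp = sum(p == "affecting" & l == "non_affecting"),
       n_excluded = sum(!use))
}

# half-up rounding (1.005 -> 1.01), as used for reported CI bounds
round_half_up <- function(x, digits = 2L) {
  floor(x * 10^digits + 0.5 + 1e-9) / 10^digits
}

#' Wilson score interval with continuity correction
#'
#' @param successes number of successes.
#' @param n number of trials (>= 1).
#' @param confidence confidence level, default 0.95.
#' @return numeric `c(lower, upper)`, clamped to 0..1.  Reported values
#'   are conventionally rounded half-up to 2 decimals (see
#'   [evaluate_calls()]); this function returns unrounded bounds.
#' @export
wilson_cc_interval <- function(successes, n, confidence = 0.95) {
  if (n < 1L) stop("n must be >= 1")
  stopifnot(successes >= 0, successes <= n)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / n; q <- 1 - p
  lower <- if (successes == 0) 0 else
    (2 * n * p + z^2 - 1 - z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * q + 1))) /
    (2 * (n + z^2))
  upper <- if (successes == n) 1 else
    (2 * n * p + z^2 + 1 + z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * q - 1))) /
    (2 * (n + z^2))
  c(max(0, lower), min(1, upper))
}

#' Evaluate calls: sensitivity/specificity with confidence limits
#'
#' @param predicted,labels as in [confusion()].
#' @param confidence confidence level for the Wilson intervals.
#' @return object of class `evaluation_result`: confusion counts,
#'   `sensitivity`, `specificity` (fractions), `ci_sensitivity`,
#'   `ci_specificity` (unrounded), and their 2-decimal reported forms
#'   `ci_sensitivity_reported`, `ci_specificity_reported`.
#' @export
evaluate_calls <- function(predicted, labels, confidence = 0.95) {
  cf <- confusion(predicted, labels)
  sens <- if (cf$tp + cf$fn > 0) cf$tp / (cf$tp + cf$fn) else NA_real_
  spec <- if (cf$tn + cf$fp > 0) cf$tn / (cf$tn + cf$fp) else NA_real_
  ci_se <- if (cf$tp + cf$fn > 0)
    wilson_cc_interval(cf$tp, cf$tp + cf$fn, confidence) else c(NA_real_, NA_real_)
  ci_sp <- if (cf$tn + cf$fp > 0)
    wilson_cc_interval(cf$tn, cf$tn + cf$fp, confidence) else c(NA_real_, NA_real_)
  structure(c(cf, list(
    sensitivity = sens, specificity = spec,
    ci_sensitivity = ci_se, ci_specificity = ci_sp,
    ci_sensitivity_reported = round_half_up(ci_se),
    ci_specificity_reported = round_half_up(ci_sp),
    confidence = confidence)), class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "<evaluation_result> tp=%d fn=%d tn=%d fp=%d (excluded %d)\n",
    x$tp, x$fn, x$tn, x$fp, x$n_excluded))
  cat(sprintf("  sensitivity %d%% CI %.2f-%.2f | specificity %d%% CI %.2f-%.2f\n",
              round(100 * x$sensitivity), x$ci_sensitivity_reported[1],
              x$ci_sensitivity_reported[2], round(100 * x$specificity),
              x$ci_specificity_reported[1], x$ci_specificity_reported[2]))
  invisible(x)
}

#' Mann-Whitney comparison of two value groups
#'
#' Exact enumeration (no ties, both groups of size <= 8) or the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param values_affecting,values_non_affecting numeric vectors with at
#'   least 2 values each.
#' @return list with `statistic` (U), `p_value`, `method`.
#' @export
compare_groups <- function(values_affecting, values_non_affecting) {
  a <- values_affecting; b <- values_non_affecting
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need at least 2 values")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && length(a) <= 8L && length(b) <= 8L
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p by summation of hypergeometric probabilities not exceeding
#' that of the observed table.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise.
#' @return two-sided p value.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (sum(counts) == 0) stop("all-zero table")
  stats::fisher.test(matrix(counts, nrow = 2, byrow = TRUE))$p.value
}

#' Spearman rank correlation with t-approximation p value
#'
#' Mid-rank rho; two-sided p from the t distribution with n - 2 degrees
#' of freedom (0 when |rho| = 1).
#'
#' @param x,y paired numeric vectors, n >= 4.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4L) stop("need at least 4 pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("constant input vector")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1 - 1e-12) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}
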