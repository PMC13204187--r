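# Per-feature effect estimation: class-balanced logistic odds ratios, Wald
# p-values, Benjamini-Hochberg FDR control, and volcano-table construction.

#' Class-balanced univariate logistic odds ratio
#'
#' Fits a single-predictor logistic regression with per-class weights
#' `n_total / (2 * n_class)` (so each class contributes half the effective
#' sample) and returns the odds ratio `exp(slope)` with a Wald p-value from
#' the weighted information matrix (dispersion fixed at 1). For a binary
#' predictor this weighting leaves the odds ratio equal to the 2x2
#' cross-product ratio.
#'
#' Degenerate inputs (zero-variance feature, single-class labels) return a
#' flagged record with missing estimates instead of raising, so batch runs
#' over hundreds of features stay alive.
#'
#' @param feature_values Numeric vector (missing values are dropped pairwise).
#' @param labels Binary vector (1 = positive).
#' @return List: `odds_ratio`, `p_value`, `flag` (`"ok"` or a reason).
#' @export
balanced_logistic_or <- function(feature_values, labels) {
  ok <- !is.na(feature_values) & !is.na(labels)
  x <- feature_values[ok]
  y <- labels[ok]
  if (length(unique(y)) < 2L)
    return(list(odds_ratio = NA_real_, p_value = NA_real_,
                flag = "single_class"))
  if (length(unique(x)) < 2L)
    return(list(odds_ratio = NA_real_, p_value = NA_real_,
                flag = "zero_variance"))
  n <- length(y)
  w <- ifelse(y == 1, n / (2 * sum(y == 1)), n / (2 * sum(y == 0)))
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::binomial(), weights = w))
  sm <- suppressWarnings(summary(fit, dispersion = 1))
  if (nrow(sm$coefficients) < 2L)
    return(list(odds_ratio = NA_real_, p_value = NA_real_,
                flag = "fit_failed"))
  slope <- sm$coefficients["x", "Estimate"]
  p <- sm$coefficients["x", "Pr(>|z|)"]
  list(odds_ratio = exp(slope), p_value = p, flag = "ok")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1 and order-preserving with the input indexing.
#'
#' @param p_values Numeric vector with entries in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Run the univariate screen over a feature matrix
#'
#' Applies [balanced_logistic_or()] per column, adjusts the p-values of the
#' testable features with [bh_adjust()] (flagged features are excluded from
#' the BH family), and declares significance at FDR-adjusted p < 0.05.
#' Continuous aggregates are analyzed on their raw scale; binning is a
#' modeling device, not an inferential one.
#'
#' @param x Feature data frame or matrix (numeric columns).
#' @param labels Binary vector (1 = positive).
#' @param alpha Significance level on the adjusted scale.
#' @return Data frame with one row per feature: `feature`, `odds_ratio`,
#'   `log2_or`, `p_value`, `p_adjusted`, `significant`, `flag`.
#' @export
run_univariate <- function(x, labels, alpha = 0.05) {
  x <- as.data.frame(x)
  res <- lapply(x, balanced_logistic_or, labels = labels)
  out <- data.frame(
    feature = names(x),
    odds_ratio = vapply(res, `[[`, numeric(1), "odds_ratio"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    flag = vapply(res, `[[`, character(1), "flag"),
    stringsAsFactors = FALSE, row.names = NULL)
  out$log2_or <- log2(out$odds_ratio)
  out$p_adjusted <- NA_real_
  testable <- out$flag == "ok" & !is.na(out$p_value)
  # p-values can underflow to 0 under complete separation; floor them so the
  # BH domain contract holds
  pv <- pmax(out$p_value[testable], .Machine$double.xmin)
  if (any(testable)) out$p_adjusted[testable] <- bh_adjust(pv)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out[, c("feature", "odds_ratio", "log2_or", "p_value", "p_adjusted",
          "significant", "flag")]
}

#' Volcano-plot table
#'
#' Rows of `(feature, log2_or, neg_log10_p_adjusted, effect_flag)` for
#' volcano plotting. A feature is flagged as a strong effect when
#' `|log2(OR)| >= 0.585` (odds ratio outside [0.67, 1.5]) and its
#' FDR-adjusted p-value is strictly below 0.05 (`-log10` threshold 1.3).
#'
#' @param results Output of [run_univariate()].
#' @param log2_or_threshold Effect-size threshold on the log2 scale
#'   (default `log2(1.5)`, i.e. 0.585 at 3 decimals, so an odds ratio of
#'   exactly 1.5 is flagged).
#' @param alpha Adjusted-p threshold.
#' @return Data frame.
#' @export
volcano_table <- function(results, log2_or_threshold = log2(1.5),
                          alpha = 0.05) {
  data.frame(
    feature = results$feature,
    log2_or = results$log2_or,
    neg_log10_p_adjusted = -log10(results$p_adjusted),
    effect_flag = !is.na(results$p_adjusted) & !is.na(results$log2_or) &
      abs(results$log2_or) >= log2_or_threshold & results$p_adjusted < alpha,
    stringsAsFactors = FALSE)
}

#' Univariate comparison of an arbitrary binary partition
#'
#' Re-runs the univariate screen with a caller-supplied binary partition as
#' the outcome — e.g. consensus false positives versus true negatives among
#' unlabeled patients, to ask whether the "errors" resemble cases.
#'
#' @param x Feature data frame.
#' @param partition_labels Binary vector (1/0); both cells must contain at
#'   least 2 members.
#' @param alpha Significance level.
#' @return Data frame as [run_univariate()].
#' @export
compare_partitions <- function(x, partition_labels, alpha = 0.05) {
  tab <- table(factor(partition_labels, levels = c(0, 1)))
  if (any(tab < 2L))
    stop("both partition cells must contain at least 2 members", call. = FALSE)
  run_univariate(x, partition_labels, alpha = alpha)
}
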