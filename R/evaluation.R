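# Evaluation primitives: repeated stratified CV plans, non-interpolated
# average precision, the metric suite, recall-binned precision-recall
# profiles, consensus misclassification, Venn overlaps, and the screening
# enrichment/workload arithmetic.

#' Repeated stratified k-fold cross-validation plan
#'
#' For each repetition, patients are partitioned into `k` validation folds
#' with class-stratified assignment: within each class the shuffled members
#' are dealt round-robin, so per-fold labeled-positive counts differ by at
#' most one.
#'
#' @param labels Binary vector (1 = labeled positive).
#' @param k Folds per repetition.
#' @param reps Repetitions.
#' @param seed Integer seed.
#' @return Object of class `cv_plan`: `assignments` (n x reps integer
#'   matrix of fold ids), `k`, `reps`, `seed`.
#' @export
make_repeated_stratified_folds <- function(labels, k = 10L, reps = 10L,
                                           seed = 1L) {
  n <- length(labels)
  if (sum(labels == 1) < k)
    stop("fewer labeled positives (", sum(labels == 1),
         ") than folds (", k, ")", call. = FALSE)
  set.seed(seed)
  assignments <- matrix(NA_integer_, nrow = n, ncol = reps)
  for (r in seq_len(reps)) {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      assignments[idx, r] <- rep_len(seq_len(k), length(idx))
    }
  }
  structure(list(assignments = assignments, k = as.integer(k),
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "cv_plan")
}

#' Non-interpolated average precision
#'
#' `AP = sum_n (R_n - R_{n-1}) * P_n` over descending unique score
#' thresholds — the weighted mean of precision at each threshold, with no
#' linear interpolation between operating points. Under heavy class
#' imbalance this avoids the optimistic bias of trapezoidal area under the
#' precision-recall curve.
#'
#' @param truth Binary vector (1 = positive).
#' @param scores Numeric scores.
#' @return AP in `[0, 1]`, or `NA` when `truth` is single-class.
#' @export
#' @examples
#' average_precision(c(1, 0, 1), c(0.9, 0.8, 0.7))  # 0.8333
average_precision <- function(truth, scores) {
  if (length(unique(truth)) < 2L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  truth <- truth[ord]
  scores <- scores[ord]
  cum_tp <- cumsum(truth == 1)
  cum_n <- seq_along(truth)
  # operating points sit at the last row of each tied-score block
  last_of_block <- c(scores[-1L] != scores[-length(scores)], TRUE)
  tp <- cum_tp[last_of_block]
  nn <- cum_n[last_of_block]
  precision <- tp / nn
  recall <- tp / sum(truth == 1)
  sum(diff(c(0, recall)) * precision)
}

#' Rank-based AUROC
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney U
#' statistic (midranks handle ties).
#'
#' @param truth Binary vector (1 = positive).
#' @param scores Numeric scores.
#' @return AUROC in `[0, 1]`, or `NA` when single-class.
#' @export
auroc <- function(truth, scores) {
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall operating points
#'
#' One `(recall, precision)` pair per unique score threshold (descending),
#' the raw points that [binned_pr_profile()] pools across runs.
#'
#' @param truth Binary vector.
#' @param scores Numeric scores.
#' @return Data frame with columns `threshold`, `recall`, `precision`.
#' @export
pr_curve_points <- function(truth, scores) {
  ord <- order(scores, decreasing = TRUE)
  truth <- truth[ord]
  scores <- scores[ord]
  cum_tp <- cumsum(truth == 1)
  cum_n <- seq_along(truth)
  last_of_block <- c(scores[-1L] != scores[-length(scores)], TRUE)
  data.frame(threshold = scores[last_of_block],
             recall = cum_tp[last_of_block] / max(1L, sum(truth == 1)),
             precision = cum_tp[last_of_block] / cum_n[last_of_block])
}

#' Metric suite for one validation run
#'
#' Threshold-free AP and AUROC plus precision, recall (sensitivity),
#' specificity and F1 at a fixed decision threshold (scores `>= threshold`
#' predict positive). Undefined ratios (0/0) are recorded as `NA` rather
#' than coerced to 0, and a single-class truth vector yields a fully
#' flagged record.
#'
#' @param truth Binary vector (1 = positive).
#' @param scores Numeric scores in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return Named list: `ap`, `auroc`, `precision`, `recall`, `specificity`,
#'   `f1`, `n_pos`, `n_neg`, `flag`.
#' @export
compute_metrics <- function(truth, scores,
                            threshold = .DEFAULT_DECISION_THRESHOLD) {
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  if (n_pos == 0L || n_neg == 0L)
    return(list(ap = NA_real_, auroc = NA_real_, precision = NA_real_,
                recall = NA_real_, specificity = NA_real_, f1 = NA_real_,
                n_pos = n_pos, n_neg = n_neg, flag = "single_class"))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- tp / (tp + fn)
  specificity <- tn / (tn + fp)
  f1 <- if (!is.na(precision) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(ap = average_precision(truth, scores),
       auroc = auroc(truth, scores),
       precision = precision, recall = recall, specificity = specificity,
       f1 = f1, n_pos = n_pos, n_neg = n_neg, flag = "ok")
}

#' Median and 95% percentile interval over validation runs
#'
#' Median plus the empirical 2.5th/97.5th percentiles (linear
#' interpolation) of the defined values; missing entries are excluded from
#' the order statistics.
#'
#' @param values Numeric vector of per-run metric values (may contain `NA`).
#' @return Named list `median`, `ci_low`, `ci_high`, `n_defined`.
#' @export
summarize_metric <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0L)
    stop("summarize_metric: no defined values", call. = FALSE)
  q <- stats::quantile(v, c(0.025, 0.5, 0.975), type = .QUANTILE_TYPE,
                       names = FALSE)
  list(median = q[2L], ci_low = q[1L], ci_high = q[3L],
       n_defined = length(v))
}

#' Recall-binned precision-recall profile
#'
#' Pools the raw precision-recall operating points of every run and
#' summarizes precision (median and interquartile range) within fixed
#' recall bins `[i*w, (i+1)*w)` (the last bin closed at 1), displaying the
#' true point distribution instead of an interpolated curve.
#'
#' @param pr_points Data frame with columns `recall`, `precision`, pooled
#'   over runs.
#' @param bin_width Recall bin width (default 0.1).
#' @return Data frame: `bin_low`, `bin_high`, `median_precision`, `q25`,
#'   `q75`, `n_points` (empty bins keep `n_points = 0` and `NA` summaries).
#' @export
binned_pr_profile <- function(pr_points, bin_width = 0.1) {
  n_bins <- ceiling(1 / bin_width)
  lows <- (seq_len(n_bins) - 1L) * bin_width
  out <- data.frame(bin_low = lows, bin_high = lows + bin_width,
                    median_precision = NA_real_, q25 = NA_real_,
                    q75 = NA_real_, n_points = 0L)
  for (i in seq_len(n_bins)) {
    hi_closed <- i == n_bins  # recall = 1 belongs to the last bin
    inb <- pr_points$recall >= out$bin_low[i] &
      (pr_points$recall < out$bin_high[i] |
         (hi_closed & pr_points$recall <= out$bin_high[i]))
    p <- pr_points$precision[inb]
    out$n_points[i] <- length(p)
    if (length(p) > 0L) {
      q <- stats::quantile(p, c(0.25, 0.5, 0.75), type = .QUANTILE_TYPE,
                           names = FALSE)
      out$q25[i] <- q[1L]; out$median_precision[i] <- q[2L]
      out$q75[i] <- q[3L]
    }
  }
  out
}

#' Consensus misclassification categories
#'
#' A patient is assigned a consensus predicted label when one outcome
#' occurs in strictly more than half of their validation evaluations;
#' exact ties are `unstable`. Crossing the consensus prediction with the
#' truth yields TP/FP/FN/TN — "frequently misclassified" patients are the
#' consensus FP and FN sets.
#'
#' @param predictions Data frame with columns `patient_id`, `truth`
#'   (0/1), `predicted` (0/1); one row per evaluation of a patient.
#' @return Data frame: `patient_id`, `truth`, `n_evaluations`,
#'   `n_predicted_positive`, `consensus_category`.
#' @export
consensus_classify <- function(predictions) {
  sp <- split(predictions, predictions$patient_id)
  out <- lapply(sp, function(d) {
    n <- nrow(d)
    npos <- sum(d$predicted == 1)
    truth <- d$truth[1L]
    cat <- if (npos * 2L == n) "unstable"
    else if (npos * 2L > n) { if (truth == 1) "TP" else "FP" }
    else { if (truth == 1) "FN" else "TN" }
    data.frame(patient_id = d$patient_id[1L], truth = truth,
               n_evaluations = n, n_predicted_positive = npos,
               consensus_category = cat, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Venn region counts across model variants
#'
#' For each consensus category, counts every intersection region of the
#' per-variant patient sets (which variants contain the patient), so the
#' regions partition the union.
#'
#' @param consensus_list Named list of [consensus_classify()] outputs, one
#'   per model variant, over the same patient universe.
#' @param category Consensus category to compare (e.g. `"FP"`).
#' @return Data frame: `region` (e.g. `"baseline&spy"`), `count`.
#' @export
venn_counts <- function(consensus_list, category) {
  universes <- lapply(consensus_list, function(d) sort(d$patient_id))
  if (length(unique(universes)) != 1L)
    stop("consensus results cover different patient universes", call. = FALSE)
  sets <- lapply(consensus_list,
                 function(d) d$patient_id[d$consensus_category == category])
  union_ids <- unique(unlist(sets))
  if (length(union_ids) == 0L)
    return(data.frame(region = character(), count = integer()))
  membership <- vapply(sets, function(s) union_ids %in% s,
                       logical(length(union_ids)))
  membership <- matrix(membership, nrow = length(union_ids),
                       dimnames = list(NULL, names(consensus_list)))
  region <- apply(membership, 1L, function(m)
    paste(colnames(membership)[m], collapse = "&"))
  tab <- table(region)
  data.frame(region = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Case enrichment factor of a screen
#'
#' Precision divided by population prevalence (both in percent): how many
#' times denser true cases are among flagged patients than in the screened
#' population.
#'
#' @param precision_pct Model precision, percent.
#' @param prevalence_pct Population prevalence, percent (> 0).
#' @return The enrichment ratio.
#' @export
#' @examples
#' enrichment_factor(20.81, 0.061)  # ~341-fold
enrichment_factor <- function(precision_pct, prevalence_pct) {
  if (!is.finite(prevalence_pct) || prevalence_pct <= 0)
    stop("prevalence_pct must be positive", call. = FALSE)
  precision_pct / prevalence_pct
}

#' Physician-review workload estimate
#'
#' Review time in hours for the flagged patients, at a fixed per-patient
#' review time comparable to a standard outpatient visit.
#'
#' @param n_flagged Number of flagged patients (>= 0).
#' @param minutes_per_patient Review minutes per patient (default 15).
#' @return Hours of physician time.
#' @export
#' @examples
#' workload_estimate(15)  # 3.75 hours
workload_estimate <- function(n_flagged, minutes_per_patient = 15) {
  if (!is.finite(n_flagged) || n_flagged < 0)
    stop("n_flagged must be >= 0", call. = FALSE)
  n_flagged * minutes_per_patient / 60
}
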