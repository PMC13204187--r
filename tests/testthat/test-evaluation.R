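test_that("repeated stratified folds satisfy the plan invariants", {
  lab <- c(rep(1, 10), rep(0, 90))
  plan <- make_repeated_stratified_folds(lab, k = 10, reps = 10, seed = 1)
  # exactly one positive per fold, every rep
  for (r in 1:10) {
    pos_per_fold <- table(plan$assignments[lab == 1, r])
    expect_true(all(pos_per_fold == 1))
    # partition: every patient in exactly one fold
    expect_equal(sort(unique(plan$assignments[, r])), 1:10)
    expect_equal(length(plan$assignments[, r]), 100)
  }
  plan2 <- make_repeated_stratified_folds(lab, k = 10, reps = 10, seed = 1)
  expect_identical(plan, plan2)
  expect_error(make_repeated_stratified_folds(c(1, rep(0, 50)), k = 10),
               "fewer labeled positives")
})

test_that("fold invariants hold over a randomized design grid", {
  set.seed(6)
  for (i in 1:12) {
    n <- sample(30:300, 1)
    k <- sample(2:10, 1)
    reps <- sample(1:5, 1)
    npos <- sample(k:max(k, round(n / 4)), 1)
    lab <- sample(c(rep(1, npos), rep(0, n - npos)))
    plan <- make_repeated_stratified_folds(lab, k, reps, seed = i)
    for (r in seq_len(reps)) {
      f <- plan$assignments[, r]
      expect_true(all(f %in% seq_len(k)))
      pos_counts <- tabulate(f[lab == 1], nbins = k)
      expect_lte(max(pos_counts) - min(pos_counts), 1)
      neg_counts <- tabulate(f[lab == 0], nbins = k)
      expect_lte(max(neg_counts) - min(neg_counts), 1)
    }
  }
})

test_that("average precision matches the threshold-sweep oracle", {
  expect_equal(average_precision(c(1, 0, 1), c(0.9, 0.8, 0.7)), 5 / 6,
               tolerance = 1e-12)
  expect_equal(average_precision(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_true(is.na(average_precision(c(1, 1), c(0.5, 0.6))))
  set.seed(14)
  for (i in 1:100) {
    n <- sample(5:200, 1)
    truth <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c(0, 1)
    scores <- round(runif(n), sample(1:3, 1))  # force ties
    expect_equal(average_precision(truth, scores), oracle_ap(truth, scores),
                 tolerance = 1e-12)
  }
})

test_that("random scores give AP near prevalence", {
  set.seed(15)
  n <- 20000; pi_pos <- 0.2
  truth <- as.integer(runif(n) < pi_pos)
  ap <- average_precision(truth, runif(n))
  se <- sqrt(pi_pos * (1 - pi_pos) / n)
  expect_lt(abs(ap - pi_pos), 3 * se + 0.01)
})

test_that("AUROC equals the normalized Mann-Whitney statistic", {
  set.seed(16)
  for (i in 1:20) {
    n <- sample(10:150, 1)
    truth <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c(0, 1)
    scores <- round(runif(n), 2)
    w <- suppressWarnings(
      wilcox.test(scores[truth == 1], scores[truth == 0]))$statistic
    expect_equal(auroc(truth, scores),
                 unname(w) / (sum(truth == 1) * sum(truth == 0)),
                 tolerance = 1e-12)
  }
  # independent implementation cross-check
  set.seed(17)
  truth <- sample(c(0, 1), 300, replace = TRUE)
  scores <- rnorm(300, mean = truth)
  expect_equal(auroc(truth, scores),
               as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("compute_metrics applies the fixed threshold and 0/0 contract", {
  perfect <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2))
  expect_true(all(unlist(perfect[c("ap", "auroc", "precision", "recall",
                                   "specificity", "f1")]) == 1))
  allneg <- compute_metrics(c(1, 0, 0), c(0.1, 0.2, 0.3))
  expect_equal(allneg$recall, 0)
  expect_equal(allneg$specificity, 1)
  expect_true(is.na(allneg$precision))
  expect_true(is.na(allneg$f1))
  single <- compute_metrics(c(1, 1), c(0.4, 0.9))
  expect_equal(single$flag, "single_class")
  # thresholded counts agree with a direct confusion matrix
  truth <- c(1, 0, 1, 0, 0)
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.5)
  m <- compute_metrics(truth, scores, threshold = 0.5)
  pred <- as.integer(scores >= 0.5)
  expect_equal(m$precision, sum(pred & truth) / sum(pred))
  expect_equal(m$recall, sum(pred & truth) / sum(truth))
})

test_that("metric summaries use median and 2.5/97.5 percentiles", {
  s <- summarize_metric(1:100)
  expect_equal(s$median, 50.5)
  expect_equal(s$ci_low, 3.475)
  expect_equal(s$ci_high, 97.525)
  cc <- summarize_metric(rep(0.4, 10))
  expect_equal(c(cc$ci_low, cc$median, cc$ci_high), rep(0.4, 3))
  sm <- summarize_metric(c(1, NA, 3))
  expect_equal(sm$n_defined, 2)
  expect_equal(sm$median, 2)
  expect_error(summarize_metric(c(NA_real_, NA_real_)), "no defined")
})

test_that("recall-binned PR profile matches a group-by oracle", {
  pts <- data.frame(recall = c(0.15, 0.12), precision = c(0.8, 0.6))
  prof <- binned_pr_profile(pts)
  expect_equal(prof$median_precision[prof$bin_low == 0.1], 0.7)
  expect_equal(prof$n_points[prof$bin_low == 0.1], 2)
  expect_equal(sum(prof$n_points), 2)
  one <- binned_pr_profile(data.frame(recall = 0.55, precision = 0.3))
  row <- one[one$bin_low == 0.5, ]
  expect_equal(row$median_precision, 0.3)
  expect_equal(row$q25, row$q75)
  set.seed(18)
  pts2 <- data.frame(recall = runif(500), precision = runif(500))
  prof2 <- binned_pr_profile(pts2)
  for (i in seq_len(nrow(prof2))) {
    hi_closed <- i == nrow(prof2)
    inb <- pts2$recall >= prof2$bin_low[i] &
      (pts2$recall < prof2$bin_high[i] |
         (hi_closed & pts2$recall <= prof2$bin_high[i]))
    if (sum(inb) > 0) {
      expect_equal(prof2$median_precision[i], median(pts2$precision[inb]))
      expect_true(prof2$q25[i] <= prof2$median_precision[i] &&
                    prof2$median_precision[i] <= prof2$q75[i])
    } else {
      expect_equal(prof2$n_points[i], 0)
    }
  }
  expect_equal(sum(prof2$n_points), 500)
})

test_that("consensus categories follow the strict-majority rule", {
  mk <- function(id, truth, preds)
    data.frame(patient_id = id, truth = truth, predicted = preds)
  res <- consensus_classify(rbind(
    mk("a", 1, c(rep(1, 6), rep(0, 4))),   # majority positive, truth 1 -> TP
    mk("b", 1, c(rep(1, 5), rep(0, 5))),   # exact tie -> unstable
    mk("c", 1, rep(0, 10)),                # all negative, truth 1 -> FN
    mk("d", 0, rep(1, 7)),                 # FP
    mk("e", 0, c(0, 0, 1))))               # TN
  got <- setNames(res$consensus_category, res$patient_id)
  expect_equal(got[["a"]], "TP")
  expect_equal(got[["b"]], "unstable")
  expect_equal(got[["c"]], "FN")
  expect_equal(got[["d"]], "FP")
  expect_equal(got[["e"]], "TN")
})

test_that("venn regions partition each category union", {
  mk_cons <- function(ids, cat_ids) data.frame(
    patient_id = ids, truth = 0, n_evaluations = 10,
    n_predicted_positive = ifelse(ids %in% cat_ids, 10, 0),
    consensus_category = ifelse(ids %in% cat_ids, "FP", "TN"))
  ids <- sprintf("p%02d", 1:20)
  same <- list(a = mk_cons(ids, ids[1:5]), b = mk_cons(ids, ids[1:5]))
  v <- venn_counts(same, "FP")
  expect_equal(nrow(v), 1)
  expect_equal(v$region, "a&b")
  expect_equal(v$count, 5)
  dis <- list(a = mk_cons(ids, ids[1:3]), b = mk_cons(ids, ids[4:7]))
  vd <- venn_counts(dis, "FP")
  expect_setequal(vd$count[order(vd$region)], c(3, 4))
  expect_false("a&b" %in% vd$region)
  set.seed(19)
  rnd <- list(a = mk_cons(ids, sample(ids, 8)),
              b = mk_cons(ids, sample(ids, 6)),
              c = mk_cons(ids, sample(ids, 10)))
  vr <- venn_counts(rnd, "FP")
  union_size <- length(unique(unlist(lapply(rnd, function(d)
    d$patient_id[d$consensus_category == "FP"]))))
  expect_equal(sum(vr$count), union_size)
  bad <- list(a = mk_cons(ids, ids[1:2]), b = mk_cons(ids[1:10], ids[1:2]))
  expect_error(venn_counts(bad, "FP"), "universes")
})

test_that("enrichment and workload arithmetic", {
  expect_equal(enrichment_factor(20.81, 0.061), 20.81 / 0.061)
  expect_gt(enrichment_factor(20.81, 0.061), 340)
  expect_equal(enrichment_factor(0.061, 0.061), 1)
  expect_error(enrichment_factor(10, 0), "positive")
  expect_equal(workload_estimate(15), 3.75)
  expect_equal(workload_estimate(0), 0)
  expect_equal(workload_estimate(4), 1)
  expect_error(workload_estimate(-1), ">= 0")
})

test_that("run_cv is reproducible and fold-safe end to end", {
  co <- small_cohort(150, 15, seed = 61)
  ws <- build_windows(co, seed = 62)
  raw <- build_raw_features(ws, co$patients)
  r1 <- run_cv(raw, "baseline", adapter = "xgboost", k = 5, reps = 2,
               seed = 63)
  r2 <- run_cv(raw, "baseline", adapter = "xgboost", k = 5, reps = 2,
               seed = 63)
  expect_identical(r1$runs, r2$runs)
  expect_identical(r1$predictions, r2$predictions)
  # every window scored exactly reps times
  tab <- table(r1$predictions$patient_id)
  expect_true(all(tab == 2))
  expect_equal(nrow(r1$runs), 10)
  expect_true(all(r1$summary$ci_low <= r1$summary$median &
                    r1$summary$median <= r1$summary$ci_high))
  # PU variants run over the same plumbing (more positives so per-fold
  # calibration holdouts are not single patients)
  co2 <- small_cohort(150, 40, seed = 65)
  raw2 <- build_raw_features(build_windows(co2, seed = 66), co2$patients)
  ren <- run_cv(raw2, "elkan_noto", adapter = "glmnet", k = 5, reps = 1,
                seed = 64)
  expect_equal(nrow(ren$runs), 5)
  expect_true(all(ren$predictions$score >= 0 & ren$predictions$score <= 1))
})
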