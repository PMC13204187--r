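# Repeated-CV driver: ties feature engineering, PU wrappers and the metric
# suite together with a strict fold-safety contract - bin edges, prevalence
# filters and PU holdout/spy draws are all computed inside training folds.

# deterministic fan-out of one top-level seed into per-(rep, fold) substreams
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run repeated stratified cross-validation of a screening model
#'
#' For every repetition and fold: decile bin edges are fitted on the
#' training-fold controls, the prevalence filter is applied to training
#' rows, the chosen model variant (supervised baseline, Elkan-Noto, or spy)
#' is fitted on the training fold — with any PU holdout or spy draw taken
#' inside that fold — and validation rows are scored. Per-run metrics treat
#' unlabeled records as negatives (the only labels available), so in a PU
#' cohort they are approximations whose "false positives" may be latent
#' cases; [consensus_classify()] on the returned predictions is the tool
#' for interrogating exactly that.
#'
#' @param raw A `raw_features` object (see [build_raw_features()]).
#' @param variant `"baseline"`, `"elkan_noto"`, or `"spy"`.
#' @param adapter A `base_adapter` or adapter name (see [get_adapter()]).
#' @param k,reps Folds and repetitions.
#' @param threshold Decision threshold for thresholded metrics.
#' @param seed Top-level seed; every random draw in the run derives from it.
#' @param prevalence_threshold Passed to [prevalence_filter()].
#' @param holdout_frac,spy_frac,noise_tol PU wrapper parameters.
#' @param profile_mode `"pooled"` (pool PR points over runs, then bin) or
#'   `"per_run"` (bin each run, then aggregate the per-run medians).
#' @return Object of class `cv_report`: `runs` (per-run metric rows),
#'   `predictions` (patient x run scores), `summary` (median + 95%
#'   percentile interval per metric), `profile` (recall-binned PR),
#'   `consensus`, and the call parameters.
#' @export
run_cv <- function(raw, variant = c("baseline", "elkan_noto", "spy"),
                   adapter = "xgboost", k = 10L, reps = 10L,
                   threshold = .DEFAULT_DECISION_THRESHOLD, seed = 1L,
                   prevalence_threshold = .DEFAULT_PREVALENCE_THRESHOLD,
                   holdout_frac = .DEFAULT_HOLDOUT_FRAC,
                   spy_frac = .DEFAULT_SPY_FRAC,
                   noise_tol = .DEFAULT_NOISE_TOL,
                   profile_mode = c("pooled", "per_run")) {
  variant <- match.arg(variant)
  profile_mode <- match.arg(profile_mode)
  if (is.character(adapter)) adapter <- get_adapter(adapter)
  stopifnot(inherits(raw, "raw_features"), inherits(adapter, "base_adapter"))

  labels <- raw$label
  plan <- make_repeated_stratified_folds(labels, k = k, reps = reps,
                                         seed = seed)
  sub_seeds <- matrix(derive_seeds(seed + 1L, reps * k), nrow = reps)
  agg_cols <- raw$meta$column[raw$meta$kind == "aggregate"]

  runs <- vector("list", reps * k)
  preds <- vector("list", reps * k)
  pr_pts <- vector("list", reps * k)
  ri <- 0L
  for (r in seq_len(reps)) {
    fold_of <- plan$assignments[, r]
    for (f in seq_len(k)) {
      ri <- ri + 1L
      val <- which(fold_of == f)
      trn <- which(fold_of != f)
      # fold-safe feature engineering: bins on training controls only
      binning <- fit_bins(raw$x[trn[labels[trn] == 0], agg_cols, drop = FALSE])
      x_all <- apply_binning_model(raw$x, binning, columns = agg_cols)
      kept <- prevalence_filter(x_all[trn, , drop = FALSE], raw$meta,
                                labels[trn],
                                threshold = prevalence_threshold)
      x_trn <- x_all[trn, kept, drop = FALSE]
      x_val <- x_all[val, kept, drop = FALSE]
      wseed <- sub_seeds[r, f]
      scores <- switch(
        variant,
        baseline = {
          m <- fit_supervised(x_trn, labels[trn], adapter)
          predict(m, x_val)
        },
        elkan_noto = {
          m <- fit_elkan_noto(x_trn, labels[trn], adapter,
                              holdout_frac = holdout_frac, seed = wseed)
          predict_elkan_noto(m, x_val)
        },
        spy = {
          m <- fit_spy(x_trn, labels[trn], adapter, spy_frac = spy_frac,
                       noise_tol = noise_tol, seed = wseed)
          predict_spy(m, x_val)
        })
      truth <- labels[val]
      met <- compute_metrics(truth, scores, threshold = threshold)
      runs[[ri]] <- data.frame(rep = r, fold = f, ap = met$ap,
                               auroc = met$auroc, precision = met$precision,
                               recall = met$recall,
                               specificity = met$specificity, f1 = met$f1,
                               flag = met$flag, stringsAsFactors = FALSE)
      preds[[ri]] <- data.frame(patient_id = raw$patient_id[val], rep = r,
                                fold = f, score = scores,
                                predicted = as.integer(scores >= threshold),
                                truth = truth, stringsAsFactors = FALSE)
      pts <- pr_curve_points(truth, scores)
      pts$rep <- r; pts$fold <- f
      pr_pts[[ri]] <- pts
    }
  }
  runs <- do.call(rbind, runs)
  predictions <- do.call(rbind, preds)
  points <- do.call(rbind, pr_pts)

  metric_names <- c("ap", "auroc", "precision", "recall", "specificity", "f1")
  summ <- lapply(metric_names, function(m) {
    s <- summarize_metric(runs[[m]])
    data.frame(metric = m, median = s$median, ci_low = s$ci_low,
               ci_high = s$ci_high, n_defined = s$n_defined,
               n_missing = sum(is.na(runs[[m]])), stringsAsFactors = FALSE)
  })
  summ <- do.call(rbind, summ)

  profile <- if (profile_mode == "pooled") {
    binned_pr_profile(points)
  } else {
    per_run <- lapply(split(points, interaction(points$rep, points$fold,
                                                drop = TRUE)),
                      binned_pr_profile)
    pooled <- do.call(rbind, per_run)
    agg <- split(pooled, pooled$bin_low)
    do.call(rbind, lapply(agg, function(d) {
      data.frame(bin_low = d$bin_low[1L], bin_high = d$bin_high[1L],
                 median_precision = stats::median(d$median_precision,
                                                  na.rm = TRUE),
                 q25 = stats::median(d$q25, na.rm = TRUE),
                 q75 = stats::median(d$q75, na.rm = TRUE),
                 n_points = sum(d$n_points))
    }))
  }

  structure(list(runs = runs, predictions = predictions, summary = summ,
                 profile = profile,
                 consensus = consensus_classify(predictions),
                 variant = variant, adapter = adapter$name, k = k,
                 reps = reps, threshold = threshold, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s + %s adapter, %d x %d-fold CV (%d runs)\n",
              x$variant, x$adapter, x$reps, x$k, nrow(x$runs)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-11s median %6.4f  (95%% CI %6.4f-%6.4f, n=%d)\n",
                s$metric[i], s$median[i], s$ci_low[i], s$ci_high[i],
                s$n_defined[i]))
  invisible(x)
}

#' Write a cv_report's artifacts to disk
#'
#' Emits `runs.csv`, `predictions.csv`, `profile.csv`, `consensus.csv` and
#' `summary.json` under `dir`.
#'
#' @param report A `cv_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_cv_report <- function(report, dir) {
  stopifnot(inherits(report, "cv_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$runs, file.path(dir, "runs.csv"), row.names = FALSE)
  utils::write.csv(report$predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(report$profile, file.path(dir, "profile.csv"),
                   row.names = FALSE)
  utils::write.csv(report$consensus, file.path(dir, "consensus.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(variant = report$variant, adapter = report$adapter, k = report$k,
         reps = report$reps, threshold = report$threshold,
         seed = report$seed, summary = report$summary),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(dir)
}
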