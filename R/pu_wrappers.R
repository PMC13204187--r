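# Positive-unlabeled wrappers over a pluggable base learner: Elkan-Noto
# label-frequency calibration and spy-based reliable-negative mining.

#' Fit an Elkan-Noto calibrated PU model
#'
#' Under the selected-completely-at-random (SCAR) assumption, a classifier
#' trained to separate labeled positives from unlabeled records estimates
#' `P(s = 1 | x) = c * P(y = 1 | x)` where `c` is the labeling frequency
#' (the probability that a true positive is labeled). `c` is estimated as
#' the mean base-learner score over a held-out set of labeled positives
#' that never enter the base fit; calibrated probabilities are then
#' `min(1, score / c_hat)`.
#'
#' The base fit here is deliberately *unweighted*: class-balancing weights
#' rescale the posterior the learner estimates (to
#' `w1*c / (w1*c + w0*(1 - c))` in the positive region), which would bias
#' the holdout mean away from the labeling frequency the estimator exists
#' to recover. Balance is instead restored downstream by the calibration
#' itself.
#'
#' @param x Feature matrix/data frame (missing sentinel allowed).
#' @param s_labels Observed PU labels: 1 = labeled positive, 0 = unlabeled.
#' @param adapter A `base_adapter`.
#' @param holdout_frac Fraction of labeled positives held out for
#'   calibration (default 0.1).
#' @param seed Integer seed for the holdout draw.
#' @return Object of class `elkan_noto_model`: fitted `base`, `c_hat`,
#'   `holdout_ids` (row indices of held-out positives).
#' @export
fit_elkan_noto <- function(x, s_labels, adapter,
                           holdout_frac = .DEFAULT_HOLDOUT_FRAC, seed = 1L) {
  stopifnot(inherits(adapter, "base_adapter"))
  pos <- which(s_labels == 1)
  if (length(pos) < 10L)
    stop("fit_elkan_noto needs at least 10 labeled positives", call. = FALSE)
  set.seed(seed)
  n_hold <- max(1L, round(holdout_frac * length(pos)))
  holdout <- sort(sample(pos, n_hold))
  if (length(holdout) == 0L)
    stop("empty Elkan-Noto holdout", call. = FALSE)
  train <- setdiff(seq_along(s_labels), holdout)
  y <- s_labels[train]
  # unweighted on purpose: the holdout-mean estimator needs raw P(s=1|x)
  fitted <- adapter$fit(x[train, , drop = FALSE], y, weights = NULL)
  c_hat <- mean(adapter$predict(fitted, x[holdout, , drop = FALSE]))
  if (!is.finite(c_hat) || c_hat <= .C_HAT_EPS)
    stop("estimated label frequency c_hat <= ", .C_HAT_EPS,
         "; the base learner carries no signal on held-out positives",
         call. = FALSE)
  c_hat <- min(c_hat, 1)
  structure(list(base = fitted, adapter = adapter, c_hat = c_hat,
                 holdout_ids = holdout),
            class = "elkan_noto_model")
}

#' Calibrated Elkan-Noto probabilities
#'
#' Elementwise `min(1, raw_score / c_hat)` — a monotone transform, so score
#' rankings are preserved exactly.
#'
#' @param model An `elkan_noto_model`.
#' @param x New feature rows.
#' @return Calibrated probabilities in `[0, 1]`.
#' @export
predict_elkan_noto <- function(model, x) {
  stopifnot(inherits(model, "elkan_noto_model"))
  raw <- model$adapter$predict(model$base, x)
  pmin(1, raw / model$c_hat)
}

#' @export
predict.elkan_noto_model <- function(object, newdata, ...) {
  predict_elkan_noto(object, newdata)
}

#' Fit a spy-based two-step PU model
#'
#' Step one plants a random `spy_frac` of the labeled positives ("spies")
#' into the unlabeled pool and fits the base learner on the remaining
#' positives versus that contaminated pool. Because spies are genuine
#' positives, their score distribution shows where positives land; the
#' noise-tolerance threshold `t` is the `ceiling(noise_tol * n_spies)`-th
#' smallest spy score, allowing a `noise_tol` fraction of spies to fall
#' below it. Unlabeled records scoring strictly below `t` are deemed
#' reliable negatives. Step two returns the spies to the positive set and
#' refits on all labeled positives versus the reliable negatives only;
#' remaining unlabeled records are excluded from the refit and merely
#' scored at prediction time.
#'
#' @param x Feature matrix/data frame.
#' @param s_labels Observed PU labels (1 = labeled positive, 0 = unlabeled).
#' @param adapter A `base_adapter`.
#' @param spy_frac Fraction of positives planted as spies (default 0.1).
#' @param noise_tol Tolerated fraction of spies below the threshold
#'   (default 0.2).
#' @param seed Integer seed for the spy draw.
#' @return Object of class `spy_model`: `final` (refit), `threshold_t`,
#'   `spy_ids`, `reliable_negative_ids` (row indices), `first_stage`.
#' @export
fit_spy <- function(x, s_labels, adapter, spy_frac = .DEFAULT_SPY_FRAC,
                    noise_tol = .DEFAULT_NOISE_TOL, seed = 1L) {
  stopifnot(inherits(adapter, "base_adapter"))
  pos <- which(s_labels == 1)
  unl <- which(s_labels == 0)
  if (length(pos) < 10L)
    stop("fit_spy needs at least 10 labeled positives", call. = FALSE)
  if (length(unl) < 1L)
    stop("fit_spy needs at least one unlabeled record", call. = FALSE)
  set.seed(seed)
  n_spies <- ceiling(spy_frac * length(pos))
  spies <- sort(sample(pos, n_spies))
  y1 <- s_labels
  y1[spies] <- 0  # spies masquerade as unlabeled in step one
  stage1 <- adapter$fit(x, y1, weights = balanced_weights(y1))
  spy_scores <- adapter$predict(stage1, x[spies, , drop = FALSE])
  threshold_t <- sort(spy_scores)[ceiling(noise_tol * n_spies)]
  unl_scores <- adapter$predict(stage1, x[unl, , drop = FALSE])
  rn <- unl[unl_scores < threshold_t]
  if (length(rn) == 0L)
    stop("no reliable negatives below the spy threshold; the first-stage ",
         "learner cannot separate spies from the unlabeled pool - consider ",
         "a stronger base learner or a larger noise tolerance",
         call. = FALSE)
  idx2 <- c(pos, rn)
  y2 <- c(rep(1L, length(pos)), rep(0L, length(rn)))
  final <- adapter$fit(x[idx2, , drop = FALSE], y2,
                       weights = balanced_weights(y2))
  structure(list(final = final, adapter = adapter,
                 threshold_t = threshold_t, spy_ids = spies,
                 reliable_negative_ids = rn, first_stage = stage1,
                 spy_frac = spy_frac, noise_tol = noise_tol),
            class = "spy_model")
}

#' Second-stage spy-model scores
#'
#' @param model A `spy_model`.
#' @param x New feature rows.
#' @return Scores in `[0, 1]` from the second-stage fit, unmodified.
#' @export
predict_spy <- function(model, x) {
  stopifnot(inherits(model, "spy_model"))
  model$adapter$predict(model$final, x)
}

#' @export
predict.spy_model <- function(object, newdata, ...) {
  predict_spy(object, newdata)
}

#' Fit the supervised baseline
#'
#' Treats every unlabeled record as negative and fits the base learner with
#' inverse-class-frequency weights — the traditional binary-classification
#' arm the PU wrappers are compared against.
#'
#' @param x Feature matrix/data frame.
#' @param s_labels Observed labels (1 = labeled positive, 0 = unlabeled).
#' @param adapter A `base_adapter`.
#' @return Object of class `supervised_model`.
#' @export
fit_supervised <- function(x, s_labels, adapter) {
  stopifnot(inherits(adapter, "base_adapter"))
  fitted <- adapter$fit(x, s_labels, weights = balanced_weights(s_labels))
  structure(list(base = fitted, adapter = adapter),
            class = "supervised_model")
}

#' @export
predict.supervised_model <- function(object, newdata, ...) {
  object$adapter$predict(object$base, newdata)
}

#' Serialize a PU wrapper's calibration state
#'
#' Writes the wrapper-level state (calibration constant or spy threshold
#' and id lists) as a JSON sidecar next to whatever native format the base
#' learner uses.
#'
#' @param model An `elkan_noto_model` or `spy_model`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_model_sidecar <- function(model, path) {
  side <- if (inherits(model, "elkan_noto_model")) {
    list(kind = "elkan_noto", c_hat = model$c_hat,
         holdout_ids = model$holdout_ids, adapter = model$adapter$name)
  } else if (inherits(model, "spy_model")) {
    list(kind = "spy", threshold_t = model$threshold_t,
         spy_ids = model$spy_ids,
         reliable_negative_ids = model$reliable_negative_ids,
         spy_frac = model$spy_frac, noise_tol = model$noise_tol,
         adapter = model$adapter$name)
  } else stop("not a PU wrapper model", call. = FALSE)
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
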