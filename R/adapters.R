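# Pluggable base-learner adapters. An adapter is a small S3 object exposing
# fit(x, y, weights) and predict(fitted, x), returning scores in [0, 1] and
# accepting the NA missing sentinel; everything PU-specific lives in the
# wrappers, not here.

#' Inverse-class-frequency sample weights
#'
#' `n_total / (2 * n_class)` per observation, so each class carries half the
#' effective weight regardless of imbalance.
#'
#' @param y Binary vector (1 = positive).
#' @return Numeric weight vector.
#' @export
balanced_weights <- function(y) {
  n <- length(y)
  ifelse(y == 1, n / (2 * sum(y == 1)), n / (2 * sum(y == 0)))
}

new_base_adapter <- function(name, fit, predict) {
  structure(list(name = name, fit = fit, predict = predict),
            class = "base_adapter")
}

#' @export
print.base_adapter <- function(x, ...) {
  cat(sprintf("<base_adapter> %s\n", x$name)); invisible(x)
}

#' Gradient-boosted-tree base learner (xgboost)
#'
#' Boosted-tree adapter with strong structural regularization suited to a
#' tiny positive class: shallow trees, few rounds, L2 regularization.
#' Handles the `NA` missing sentinel natively (missing values are routed by
#' the learned default direction) and is deterministic on a single thread.
#'
#' @param nrounds Number of boosting rounds.
#' @param max_depth Maximum tree depth.
#' @param eta Learning rate.
#' @param lambda L2 regularization.
#' @param min_child_weight Minimum hessian per leaf.
#' @return A `base_adapter`.
#' @export
adapter_xgboost <- function(nrounds = 60L, max_depth = 3L, eta = 0.3,
                            lambda = 1, min_child_weight = 1) {
  params <- list(objective = "binary:logistic", max_depth = max_depth,
                 eta = eta, lambda = lambda,
                 min_child_weight = min_child_weight, nthread = 1L,
                 verbosity = 0L)
  new_base_adapter(
    name = "xgboost",
    fit = function(x, y, weights = NULL) {
      dm <- xgboost::xgb.DMatrix(data = as.matrix(x), label = y,
                                 missing = NA)
      if (!is.null(weights)) xgboost::setinfo(dm, "weight", weights)
      xgboost::xgb.train(params = params, data = dm, nrounds = nrounds)
    },
    predict = function(fitted, x) {
      dm <- xgboost::xgb.DMatrix(data = as.matrix(x), missing = NA)
      as.numeric(stats::predict(fitted, dm))
    })
}

# one-hot encoding for the glmnet fallback: bin-indexed / low-cardinality
# columns expand to per-level indicators plus a missing indicator; continuous
# columns are decile-binned on the training data first, so the model is
# piecewise-constant in every feature (step functions can represent the flat
# score plateaus PU calibration relies on)
.onehot_fit <- function(x, max_levels = 12L) {
  lapply(x, function(v) {
    u <- sort(unique(v[!is.na(v)]))
    if (length(u) <= max_levels && (length(u) == 0L || all(u == round(u))))
      list(type = "cat", levels = u)
    else
      list(type = "numbin",
           edges = unique(stats::quantile(v[!is.na(v)], seq(0.1, 0.9, 0.1),
                                          type = .QUANTILE_TYPE,
                                          names = FALSE)))
  })
}

.onehot_apply <- function(x, enc) {
  blocks <- vector("list", length(enc))
  for (j in seq_along(enc)) {
    cn <- names(enc)[j]
    v <- x[[cn]]
    e <- enc[[j]]
    if (e$type == "cat") {
      m <- matrix(0, nrow = length(v), ncol = length(e$levels) + 1L)
      for (k in seq_along(e$levels))
        m[, k] <- as.numeric(!is.na(v) & v == e$levels[k])
      m[, length(e$levels) + 1L] <- as.numeric(is.na(v))
      colnames(m) <- c(paste0(cn, "=", e$levels), paste0(cn, "=NA"))
    } else {
      idx <- findInterval(v, e$edges, left.open = TRUE)
      nb <- length(e$edges) + 1L
      m <- matrix(0, nrow = length(v), ncol = nb + 1L)
      for (k in seq_len(nb))
        m[, k] <- as.numeric(!is.na(idx) & idx == (k - 1L))
      m[, nb + 1L] <- as.numeric(is.na(v))
      colnames(m) <- c(paste0(cn, "=b", seq_len(nb) - 1L), paste0(cn, "=NA"))
    }
    blocks[[j]] <- m
  }
  Matrix::Matrix(do.call(cbind, blocks), sparse = TRUE)
}

#' Regularized-logistic base learner on one-hot bins (glmnet)
#'
#' Dependency-light fallback learner: every bin-indexed or low-cardinality
#' column is expanded to per-level indicators (missingness gets its own
#' indicator, honouring the no-imputation contract for categorical
#' features), continuous columns are median-filled with a companion missing
#' indicator, and a ridge/elastic-net logistic model is fitted at a fixed
#' penalty.
#'
#' @param alpha Elastic-net mixing (0 = ridge).
#' @param lambda Penalty strength.
#' @return A `base_adapter`.
#' @export
adapter_glmnet <- function(alpha = 0, lambda = 0.01) {
  new_base_adapter(
    name = "glmnet",
    fit = function(x, y, weights = NULL) {
      x <- as.data.frame(x)
      enc <- .onehot_fit(x)
      X <- .onehot_apply(x, enc)
      # glmnet wants a decreasing path; the model used is the one at `lambda`
      path <- exp(seq(log(max(1, lambda * 100)), log(lambda),
                      length.out = 20))
      fit <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                            lambda = path, weights = weights,
                            standardize = TRUE)
      list(enc = enc, fit = fit, lambda = lambda)
    },
    predict = function(fitted, x) {
      X <- .onehot_apply(as.data.frame(x), fitted$enc)
      as.numeric(stats::predict(fitted$fit, X, s = fitted$lambda,
                                type = "response"))
    })
}

#' Look up a shipped adapter by name
#'
#' @param name `"xgboost"` or `"glmnet"`.
#' @param ... Passed to the adapter constructor.
#' @return A `base_adapter`.
#' @export
get_adapter <- function(name, ...) {
  switch(name,
         xgboost = adapter_xgboost(...),
         glmnet = adapter_glmnet(...),
         stop("unknown adapter: ", name, call. = FALSE))
}
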