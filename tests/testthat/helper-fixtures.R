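# Shared fixtures: tiny cohorts, separable PU datasets, and a transparent
# fake adapter whose score is simply the first feature column - handy for
# testing wrapper arithmetic independently of any real learner.

fake_adapter <- function() {
  structure(list(
    name = "fake",
    fit = function(x, y, weights = NULL) list(),
    predict = function(fitted, x) as.numeric(as.data.frame(x)[[1L]])),
    class = "base_adapter")
}

# two-feature PU dataset with well-separated classes and a SCAR labeling
# mechanism at labeling frequency c_true
make_separable_pu <- function(n = 2000, pi_pos = 0.1, c_true = 0.5,
                              sep = 3, seed = 1) {
  set.seed(seed)
  y <- as.integer(runif(n) < pi_pos)
  x <- cbind(x1 = rnorm(n, mean = sep * y, sd = 0.5),
             x2 = rnorm(n, mean = sep * y, sd = 0.5))
  s <- ifelse(y == 1 & runif(n) < c_true, 1L, 0L)
  list(x = as.data.frame(x), y = y, s = s)
}

small_cohort <- function(n_unlabeled = 150, n_labeled = 15, seed = 1, ...) {
  generate_cohort(cohort_config(n_unlabeled = n_unlabeled,
                                n_labeled_positive = n_labeled,
                                seed = seed, ...))
}

# brute-force oracles -------------------------------------------------------

oracle_ap <- function(truth, scores) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  ap <- 0
  npos <- sum(truth == 1)
  for (t in thresholds) {
    sel <- scores >= t
    precision <- sum(truth[sel] == 1) / sum(sel)
    recall <- sum(truth[sel] == 1) / npos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running_min <- 1
  for (i in rev(seq_len(m))) {
    running_min <- min(running_min, p[ord[i]] * m / i)
    adj[ord[i]] <- running_min
  }
  pmin(adj, 1)
}

# weighted logistic log-likelihood maximized numerically; returns the slope
oracle_weighted_logistic_slope <- function(x, y) {
  n <- length(y)
  w <- ifelse(y == 1, n / (2 * sum(y == 1)), n / (2 * sum(y == 0)))
  nll <- function(beta) {
    eta <- beta[1] + beta[2] * x
    -sum(w * (y * eta - log1p(exp(eta))))
  }
  optim(c(0, 0), nll, method = "BFGS")$par[2]
}
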