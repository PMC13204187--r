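test_that("Elkan-Noto c_hat is the mean holdout score, clipped to (0, 1]", {
  # fake adapter scores = first feature; all positives score 0.7
  n <- 60
  x <- data.frame(x1 = c(rep(0.7, 20), rep(0.1, 40)))
  s <- c(rep(1L, 20), rep(0L, 40))
  m <- fit_elkan_noto(x, s, fake_adapter(), holdout_frac = 0.1, seed = 5)
  expect_equal(m$c_hat, 0.7)
  expect_true(all(s[m$holdout_ids] == 1))
  # calibration rule: raw / c_hat, capped at 1
  expect_equal(predict_elkan_noto(m, data.frame(x1 = 0.35)), 0.5)
  expect_equal(predict_elkan_noto(m, data.frame(x1 = 0.9)), 1.0)
  # c_hat = 1 -> identity
  x1 <- data.frame(x1 = c(rep(1, 20), rep(0.3, 40)))
  m1 <- fit_elkan_noto(x1, s, fake_adapter(), seed = 5)
  expect_equal(m1$c_hat, 1)
  expect_equal(predict_elkan_noto(m1, data.frame(x1 = c(0.2, 0.8))),
               c(0.2, 0.8))
})

test_that("Elkan-Noto errors on degenerate inputs", {
  x <- data.frame(x1 = rep(0.5, 20))
  expect_error(fit_elkan_noto(x, c(rep(1, 5), rep(0, 15)), fake_adapter()),
               "at least 10 labeled positives")
  x0 <- data.frame(x1 = c(rep(0, 12), rep(0.4, 8)))
  expect_error(fit_elkan_noto(x0, c(rep(1L, 12), rep(0L, 8)), fake_adapter(),
                              holdout_frac = 0.999, seed = 1),
               "no signal")
})

test_that("calibration preserves score ranking exactly", {
  set.seed(11)
  x <- data.frame(x1 = runif(200, 0.05, 0.95))
  s <- c(rep(1L, 30), rep(0L, 170))
  m <- fit_elkan_noto(x, s, fake_adapter(), seed = 2)
  raw <- fake_adapter()$predict(NULL, x)
  cal <- predict_elkan_noto(m, x)
  # weakly monotone overall (the cap at 1 ties top scores) ...
  expect_true(all(diff(cal[order(raw)]) >= -1e-12))
  # ... and strictly order-preserving below the cap
  sub <- raw < m$c_hat
  expect_equal(order(cal[sub]), order(raw[sub]))
  expect_true(all(cal >= raw - 1e-12))
})

test_that("c_hat recovers the true labeling frequency on SCAR cohorts", {
  # seed-averaged absolute bias per cohort size; the n = 500 cohorts hold
  # out only ~3 positives, so their single-seed estimates are noisy by design
  mean_abs_bias <- sapply(c(500, 2000, 8000), function(n) {
    mean(sapply(1:3, function(s) {
      d <- make_separable_pu(n = n, c_true = 0.5, seed = n + s)
      m <- fit_elkan_noto(d$x, d$s, adapter_xgboost(), seed = n + s + 1)
      abs(m$c_hat - 0.5)
    }))
  })
  # consistency: bias shrinks from the smallest to the largest cohort
  expect_lt(mean_abs_bias[3], mean_abs_bias[1])
  expect_lt(mean_abs_bias[2], 0.1)
  expect_lt(mean_abs_bias[3], 0.1)
})

test_that("spy threshold is the noise-tolerance order statistic of spy scores", {
  set.seed(13)
  n_pos <- 20; n_unl <- 100
  x <- data.frame(x1 = c(runif(n_pos, 0.5, 0.9), runif(n_unl, 0, 0.6)))
  s <- c(rep(1L, n_pos), rep(0L, n_unl))
  m <- fit_spy(x, s, fake_adapter(), spy_frac = 0.25, noise_tol = 0.2,
               seed = 3)
  spy_scores <- x$x1[m$spy_ids]
  expect_equal(m$threshold_t,
               sort(spy_scores)[ceiling(0.2 * length(m$spy_ids))])
  # reliable negatives: unlabeled, non-spy, strictly below t
  expect_true(all(s[m$reliable_negative_ids] == 0))
  expect_true(all(x$x1[m$reliable_negative_ids] < m$threshold_t))
  unl <- which(s == 0)
  expect_setequal(m$reliable_negative_ids, unl[x$x1[unl] < m$threshold_t])
  # direct rule on a fixed spy score set {0.5 ... 0.9}, noise_tol 0.2:
  # threshold is the 1st smallest = 0.5
  expect_equal(sort(c(0.9, 0.6, 0.8, 0.5, 0.7))[ceiling(0.2 * 5)], 0.5)
})

test_that("spy mining recovers the true negatives on a separable toy", {
  d <- make_separable_pu(n = 800, pi_pos = 0.15, c_true = 0.6, seed = 19)
  m <- fit_spy(d$x, d$s, adapter_xgboost(), seed = 20)
  rn_latent <- mean(d$y[m$reliable_negative_ids] == 1)
  pool_latent <- mean(d$y[d$s == 0] == 1)
  expect_lt(rn_latent, pool_latent)
  expect_lt(rn_latent, 0.05)
  expect_error(fit_spy(d$x, rep(0L, 800), adapter_xgboost()),
               "labeled positives")
})

test_that("spy purity gain holds across seeds (paired)", {
  gains <- sapply(1:8, function(sd) {
    d <- make_separable_pu(n = 600, pi_pos = 0.15, c_true = 0.5, seed = sd)
    m <- fit_spy(d$x, d$s, adapter_xgboost(), seed = sd + 100)
    mean(d$y[d$s == 0] == 1) - mean(d$y[m$reliable_negative_ids] == 1)
  })
  expect_true(all(gains >= 0))
  expect_gt(mean(gains), 0)
})

test_that("predict_spy returns deterministic in-range second-stage scores", {
  d <- make_separable_pu(n = 400, seed = 31)
  m <- fit_spy(d$x, d$s, adapter_xgboost(), seed = 32)
  p1 <- predict_spy(m, d$x)
  p2 <- predict_spy(m, d$x)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # with the transparent adapter, stage ranking agrees perfectly
  xf <- data.frame(x1 = c(runif(15, 0.6, 0.9), runif(60, 0, 0.5)))
  sf <- c(rep(1L, 15), rep(0L, 60))
  mf <- fit_spy(xf, sf, fake_adapter(), seed = 33)
  s1 <- fake_adapter()$predict(NULL, xf)
  expect_equal(cor(rank(predict_spy(mf, xf)), rank(s1)), 1)
})

test_that("wrappers degrade to supervised behaviour without hidden positives", {
  d <- make_separable_pu(n = 600, pi_pos = 0.15, c_true = 1, seed = 41)
  expect_true(all(d$s == d$y))
  men <- fit_elkan_noto(d$x, d$s, adapter_xgboost(), seed = 42)
  expect_gt(men$c_hat, 0.85)
  msp <- fit_spy(d$x, d$s, adapter_xgboost(), seed = 43)
  # reliable negatives cover most of the unlabeled pool and are pure
  expect_gt(length(msp$reliable_negative_ids), 0.5 * sum(d$s == 0))
  expect_lt(mean(d$y[msp$reliable_negative_ids] == 1), 0.02)
})

test_that("model sidecars serialize the wrapper state", {
  d <- make_separable_pu(n = 300, seed = 51)
  m <- fit_elkan_noto(d$x, d$s, adapter_xgboost(), seed = 52)
  f <- withr::local_tempfile(fileext = ".json")
  write_model_sidecar(m, f)
  side <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(side$kind, "elkan_noto")
  expect_equal(side$c_hat, m$c_hat)
})
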