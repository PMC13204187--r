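test_that("aggregate_series matches direct formula evaluation", {
  a <- aggregate_series(c(1, 2, 3))
  expect_equal(unname(a[c("p25", "p50", "p75")]), c(1.5, 2, 2.5))
  expect_equal(unname(a[c("min", "max")]), c(1, 3))
  expect_equal(unname(a["var"]), 1.0)
  expect_equal(unname(a["absdiff"]), 2)
  expect_equal(unname(a["mono"]), 1)

  s <- aggregate_series(5)
  expect_true(all(s[c("p25", "p50", "p75", "min", "max")] == 5))
  expect_equal(unname(s[c("var", "absdiff", "mono")]), c(0, 0, 0))

  d <- aggregate_series(c(3, 1))
  expect_equal(unname(d["absdiff"]), 2)
  expect_equal(unname(d["mono"]), 0)

  expect_true(all(is.na(aggregate_series(numeric(0)))))
})

test_that("aggregate order statistics keep min <= p25 <= p50 <= p75 <= max", {
  set.seed(5)
  for (i in 1:50) {
    v <- rlnorm(sample(1:30, 1), meanlog = rnorm(1), sdlog = runif(1, 0.1, 2))
    a <- aggregate_series(v)
    expect_true(a["min"] <= a["p25"] && a["p25"] <= a["p50"] &&
                  a["p50"] <= a["p75"] && a["p75"] <= a["max"])
    expect_gte(a["var"], 0)
    # oracle: direct quantile/variance formulas
    expect_equal(unname(a["p50"]), unname(quantile(v, 0.5, type = 7)))
    expect_equal(unname(a["var"]),
                 if (length(v) > 1) sum((v - mean(v))^2) / (length(v) - 1)
                 else 0)
  }
})

test_that("fit_bins places interior edges at control deciles", {
  bm <- fit_bins(data.frame(f = 1:100))
  expect_length(bm$edges$f, 9)
  expect_equal(bm$edges$f[1], 10.9)
  expect_equal(bm$edges$f, unname(quantile(1:100, seq(0.1, 0.9, 0.1),
                                           type = 7)))
  # degenerate constant feature: all edges equal, everything maps to bin 0
  bc <- fit_bins(data.frame(g = rep(7, 50)))
  expect_true(all(bc$edges$g == 7))
  expect_equal(apply_bins(c(6, 7, 8), bc$edges$g), c(0L, 0L, 9L))
  expect_error(fit_bins(data.frame(h = 1:9)), "h")
})

test_that("apply_bins uses strict-below counting with ties to the lower bin", {
  edges <- as.numeric(1:9)
  expect_equal(apply_bins(0.5, edges), 0L)
  expect_equal(apply_bins(100, edges), 9L)
  expect_equal(apply_bins(5, edges), 4L)   # equal to an edge -> lower interval
  expect_equal(apply_bins(NA_real_, edges), NA_integer_)
  # brute-force oracle: count of edges strictly below
  set.seed(8)
  for (v in runif(50, -1, 11))
    expect_equal(apply_bins(v, edges), sum(edges < v))
})

test_that("decile bins give near-equal occupancy on a uniform sample", {
  set.seed(31)
  ctrl <- runif(10000)
  bm <- fit_bins(data.frame(u = ctrl))
  occ <- table(factor(apply_bins(ctrl, bm$edges$u), levels = 0:9)) / 10000
  expect_true(all(abs(occ - 0.10) <= 0.01))
})

test_that("prevalence filter requires 5% presence in both cohorts", {
  n_pos <- 50; n_neg <- 100
  lab <- c(rep(1, n_pos), rep(0, n_neg))
  x <- data.frame(
    rare_ctrl = c(rep(1, 40), rep(0, 10), rep(1, 4), rep(0, 96)),  # 80% / 4%
    boundary = c(rep(1, 3), rep(0, 47), rep(1, 5), rep(0, 95)),    # 6% / 5%
    everywhere = rep(1, 150),
    exempt_na = rep(NA_real_, 150))
  meta <- data.frame(column = names(x),
                     kind = c("binary", "binary", "binary", "aggregate"),
                     exempt = c(FALSE, FALSE, FALSE, TRUE))
  kept <- prevalence_filter(x, meta, lab)
  expect_false("rare_ctrl" %in% kept)
  expect_true("boundary" %in% kept)      # >= is inclusive at exactly 5%
  expect_true("everywhere" %in% kept)
  expect_true("exempt_na" %in% kept)     # mandatory features bypass the filter
  expect_error(prevalence_filter(x, meta, rep(1, 150)), "positive and one")
})

test_that("phenotype mapping is exact-first with root fallback", {
  map <- data.frame(code = c("D64.8", "Z03"),
                    phenotype = c("anemias", "diagnostic_observation"))
  expect_equal(map_phewas("D64.8", map), "anemias")
  expect_equal(map_phewas("D64.1", map), "anemias")  # root fallback
  expect_true(is.na(map_phewas("E11", map)))
  bad <- rbind(map, data.frame(code = "D64.8", phenotype = "other"))
  expect_error(map_phewas("D64.8", bad), "conflicting")
  # exact duplicates are harmless
  ok <- rbind(map, map[1, ])
  expect_equal(map_phewas("D64.8", ok), "anemias")
})

test_that("weight-of-evidence encoding matches its smoothed formula", {
  # equal class proportions in every category -> WoE 0
  x <- data.frame(b = rep(c(0, 1), each = 20))
  lab <- rep(c(1, 0, 1, 0), each = 10)
  w0 <- woe_transform(x, lab)
  expect_true(all(abs(w0$encoded$b) < 1e-12))

  # pos 8/10 in category A, neg 10/100 in category A, k = 2
  x2 <- data.frame(b = c(rep("A", 8), rep("B", 2), rep("A", 10), rep("B", 90)))
  lab2 <- c(rep(1, 10), rep(0, 100))
  w2 <- woe_transform(x2, lab2)
  tab <- w2$tables$b
  expect_equal(tab$woe[tab$category == "A"],
               log((8.5 / 11) / (10.5 / 101)), tolerance = 1e-12)
  expect_equal(round(tab$woe[tab$category == "A"], 3), 2.006)

  # empty category stays finite through the pseudo-count
  x3 <- data.frame(b = c(rep("A", 10), rep("B", 5)))
  lab3 <- c(rep(1, 10), rep(0, 5))  # B has zero positives
  w3 <- woe_transform(x3, lab3)
  expect_true(all(is.finite(w3$tables$b$woe)))
  # unseen categories at apply time encode to 0; missing is its own category
  x4 <- data.frame(b = c("A", "C", NA))
  enc <- woe_apply(x4, w3$tables)
  expect_equal(enc$b[2], 0)
  expect_error(woe_transform(x, rep(1, 40)), "both classes")
})

test_that("raw feature extraction realizes the 212-column schema", {
  expect_equal(feature_schema_count(), 212L)
  expect_equal(feature_schema_count(22, 5, 7, 2), 22 * 9 + 5 + 7 + 2)
  co <- small_cohort(60, 12, seed = 21)
  ws <- build_windows(co, seed = 3)
  raw <- build_raw_features(ws, co$patients)
  expect_equal(ncol(raw$x), 212)
  expect_equal(nrow(raw$x), length(ws))
  expect_equal(sum(raw$meta$kind == "aggregate"), 176)
  expect_equal(sum(raw$meta$kind == "binary") , 22 + 5 + 7)
  expect_equal(sum(raw$meta$kind == "demographic"), 2)
  # a window without ICD events has all code columns 0
  no_icd <- vapply(ws, function(w) !any(w$events$kind == "icd10"), logical(1))
  if (any(no_icd)) {
    code_cols <- raw$meta$column[startsWith(raw$meta$column, "icd_")]
    expect_true(all(raw$x[which(no_icd)[1], code_cols] == 0))
  }
  # determinism
  raw2 <- build_raw_features(ws, co$patients)
  expect_identical(raw, raw2)
})

test_that("build_feature_matrix bins aggregates and applies the filter", {
  co <- small_cohort(120, 15, seed = 22)
  ws <- build_windows(co, seed = 5)
  raw <- build_raw_features(ws, co$patients)
  fm <- build_feature_matrix(raw)
  agg_cols <- fm$meta$column[fm$meta$kind == "aggregate_binned"]
  vals <- unlist(fm$x[, agg_cols])
  expect_true(all(is.na(vals) | (vals >= 0 & vals <= 9)))
  # missingness is preserved, never imputed
  expect_gt(sum(is.na(vals)), 0)
  expect_true(all(fm$meta$column %in% raw$meta$column))
})
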