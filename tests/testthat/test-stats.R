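test_that("diagnostic metrics reproduce the reference confusion matrix", {
  cm <- confusion_matrix(TP = 15, FP = 10, TN = 35, FN = 6)
  m <- diagnostic_metrics(cm)
  expect_equal(round(unname(m), 2),
               c(71.43, 77.78, 60.00, 85.37, 75.76))
  # perfect classifier
  expect_equal(unname(diagnostic_metrics(confusion_matrix(5, 0, 7, 0))),
               rep(100, 5))
  # swapping class labels swaps sens<->spec and PPV<->NPV
  sw <- diagnostic_metrics(confusion_matrix(TP = 35, FP = 6, TN = 15,
                                            FN = 10))
  expect_equal(sw[["sensitivity"]], m[["specificity"]])
  expect_equal(sw[["ppv"]], m[["npv"]])
  expect_equal(sw[["accuracy"]], m[["accuracy"]])
  # TP = FN = 0: sensitivity has a zero denominator
  expect_warning(diagnostic_metrics(confusion_matrix(0, 3, 5, 0)),
                 "sensitivity")
  expect_error(confusion_matrix(-1, 0, 0, 1), "non-negative")
})

test_that("classification uses the strict below-threshold convention", {
  expect_false(classify(0.8, 0.8))          # boundary value is negative
  expect_identical(classify(c(0.9, 0.95), 0.8), c(FALSE, FALSE))
  set.seed(11)
  v <- runif(200); thr <- 0.47
  expect_identical(classify(v, thr), vapply(v, function(x) x < thr,
                                            logical(1)))
})

test_that("polynomial fits recover known relations", {
  # noiseless linear data: exact recovery
  x <- seq(0.4, 1, length.out = 30)
  # suppress summary.lm's "essentially perfect fit" note on noiseless data
  f1 <- suppressWarnings(fit_polynomial(x, 0.6469 * x + 0.3688, 1))
  expect_equal(f1$coefficients, c(0.6469, 0.3688), tolerance = 1e-10)
  expect_equal(f1$r_squared, 1, tolerance = 1e-10)
  # quadratic + stated noise, cohort size 66: coefficients within 3 SE
  ch <- synthetic_cohort(seed = 4)
  f2 <- fit_polynomial(ch$cffr, ch$cifr, 2)
  se <- summary(f2$lm)$coefficients[, "Std. Error"]
  ref <- c(-0.5926, 1.5616, 0.0218)
  expect_true(all(abs(f2$coefficients - ref) < 3 * rev(se)))
  # cubic fit on quadratic data: leading coefficient insignificant
  f3 <- fit_polynomial(ch$cffr, ch$cifr, 3)
  tstat <- summary(f3$lm)$coefficients[4, "t value"]
  expect_lt(abs(tstat), 3)
  expect_error(fit_polynomial(x[1:2], x[1:2], 2), "degree")
})

test_that("threshold evaluation reproduces the reference cut-offs", {
  expect_equal(round(threshold_from_fit(c(0.6469, 0.3688)), 4), 0.8863)
  expect_equal(round(threshold_from_fit(c(-0.5926, 1.5616, 0.0218)), 4),
               0.8918)
  expect_equal(round(threshold_from_fit(
    c(0.6770, -2.1472, 2.7307, -0.2654)), 4), 0.8916)
  # accepts the fit object directly
  x <- seq(0.4, 1, length.out = 20)
  f <- suppressWarnings(fit_polynomial(x, 2 * x - 0.5, 1))
  expect_equal(threshold_from_fit(f, 0.8), 1.1, tolerance = 1e-10)
})

test_that("Bland-Altman agrees with the hand-computed table", {
  a <- c(0.9, 0.85, 0.7, 0.95, 0.6)
  b <- c(0.88, 0.80, 0.75, 0.90, 0.65)
  ba <- bland_altman(a, b)
  expect_equal(ba$mean_difference, 0.004, tolerance = 1e-12)
  expect_equal(ba$sd_difference, 0.05079370039680118, tolerance = 1e-12)
  expect_equal(unname(ba$limits_of_agreement),
               0.004 + c(-1.96, 1.96) * ba$sd_difference)
  expect_equal(bland_altman(a, a)$mean_difference, 0)
  expect_equal(bland_altman(a, a)$sd_difference, 0)
  off <- bland_altman(a + 0.1, a)
  expect_equal(off$mean_difference, 0.1, tolerance = 1e-12)
  expect_equal(off$sd_difference, 0, tolerance = 1e-12)
  expect_error(bland_altman(1, 2), "2 pairs")
})

test_that("pearson matches the product-moment definition", {
  x <- seq(0.1, 1, length.out = 15)
  expect_equal(pearson(x, 3 * x + 1), 1)
  expect_equal(pearson(x, -2 * x), -1)
  set.seed(8)
  a <- rnorm(50); b <- rnorm(50)
  brute <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson(a, b), brute, tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), a[1:5]), "variance")
})

test_that("ROC analysis equals the rank-based (Mann-Whitney) oracle", {
  # perfectly separable values
  v <- c(0.5, 0.6, 0.7, 0.9, 0.95, 1.0)
  ref <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  r <- roc(v, ref)
  expect_equal(r$auc, 1)
  expect_equal(r$youden_j, 1)
  expect_gt(r$optimal_threshold, 0.7)
  expect_lte(r$optimal_threshold, 0.9)
  # AUC == U / (n_pos n_neg) on random data, with and without ties
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    vals <- if (i %% 2) round(runif(n), 1) else runif(n)
    ref <- runif(n) < 0.4
    if (!any(ref) || all(ref)) next
    r <- roc(vals, ref)
    pos <- vals[ref]; neg <- vals[!ref]
    u <- 0
    for (p in pos) u <- u + sum(p < neg) + 0.5 * sum(p == neg)
    expect_equal(r$auc, u / (length(pos) * length(neg)), tolerance = 1e-12)
  }
  # labels random w.r.t. values: AUC ~ 0.5
  set.seed(31)
  vals <- runif(4000); ref <- runif(4000) < 0.5
  expect_lt(abs(roc(vals, ref)$auc - 0.5), 0.05)
  expect_error(roc(vals, rep(TRUE, 4000)), "both classes")
})

test_that("cohort report assembles the full statistics layer", {
  ch <- synthetic_cohort(seed = 2)
  rep_ <- cohort_report(ch)
  expect_equal(rep_$n, 66)
  expect_gt(rep_$pearson, 0.95)
  # model-generated cohort: quadratic fits better than linear
  expect_gt(rep_$fit_r_squared[2], rep_$fit_r_squared[1])
  expect_true(rep_$thresholds_at_cut[2] > 0.88 &&
                rep_$thresholds_at_cut[2] < 0.90)
  expect_gt(rep_$roc_auc, 0.95)
  # determinism of the generator
  expect_identical(synthetic_cohort(seed = 2), ch)
  expect_false(identical(synthetic_cohort(seed = 3)$cffr, ch$cffr))
})
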