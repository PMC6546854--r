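test_that("metrics reproduce the reported confusion-matrix arithmetic", {
  # layout [TP FP; FN TN]; matrix() fills column-major: c(TP, FN, FP, TN)
  worked <- list(
    list(cm = c(19, 5, 4, 20), CA = 81, Sen = 79, Spe = 83, ER = 0.19),
    list(cm = c(22, 2, 8, 16), CA = 79, Sen = 92, Spe = 67, ER = 0.21),
    list(cm = c(20, 4, 10, 14), CA = 71, Sen = 83, Spe = 58, ER = 0.29),
    list(cm = c(12, 12, 12, 12), CA = 50, Sen = 50, Spe = 50, ER = 0.50),
    list(cm = c(17, 7, 8, 16), CA = 69, Sen = 71, Spe = 67, ER = 0.31),
    list(cm = c(16, 8, 14, 10), CA = 54, Sen = 67, Spe = 42, ER = 0.46),
    list(cm = c(19, 5, 9, 15), CA = 71, Sen = 79, Spe = 63, ER = 0.29),
    list(cm = c(16, 8, 12, 12), CA = 58, Sen = 67, Spe = 50, ER = 0.42),
    list(cm = c(17, 7, 6, 18), CA = 73, Sen = 71, Spe = 75, ER = 0.27))
  for (w in worked) {
    m <- classification_metrics(matrix(w$cm, 2))
    expect_identical(m$display$CA, w$CA)
    expect_identical(m$display$Sen, w$Sen)
    expect_identical(m$display$Spe, w$Spe)
    expect_identical(m$display$ER, w$ER)
    expect_identical(m$CA + m$ER, 1)          # exact, pre-rounding
    expect_identical(m$total, sum(w$cm))
  }
  # half-up display rounding: 15/24 = 62.5% must print as 63%
  expect_identical(classification_metrics(matrix(c(19, 5, 9, 15), 2))$display$Spe, 63)
})

test_that("undefined metrics are NA, not zero", {
  m <- classification_metrics(matrix(c(0, 0, 5, 19), 2))
  expect_true(is.na(m$Sen))
  expect_false(is.na(m$Spe))
  expect_error(classification_metrics(matrix(0, 2, 2)), "empty")
})

test_that("a perfectly separable table yields the diagonal confusion matrix", {
  tb <- random_table(40, n_subjects = 24, signal = 2, delta = 10)
  cm <- loocv_confusion(tb, 2)
  expect_identical(as.integer(cm), c(24L, 0L, 0L, 24L))
  expect_identical(classification_metrics(cm)$ER, 0)
})

test_that("permutation test is deterministic and its p formula is exact", {
  tb <- random_table(41, n_subjects = 10, n_regions = 6, signal = 1, delta = 1.5)
  p1 <- permutation_test(tb, subset = 1, n_perm = 99, seed = 17)
  p2 <- permutation_test(tb, subset = 1, n_perm = 99, seed = 17)
  expect_identical(p1$null_errors, p2$null_errors)
  expect_identical(p1$p_value, p2$p_value)
  expect_identical(p1$p_value,
                   (1 + sum(p1$null_errors <= p1$observed_error + 1e-12)) / 100)
  expect_gt(p1$p_value, 0); expect_lte(p1$p_value, 1)
})

test_that("an observed error below every null error gives p = 1/(n_perm + 1)", {
  # 24 paired subjects, one hugely separated region: the observed LOOCV error
  # is 0, and among sign-flip permutations only the identity or the flip of
  # all 24 subjects could reproduce it (probability ~1e-3 over 9999 draws;
  # none occur at this seed)
  tb <- random_table(42, n_subjects = 24, n_regions = 3, signal = 2, delta = 12)
  pt <- permutation_test(tb, subset = 2, n_perm = 9999, seed = 23)
  expect_identical(pt$observed_error, 0)
  expect_true(all(pt$null_errors > 0))
  expect_identical(pt$p_value, 1e-4)
})

test_that("the post-selection null is LOOCV-pessimistic but the p-value stays calibrated", {
  # pre-fixed subset on null data: the null ER mean sits above 0.5 (the
  # leave-one-out majority artifact), within a predictable band
  means <- vapply(1:5, function(s) {
    ft <- simulate_feature_table(12, 8, seed = 500 + s)
    mean(permutation_test(ft$table, subset = c(1, 2, 3), n_perm = 99,
                          seed = s)$null_errors)
  }, numeric(1))
  expect_gt(mean(means), 0.5)
  expect_lt(mean(means), 0.75)
})

test_that("post-selection p-values on a subset selected from the same data are anti-conservative", {
  ps <- vapply(1:30, function(s) {
    ft <- simulate_feature_table(10, 8, effect_size = 0, seed = 900 + s)
    sel <- sfs(ft$table, max_k = 2)
    permutation_test(ft$table, subset = sel$final_subset, n_perm = 99,
                     seed = s)$p_value
  }, numeric(1))
  expect_gt(mean(ps <= 0.05), 0.10)  # far above the nominal 5%
})

test_that("full-pipeline permutation mode reruns selection and respects its budget", {
  tb <- random_table(43, n_subjects = 8, n_regions = 6, signal = 5, delta = 4)
  pt <- permutation_test(tb, n_perm = 15, mode = "full_pipeline",
                         selector = "sfs", max_k = 2, seed = 3)
  expect_length(pt$null_errors, 15)
  expect_identical(pt$observed_error, sfs(tb, max_k = 2)$final_criterion)
  pt2 <- permutation_test(tb, n_perm = 15, mode = "full_pipeline",
                          selector = "sfs", max_k = 2, seed = 3)
  expect_identical(pt$null_errors, pt2$null_errors)
  expect_error(permutation_test(tb, n_perm = 1e6, mode = "full_pipeline"),
               "lower n_perm")
})

test_that("permutation schemes respect the design", {
  tb <- random_table(44, n_subjects = 8)
  # free scheme works and keeps class balance
  pf <- permutation_test(tb, subset = 1, n_perm = 20, scheme = "free", seed = 2)
  expect_length(pf$null_errors, 20)
  # within-subject swaps demand a paired design
  tb_unpaired <- tb
  tb_unpaired$paired <- FALSE
  expect_error(permutation_test(tb_unpaired, subset = 1, n_perm = 5,
                                scheme = "within_subject", seed = 1),
               "paired")
})

test_that("p-values are invariant under common positive affine rescaling of the features", {
  tb <- random_table(45, n_subjects = 10, n_regions = 6, signal = 3, delta = 1.5)
  p1 <- permutation_test(tb, subset = c(2, 3), n_perm = 49, seed = 5)
  tb2 <- tb
  tb2$X <- tb$X * 12.5 + 3
  p2 <- permutation_test(tb2, subset = c(2, 3), n_perm = 49, seed = 5)
  # training-fold z-scoring makes the classifier affine-invariant up to
  # floating point; a decision value sitting at ~0 on a label-permuted noise
  # fold can flip with rounding, so demand agreement, not bit-identity
  expect_identical(p1$observed_error, p2$observed_error)
  expect_lte(mean(p1$null_errors != p2$null_errors), 0.05)
  expect_lt(abs(p1$p_value - p2$p_value), 0.05)
})
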