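test_that("block parcellation partitions the grid exactly", {
  p <- make_toy_parcellation(c(6, 6, 6), 8)
  expect_identical(sort(unique(as.vector(p$labels))), 1:8)
  # eight exact octants of 27 voxels each, every voxel labelled
  expect_true(all(table(p$labels) == 27))
  expect_true(all(p$mask))
  # blocks are contiguous cubes: each label spans a 3-wide range per axis
  for (l in 1:8) {
    idx <- which(p$labels == l, arr.ind = TRUE)
    expect_true(all(apply(idx, 2, function(v) max(v) - min(v) + 1) == 3))
  }

  p2 <- make_toy_parcellation(c(12, 12, 12), 8)
  expect_true(all(table(p2$labels) >= 27))
  expect_identical(sum(table(p2$labels)), 1728L)
})

test_that("parcellation sizing errors are raised", {
  expect_error(make_toy_parcellation(c(3, 3, 3), 2), "grid too small")
  expect_error(make_toy_parcellation(c(5, 5, 5), 4), "grid too small")
})

test_that("feature-table generator matches the study dimensions and is deterministic", {
  ft <- simulate_feature_table(24, 90, informative_regions = c(5, 17, 35, 50, 73),
                               effect_size = 1.5, seed = 42)
  expect_identical(dim(ft$table$X), c(48L, 90L))
  expect_identical(nlevels(ft$table$subject), 24L)
  expect_true(ft$table$paired)
  ft2 <- simulate_feature_table(24, 90, informative_regions = c(5, 17, 35, 50, 73),
                                effect_size = 1.5, seed = 42)
  expect_identical(ft$table$X, ft2$table$X)
  expect_identical(ft$truth$realized_d, ft2$truth$realized_d)
})

test_that("generator input validation", {
  expect_error(simulate_feature_table(10, 8, effect_size = Inf), "finite")
  expect_error(simulate_feature_table(10, 8, subject_rho = 1), "\\[0, 1\\)")
  expect_error(simulate_feature_table(10, 8, subject_rho = -0.1), "\\[0, 1\\)")
  expect_error(simulate_feature_table(10, 8, informative_regions = 9), "subset of 1")
})

test_that("a huge effect separates the conditions and is classified perfectly", {
  ft <- simulate_feature_table(24, 8, informative_regions = 3,
                               effect_size = 10, seed = 7)
  X <- ft$table$X; h <- ft$table$condition == "hunger"
  pooled <- sqrt((var(X[h, 3]) + var(X[!h, 3])) / 2)
  expect_gte((mean(X[h, 3]) - mean(X[!h, 3])) / pooled, 5)
  expect_identical(criterion_loocv_error(ft$table, 3), 0)
})

test_that("null tables carry no condition signal", {
  ft <- simulate_feature_table(24, 90, effect_size = 0, seed = 11)
  h <- ft$table$condition == "hunger"
  pvals <- apply(ft$table$X, 2, function(v) t.test(v[h], v[!h], paired = TRUE)$p.value)
  expect_lte(sum(pvals < 0.05), 12)  # ~4.5 expected of 90 at the null
  # LOOCV error of a fixed random subset is near chance over seeds
  errs <- vapply(1:15, function(s) {
    f <- simulate_feature_table(12, 8, effect_size = 0, seed = 300 + s)
    criterion_loocv_error(f$table, c(1, 2, 3))
  }, numeric(1))
  expect_gt(mean(errs), 0.35)
  # LOOCV pessimism biases noise error above 0.5, never towards signal
  expect_lt(mean(errs), 0.85)
})

test_that("BOLD cohort simulation is deterministic and validates inputs", {
  p <- make_toy_parcellation(c(6, 6, 6), 8)
  co <- cohort_spec(n_subjects = 2, n_timepoints = 32, tr = 2)
  es <- effect_spec(informative_regions = 2, effect_size = 1, subject_rho = 0.5)
  s1 <- simulate_bold_cohort(p, co, es, seed = 5)
  s2 <- simulate_bold_cohort(p, co, es, seed = 5)
  expect_identical(s1$runs[[1]]$data, s2$runs[[1]]$data)
  expect_identical(s1$runs[[4]]$data, s2$runs[[4]]$data)
  expect_identical(s1$truth$modulation, s2$truth$modulation)
  expect_length(s1$runs, 4)
  expect_identical(dim(s1$runs[[1]]$data), c(6L, 6L, 6L, 32L))

  expect_error(simulate_bold_cohort(p, co, effect_spec(informative_regions = 99,
                                                       effect_size = 1), seed = 1),
               "absent from the parcellation")
  expect_error(effect_spec(effect_kind = "nonsense"), "arg")
  expect_error(cohort_spec(n_subjects = 1), "n_subjects")
  expect_error(cohort_spec(conditions = c("a", "a")), "distinct")
})

test_that("amplitude effect realizes the requested d at large n", {
  p <- make_toy_parcellation(c(6, 6, 6), 8)
  sim <- simulate_bold_cohort(p, cohort_spec(n_subjects = 200, n_timepoints = 170, tr = 2),
                              effect_spec(informative_regions = c(2, 5),
                                          effect_kind = "amplitude", effect_size = 2.0),
                              seed = 11)
  tbl <- extract_feature_table(sim$runs, p, "falff", fwhm = 0)
  h <- tbl$condition == "hunger"
  d_real <- vapply(1:8, function(r) {
    a <- tbl$X[h, r]; b <- tbl$X[!h, r]
    (mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
  }, numeric(1))
  expect_true(all(abs(d_real[c(2, 5)] - 2.0) <= 0.3))
  expect_true(all(abs(d_real[-c(2, 5)]) <= 0.5))
})

test_that("coherence and coupling effects move their target features in the right direction", {
  p <- make_toy_parcellation(c(6, 6, 6), 8)
  for (kind in c("local_coherence", "global_coupling")) {
    f <- if (kind == "local_coherence") "reho" else "dc"
    signs <- vapply(1:6, function(s) {
      sim <- simulate_bold_cohort(p, cohort_spec(n_subjects = 10, n_timepoints = 64, tr = 2),
                                  effect_spec(informative_regions = c(2, 5),
                                              effect_kind = kind, effect_size = 1.5),
                                  seed = 400 + s)
      tbl <- suppressWarnings(extract_feature_table(sim$runs, p, f, fwhm = 0))
      h <- tbl$condition == "hunger"
      dm <- colMeans(tbl$X[h, ]) - colMeans(tbl$X[!h, ])
      mean(dm[c(2, 5)]) > 0
    }, logical(1))
    expect_gte(sum(signs), 5)
  }
})

test_that("the nesting demo table has its defining geometry", {
  tb <- nesting_demo_table()
  expect_identical(dim(tb$X), c(20L, 8L))
  # regions 1 and 2 sum to the class signal: jointly separable
  expect_identical(criterion_loocv_error(tb, c(1, 2)), 0)
  # region 5 is the unique best singleton
  singles <- vapply(1:8, function(r) criterion_loocv_error(tb, r), numeric(1))
  expect_identical(which.min(singles), 5L)
  expect_identical(sum(singles == min(singles)), 1L)
})
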