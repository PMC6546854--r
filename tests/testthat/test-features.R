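test_that("band-pass keeps in-band sinusoids and removes out-of-band ones", {
  n <- 170; tr <- 2
  s_in <- on_bin_sinusoid(17, n, tr)    # 17/340 = 0.05 Hz
  s_out <- on_bin_sinusoid(68, n, tr)   # 68/340 = 0.20 Hz
  r1 <- bandpass(replicated_run(s_in + 5), 0.01, 0.08)
  expect_lt(max(abs(r1$data[1, 1, 1, ] - s_in)), 1e-10)   # mean removed, shape kept
  r2 <- bandpass(replicated_run(s_out), 0.01, 0.08)
  expect_lt(max(abs(r2$data)), 1e-10)
})

test_that("band-pass passes the Parseval variance ratio on white noise", {
  n <- 170; tr <- 2
  k <- 0:(n - 1)
  kept <- sum(pmin(k, n - k) / (n * tr) >= 0.01 & pmin(k, n - k) / (n * tr) <= 0.08)
  expected <- kept / (n - 1)  # fraction of nonzero-frequency bins retained
  run <- white_noise_run(c(10, 10, 10), n, tr, seed = 21)
  bp <- bandpass(run, 0.01, 0.08)
  ratio <- var(as.vector(bp$data)) / var(as.vector(run$data))
  expect_lt(abs(ratio / expected - 1), 0.10)
})

test_that("band-pass rejects invalid bands", {
  run <- white_noise_run(c(3, 3, 3), 32, tr = 2)
  expect_error(bandpass(run, 0.08, 0.01), "f_lo < f_hi")
  expect_error(bandpass(run, 0.01, 0.3), "Nyquist")
  expect_error(bandpass(run, -0.01, 0.08), "f_lo")
})

test_that("Gaussian smoothing: identity, constants and impulse response", {
  vol <- array(rnorm(125), c(5, 5, 5))
  expect_identical(smooth_gaussian(vol, fwhm = 0), vol)
  cv <- array(3.25, c(5, 5, 5))
  expect_equal(smooth_gaussian(cv, 6, 3), cv, tolerance = 1e-12)
  # interior impulse peak equals the central weight of the normalized kernel
  imp <- array(0, c(9, 9, 9)); imp[5, 5, 5] <- 1
  sm <- smooth_gaussian(imp, 6, 3)
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 3
  r <- max(1, ceiling(4 * sigma))
  k1 <- exp(-((-r):r)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  expect_equal(sm[5, 5, 5], max(k1)^3, tolerance = 1e-12)
  expect_error(smooth_gaussian(vol, fwhm = -1), "non-negative")
})

test_that("kendall_w agrees with the brute-force rank-sum oracle", {
  set.seed(33)
  for (i in 1:200) {
    K <- sample(2:5, 1); n <- sample(3:10, 1)
    S <- matrix(rnorm(K * n), K, n)
    expect_lt(abs(kendall_w(S, warn_ties = FALSE) - brute_kendall_w(S)), 1e-12)
  }
  # rank-sum conservation: sum_i R_i = n K (n+1) / 2
  S <- matrix(rnorm(4 * 9), 4, 9)
  Ri <- rowSums(apply(S, 1, rank))
  expect_equal(sum(Ri), 9 * 4 * 10 / 2)
})

test_that("kendall_w boundary cases and invariances", {
  mono <- matrix(rep(cumsum(runif(12, 0.1, 1)), 5), 5, 12, byrow = TRUE)
  expect_identical(kendall_w(mono), 1)
  rev2 <- rbind(1:9, 9:1)
  expect_identical(kendall_w(rev2), 0)
  expect_error(kendall_w(matrix(1:5, 1, 5)), "K >= 2")
  expect_error(kendall_w(matrix(1:2, 2, 1)), "2 time points")
  # invariant under per-voxel strictly monotone transforms
  set.seed(4)
  S <- matrix(rnorm(3 * 20), 3, 20)
  S2 <- rbind(exp(S[1, ]), S[2, ]^3, 5 * S[3, ] - 2)
  expect_lt(abs(kendall_w(S) - kendall_w(S2)), 1e-12)
  # ties are flagged
  expect_warning(kendall_w(rbind(rep(1:2, 5), rnorm(10))), "tied")
})

test_that("reho_map: perfect concordance, null level, and coherence ordering", {
  mask <- full_mask(c(6, 6, 6))
  # identical strictly monotone series everywhere -> W = 1 on the full mask
  mono <- cumsum(runif(40, 0.1, 1))
  run <- bold_run(array(rep(mono, each = 216), c(6, 6, 6, 40)), 2, "S01", "hunger")
  m <- reho_map(run, mask)
  expect_true(all(abs(m$values[mask] - 1) < 1e-12))

  # white-noise null: interior (full K = 27) map mean matches the MC oracle
  set.seed(55)
  oracle <- replicate(300, kendall_w(matrix(rnorm(27 * 64), 27, 64), warn_ties = FALSE))
  mm <- vapply(1:3, function(s) {
    r <- white_noise_run(c(6, 6, 6), 64, seed = 60 + s)
    mean(reho_map(r, mask)$values[2:5, 2:5, 2:5])
  }, numeric(1))
  expect_lt(abs(mean(mm) - mean(oracle)), 0.004)

  # a coherent region out-ranks an incoherent one in every seed of a batch
  p <- make_toy_parcellation(c(6, 6, 6), 8)
  wins <- vapply(1:10, function(s) {
    set.seed(700 + s)
    lat <- rnorm(48)
    dat <- array(rnorm(216 * 48, sd = 1), c(6, 6, 6, 48))
    hi <- which(p$labels == 2)
    for (t in seq_len(48)) {
      slab <- dat[, , , t]; slab[hi] <- slab[hi] + 2 * lat[t]
      dat[, , , t] <- slab
    }
    r <- bold_run(dat, 2, "S01", "hunger")
    m <- reho_map(r, mask)
    mean(m$values[p$labels == 2]) > mean(m$values[p$labels == 3])
  }, logical(1))
  expect_true(all(wins))
})

test_that("dc_map: analytic degree cases and the null tail of Pearson r", {
  mask <- full_mask(c(3, 3, 3))
  set.seed(8)
  noisy <- rnorm(80)
  # identical copies -> r = 1 off-diagonal -> degree N - 1 everywhere
  m <- dc_map(replicated_run(noisy, c(3, 3, 3)), mask)
  expect_true(all(m$values[mask] == 26))

  # two anti-correlated groups: within r = 1, across r = -1
  base <- rnorm(60)
  arr <- array(0, c(3, 3, 3, 60))
  idx <- array(seq_len(27), c(3, 3, 3))
  grpA <- idx <= 13
  for (t in 1:60) {
    slab <- array(0, c(3, 3, 3))
    slab[grpA] <- base[t]; slab[!grpA] <- -base[t]
    arr[, , , t] <- slab
  }
  m2 <- dc_map(bold_run(arr, 2, "S01", "hunger"), mask)
  expect_true(all(m2$values[grpA] == 13 - 1))
  expect_true(all(m2$values[!grpA] == 14 - 1))

  # independent Gaussian voxels: mean degree ~ (N-1) P(r >= 0.25 | null)
  expected <- 215 * null_p_r_at_least(0.25, 170)
  dd <- vapply(1:5, function(s)
    mean(dc_map(white_noise_run(c(6, 6, 6), 170, seed = 80 + s),
                full_mask(c(6, 6, 6)))$values[full_mask(c(6, 6, 6))]), numeric(1))
  expect_lt(abs(mean(dd) - expected), 3 * sd(dd) / sqrt(5) + 0.03)

  # zero-variance voxel is dropped from the mask with a warning
  arr2 <- array(rnorm(27 * 40), c(3, 3, 3, 40)); arr2[1, 1, 1, ] <- 7
  expect_warning(m3 <- dc_map(bold_run(arr2, 2, "s", "hunger"), mask), "zero-variance")
  expect_false(m3$mask[1, 1, 1])

  # degree symmetry: the total degree is even
  m4 <- dc_map(white_noise_run(c(4, 4, 4), 60, seed = 3), full_mask(c(4, 4, 4)),
               r_threshold = 0.1)
  expect_identical(sum(m4$values[m4$mask]) %% 2, 0)
})

test_that("dc_map is invariant under positive per-voxel affine rescaling", {
  run <- white_noise_run(c(3, 3, 3), 50, seed = 14)
  mask <- full_mask(c(3, 3, 3))
  m1 <- dc_map(run, mask)
  run2 <- run
  sc <- matrix(runif(27, 0.5, 4), 27)
  off <- matrix(rnorm(27, sd = 10), 27)
  run2$data <- array(sweep(sweep(matrix(run$data, 27), 1, sc, `*`), 1, off, `+`),
                     dim(run$data))
  m2 <- dc_map(run2, mask)
  expect_identical(m1$values, m2$values)
})

test_that("falff_map: on-bin sinusoids, the white-noise bin-count level, scaling invariance", {
  mask <- full_mask(c(3, 3, 3))
  f1 <- falff_map(replicated_run(on_bin_sinusoid(17)), mask)   # 0.05 Hz
  expect_true(all(abs(f1$values[mask] - 1) < 1e-10))
  f2 <- falff_map(replicated_run(on_bin_sinusoid(68)), mask)   # 0.20 Hz
  expect_true(all(abs(f2$values[mask]) < 1e-10))

  # white noise: E[fALFF] ~ (#bins in [0.01,0.08]) / (#bins in (0,0.25]) = 24/85
  kk <- 1:85; fr <- kk / 340
  n_in <- sum(fr >= 0.01 & fr <= 0.08); n_tot <- length(kk)
  expect_identical(c(n_in, n_tot), c(24L, 85L))
  big <- white_noise_run(c(22, 22, 22), 170, seed = 5)
  fm <- falff_map(big, full_mask(c(22, 22, 22)))
  expect_lt(abs(mean(fm$values) - n_in / n_tot), 0.02)

  # invariant under global positive scaling
  run <- white_noise_run(c(3, 3, 3), 64, seed = 2)
  a <- falff_map(run, mask)
  run$data <- run$data * 37.5
  b <- falff_map(run, mask)
  expect_equal(a$values, b$values, tolerance = 1e-12)

  # 0/0 guard on an all-zero series
  arr <- array(rnorm(27 * 64), c(3, 3, 3, 64)); arr[2, 2, 2, ] <- 0
  expect_warning(z <- falff_map(bold_run(arr, 2, "s", "h"), mask), "all-zero")
  expect_identical(z$values[2, 2, 2], 0)
})

test_that("roi_means matches a brute-force aggregation and validates regions", {
  p <- make_toy_parcellation(c(6, 6, 6), 8)
  expect_equal(as.numeric(roi_means(voxel_map(array(2.5, c(6, 6, 6)), p$mask, "falff"), p)),
               rep(2.5, 8))
  expect_equal(as.numeric(roi_means(voxel_map(array(as.numeric(p$labels), c(6, 6, 6)),
                                              p$mask, "falff"), p)),
               as.numeric(1:8))
  set.seed(6)
  vals <- array(rnorm(216), c(6, 6, 6))
  vm <- voxel_map(vals, p$mask, "reho")
  expect_equal(as.numeric(roi_means(vm, p)),
               brute_roi_means(vals, p$labels, 8), tolerance = 1e-12)
  # region with no masked voxels is a named error
  vm2 <- vm; vm2$mask[p$labels == 3] <- FALSE
  vm2$values[!vm2$mask] <- NA
  expect_error(roi_means(vm2, p), "region 3")
})

test_that("the per-feature pipeline order produces condition-separating tables", {
  p <- make_toy_parcellation(c(6, 6, 6), 8)
  sim <- simulate_bold_cohort(p, cohort_spec(n_subjects = 8, n_timepoints = 64, tr = 2),
                              effect_spec(informative_regions = 2,
                                          effect_kind = "amplitude", effect_size = 2.5),
                              seed = 19)
  tbl <- extract_feature_table(sim$runs, p, "falff", fwhm = 6, voxel_size = 3)
  expect_identical(dim(tbl$X), c(16L, 8L))
  expect_identical(tbl$feature_kind, "falff")
  h <- tbl$condition == "hunger"
  dm <- colMeans(tbl$X[h, ]) - colMeans(tbl$X[!h, ])
  expect_gt(dm[2], max(abs(dm[-2])))
  # fALFF values are ratios in [0, 1]
  expect_true(all(tbl$X >= 0 & tbl$X <= 1))
})
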