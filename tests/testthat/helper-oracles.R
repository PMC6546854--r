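# Independent oracles and fixture builders shared by the test files.
# Everything here is brute force / first principles, deliberately not reusing
# the package's own implementation paths.

# Kendall's W from the definition: average ranks computed by counting, then
# the normalized variance of rank sums 12*S / (K^2 (n^3 - n)).
brute_kendall_w <- function(series) {
  K <- nrow(series); n <- ncol(series)
  R <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(K)) {
      v <- series[j, ]
      # average rank of time point i within voxel j by counting
      R[i] <- R[i] + sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
  }
  S <- sum((R - mean(R))^2)
  12 * S / (K^2 * (n^3 - n))
}

# mean over each region of a map by an explicit triple loop
brute_roi_means <- function(values, labels, n_regions) {
  out <- numeric(n_regions); cnt <- integer(n_regions)
  d <- dim(labels)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    l <- labels[x, y, z]
    if (l > 0 && is.finite(values[x, y, z])) {
      out[l] <- out[l] + values[x, y, z]
      cnt[l] <- cnt[l] + 1L
    }
  }
  out / cnt
}

# exact null tail probability of a Pearson correlation at a threshold
null_p_r_at_least <- function(thr, n) {
  stats::pt(thr * sqrt(n - 2) / sqrt(1 - thr^2), df = n - 2, lower.tail = FALSE)
}

# paired random feature table built from raw normals (independent of the
# package's generator); region `signal` gets a mean shift of `delta`
random_table <- function(seed, n_subjects = 10, n_regions = 8,
                         signal = integer(), delta = 0) {
  set.seed(seed)
  n <- 2 * n_subjects
  X <- matrix(rnorm(n * n_regions), n, n_regions)
  y <- rep(c(1, -1), n_subjects)
  for (r in signal) X[, r] <- X[, r] + delta / 2 * y
  feature_table(X,
                condition = factor(ifelse(y > 0, "hunger", "satiety"),
                                   levels = c("hunger", "satiety")),
                subject = rep(sprintf("S%02d", seq_len(n_subjects)), each = 2))
}

# single-voxel-series run replicated over a small grid
replicated_run <- function(series, grid = c(3, 3, 3), tr = 2) {
  bold_run(array(rep(series, each = prod(grid)), c(grid, length(series))),
           tr = tr, subject_id = "S01", condition = "hunger")
}

white_noise_run <- function(grid, n, tr = 2, seed = 1) {
  set.seed(seed)
  bold_run(array(rnorm(prod(grid) * n), c(grid, n)), tr, "S01", "hunger")
}

on_bin_sinusoid <- function(k, n = 170, tr = 2) {
  sin(2 * pi * (k / (n * tr)) * (0:(n - 1)) * tr)
}

full_mask <- function(grid) array(TRUE, grid)

`%||%` <- function(a, b) if (is.null(a)) b else a
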