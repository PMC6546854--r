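# Voxel-wise feature maps (ReHo, DC, fALFF) and the band-pass / smoothing
# stages around them. All spectral definitions use bin centres k/(n*tr) Hz.

# zero-filled shift of the first three dimensions of a 3D or 4D array
shift_xyz <- function(a, off) {
  d <- dim(a)
  src <- Map(function(n, o) seq_len(n) + o, d[1:3], off)
  keep <- Map(function(s, n) s >= 1 & s <= n, src, d[1:3])
  b <- array(0, d)
  to <- lapply(keep, which)
  from <- Map(function(s, k) s[k], src, keep)
  if (length(d) == 3) b[to[[1]], to[[2]], to[[3]]] <- a[from[[1]], from[[2]], from[[3]]]
  else b[to[[1]], to[[2]], to[[3]], ] <- a[from[[1]], from[[2]], from[[3]], ]
  b
}

#' Construct a voxel map
#'
#' @param values 3D numeric array, finite exactly on the mask (NA elsewhere).
#' @param mask 3D logical array.
#' @param feature_kind one of `"reho"`, `"dc"`, `"falff"` (or another tag).
#' @return object of class `voxel_map`.
#' @export
voxel_map <- function(values, mask, feature_kind) {
  stopifnot(is.array(values), length(dim(values)) == 3,
            identical(dim(values), dim(mask)))
  if (any(!is.finite(values[mask])))
    stop("voxel map has non-finite values inside the mask")
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask, feature_kind = feature_kind),
            class = "voxel_map")
}

#' @export
print.voxel_map <- function(x, ...) {
  cat(sprintf("voxel_map [%s]: %s grid, %d masked voxels, range %.4g..%.4g\n",
              x$feature_kind, paste(dim(x$values), collapse = "x"),
              sum(x$mask), min(x$values[x$mask]), max(x$values[x$mask])))
  invisible(x)
}

#' Ideal temporal band-pass filter
#'
#' Per voxel: removes the series mean, zeroes every Fourier bin whose centre
#' frequency `min(k, n-k)/(n*tr)` lies outside `[f_lo, f_hi]`, and inverse
#' transforms. An ideal spectral mask (rather than an IIR design) matches the
#' frequency-domain feature definitions and is exactly invertible on on-bin
#' sinusoids.
#'
#' @param run a [bold_run].
#' @param f_lo,f_hi band edges in Hz; `0 <= f_lo < f_hi <= Nyquist`.
#' @return the filtered [bold_run] (same dimensions and TR).
#' @export
bandpass <- function(run, f_lo = 0.01, f_hi = 0.08) {
  stopifnot(inherits(run, "bold_run"))
  nyq <- 1 / (2 * run$tr)
  if (f_lo < 0 || f_lo >= f_hi || f_hi > nyq + 1e-12)
    stop(sprintf("band [%g, %g] Hz must satisfy 0 <= f_lo < f_hi <= Nyquist (%g Hz)",
                 f_lo, f_hi, nyq))
  d <- dim(run$data); nt <- d[4]
  m <- matrix(run$data, ncol = nt)
  m <- m - rowMeans(m)
  Fm <- mvfft(t(m))
  k <- 0:(nt - 1)
  fk <- pmin(k, nt - k) / (nt * run$tr)
  Fm[fk < f_lo | fk > f_hi, ] <- 0
  run$data <- array(t(Re(mvfft(Fm, inverse = TRUE)) / nt), dim = d)
  run
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# separable 3D convolution, zero padding, optional renormalisation weights
conv_gauss3 <- function(a, k) {
  r <- (length(k) - 1) / 2
  for (ax in 1:3) {
    out <- array(0, dim(a))
    for (o in -r:r) {
      off <- c(0, 0, 0); off[ax] <- o
      out <- out + k[o + r + 1] * shift_xyz(a, off)
    }
    a <- out
  }
  a
}

#' Spatial Gaussian smoothing
#'
#' Convolves with a separable Gaussian of the given full width at half
#' maximum; `sigma = fwhm / (2 sqrt(2 ln 2)) / voxel_size` voxels per axis.
#' Runs are smoothed per time point; voxel maps are smoothed within their mask
#' (mask-renormalised convolution, so support stays on the mask); volumes are
#' renormalised at the grid boundary so constants are preserved. `fwhm = 0` is
#' the identity.
#'
#' @param x a [bold_run], [voxel_map] or 3D numeric array.
#' @param fwhm full width at half maximum in mm (>= 0).
#' @param voxel_size isotropic voxel edge in mm (study value: 3 mm).
#' @return object of the same class and shape as `x`.
#' @export
smooth_gaussian <- function(x, fwhm = 6, voxel_size = 3) {
  if (fwhm < 0) stop("fwhm must be non-negative")
  if (fwhm == 0) return(x)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  k <- gaussian_kernel_1d(sigma)

  if (inherits(x, "bold_run")) {
    d <- dim(x$data)
    wt <- conv_gauss3(array(1, d[1:3]), k)
    for (t in seq_len(d[4]))
      x$data[, , , t] <- conv_gauss3(x$data[, , , t, drop = TRUE], k) / wt
    return(x)
  }
  if (inherits(x, "voxel_map")) {
    m <- array(as.numeric(x$mask), dim(x$values))
    v <- x$values; v[!x$mask] <- 0
    wt <- conv_gauss3(m, k)
    out <- conv_gauss3(v, k)
    vals <- array(NA_real_, dim(x$values))
    vals[x$mask] <- out[x$mask] / wt[x$mask]
    x$values <- vals
    return(x)
  }
  stopifnot(is.array(x), length(dim(x)) == 3)
  conv_gauss3(x, k) / conv_gauss3(array(1, dim(x)), k)
}

#' Kendall's coefficient of concordance of a voxel cluster
#'
#' Ranks each voxel's series over time (average ranks for ties), forms the
#' rank sums \eqn{R_i = \sum_j r_{ij}} over the K voxels at each of the n time
#' points, and returns
#' \deqn{W = \frac{\sum_i R_i^2 - n \bar{R}^2}{\frac{1}{12} K^2 (n^3 - n)},}
#' the concordance of the K series, in `[0, 1]` (clipped only against
#' floating-point overshoot of at most 1e-12). No tie-correction term is
#' applied; a warning flags inputs where more than 10% of a series' values are
#' tied.
#'
#' @param series numeric matrix, one row per voxel (K x n).
#' @param warn_ties warn when ties are frequent.
#' @return scalar concordance in `[0, 1]`.
#' @export
kendall_w <- function(series, warn_ties = TRUE) {
  stopifnot(is.matrix(series))
  K <- nrow(series); n <- ncol(series)
  if (K < 2) stop("Kendall's W needs at least 2 voxels (K >= 2)")
  if (n < 2) stop("Kendall's W needs at least 2 time points")
  ranks <- apply(series, 1, rank)  # n x K
  if (warn_ties) {
    tie_frac <- 1 - apply(series, 1, function(v) length(unique(v))) / n
    if (any(tie_frac > 0.1))
      warning(sprintf("%d of %d series have more than 10%% tied values; no tie correction is applied",
                      sum(tie_frac > 0.1), K))
  }
  Ri <- rowSums(ranks)
  W <- (sum(Ri^2) - n * mean(Ri)^2) / (K^2 * (n^3 - n) / 12)
  if (W > 1 && W <= 1 + 1e-12) W <- 1
  if (W < 0 && W >= -1e-12) W <- 0
  W
}

#' Regional homogeneity map
#'
#' For every masked voxel, Kendall's W over the 3x3x3 cluster centred there,
#' using only in-mask, in-volume neighbours (the cluster size K is the actual
#' neighbour count, at most 27; the full-cluster study value is K = 27). The
#' concordance value is written to the centre voxel. The run is expected to be
#' band-passed already (pipeline order).
#'
#' @param run a [bold_run].
#' @param mask 3D logical array.
#' @return a [voxel_map] of kind `"reho"`; masked voxels with no in-mask
#'   neighbour (K < 2) are set to NA with a warning.
#' @export
reho_map <- function(run, mask) {
  stopifnot(inherits(run, "bold_run"), is.array(mask))
  d4 <- dim(run$data); d <- d4[1:3]; nt <- d4[4]
  stopifnot(identical(dim(mask), d))
  if (!any(mask)) stop("empty mask")

  V <- prod(d)
  m <- matrix(run$data, ncol = nt)
  mi <- which(mask)
  rk <- matrix(0, V, nt)
  rk[mi, ] <- t(apply(m[mi, , drop = FALSE], 1, rank))

  tie_frac <- 1 - apply(m[mi, , drop = FALSE], 1, function(v) length(unique(v))) / nt
  if (any(tie_frac > 0.1))
    warning(sprintf("%d of %d masked voxels have more than 10%% tied values; no tie correction is applied",
                    sum(tie_frac > 0.1), length(mi)))

  rka <- array(rk, c(d, nt))
  mnum <- array(as.numeric(mask), d)
  S <- array(0, c(d, nt))
  Kv <- array(0, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    S <- S + shift_xyz(rka, c(dx, dy, dz))
    Kv <- Kv + shift_xyz(mnum, c(dx, dy, dz))
  }

  Smat <- matrix(S, V, nt)
  s1 <- rowSums(Smat); s2 <- rowSums(Smat^2)
  Kvv <- as.vector(Kv)
  W <- (s2 - s1^2 / nt) / (Kvv^2 * (nt^3 - nt) / 12)
  W[W > 1 & W <= 1 + 1e-12] <- 1
  W[W < 0 & W >= -1e-12] <- 0

  vals <- array(NA_real_, d)
  ok <- mask & Kv >= 2
  if (any(mask & !ok)) {
    warning(sprintf("%d masked voxel(s) have no in-mask neighbour (K < 2); set to NA",
                    sum(mask & !ok)))
  }
  vals[ok] <- W[as.vector(ok)]
  out_mask <- ok
  voxel_map(vals, out_mask, "reho")
}

#' Degree centrality map
#'
#' Pearson correlation between every pair of masked voxel time series; the
#' degree of a voxel is the number of *other* voxels whose correlation with it
#' is at or above `r_threshold` (the diagonal self-connection is excluded, so
#' degrees run 0..N-1). The run is expected to be smoothed and band-passed
#' (pipeline order). Zero-variance voxels cannot enter a correlation and are
#' excluded from the returned map's mask with a warning.
#'
#' @param run a [bold_run].
#' @param mask 3D logical array.
#' @param r_threshold correlation cutoff (study value 0.25).
#' @return a [voxel_map] of kind `"dc"` with non-negative integer values.
#' @export
dc_map <- function(run, mask, r_threshold = 0.25) {
  stopifnot(inherits(run, "bold_run"), is.array(mask))
  d4 <- dim(run$data); d <- d4[1:3]; nt <- d4[4]
  stopifnot(identical(dim(mask), d))
  if (!any(mask)) stop("empty mask")

  mi <- which(mask)
  ts <- t(matrix(run$data, ncol = nt)[mi, , drop = FALSE])  # nt x N
  sds <- sqrt(colSums(sweep(ts, 2, colMeans(ts))^2))
  zero <- sds < 1e-12
  if (any(zero)) {
    warning(sprintf("excluding %d zero-variance voxel(s) from the mask", sum(zero)))
    mask[mi[zero]] <- FALSE
    mi <- mi[!zero]
    ts <- ts[, !zero, drop = FALSE]
  }
  if (length(mi) < 2) stop("fewer than 2 usable voxels in the mask")
  r <- cor(ts)
  deg <- colSums(r >= r_threshold) - 1L
  vals <- array(NA_real_, d)
  vals[mi] <- as.numeric(deg)
  voxel_map(vals, mask, "dc")
}

#' Fractional amplitude of low-frequency fluctuations map
#'
#' Per masked voxel: the amplitude spectrum (square root of the power
#' spectrum) of the demeaned series; fALFF is the summed amplitude over bins
#' with centre frequency in the closed low band divided by the summed
#' amplitude over all bins in the half-open full band `(0, Nyquist]`. The
#' zero-frequency bin is excluded from both sums unless `include_dc_bin` is
#' set. The run must NOT be band-passed (the ratio is the point of the
#' measure).
#'
#' @param run a [bold_run].
#' @param mask 3D logical array.
#' @param low_band numerator band in Hz (study value `c(0.01, 0.08)`).
#' @param full_band denominator band in Hz (defaults to `(0, Nyquist]`).
#' @param include_dc_bin also count the k = 0 bin in the sums (off by
#'   default; the series is demeaned so the bin is numerically ~0 anyway).
#' @return a [voxel_map] of kind `"falff"` with values in `[0, 1]`; an
#'   all-zero series yields 0 with a warning.
#' @export
falff_map <- function(run, mask, low_band = c(0.01, 0.08), full_band = NULL,
                      include_dc_bin = FALSE) {
  stopifnot(inherits(run, "bold_run"), is.array(mask))
  d4 <- dim(run$data); d <- d4[1:3]; nt <- d4[4]
  stopifnot(identical(dim(mask), d))
  if (!any(mask)) stop("empty mask")
  nyq <- 1 / (2 * run$tr)
  full_band <- full_band %||% c(0, nyq)
  if (low_band[2] > nyq + 1e-12)
    stop(sprintf("low band upper edge %g Hz exceeds Nyquist (%g Hz)", low_band[2], nyq))

  mi <- which(mask)
  ts <- t(matrix(run$data, ncol = nt)[mi, , drop = FALSE])
  ts <- sweep(ts, 2, colMeans(ts))
  A <- abs(mvfft(ts))
  kk <- seq_len(floor(nt / 2))
  fr <- kk / (nt * run$tr)
  num_rows <- 1 + kk[fr >= low_band[1] & fr <= low_band[2]]
  den_rows <- 1 + kk[fr > full_band[1] & fr <= full_band[2]]
  if (include_dc_bin) {
    den_rows <- c(1, den_rows)
    if (low_band[1] <= 0) num_rows <- c(1, num_rows)
  }
  num <- colSums(A[num_rows, , drop = FALSE])
  den <- colSums(A[den_rows, , drop = FALSE])
  vals <- array(NA_real_, d)
  bad <- den <= 0
  if (any(bad))
    warning(sprintf("%d voxel(s) with an all-zero series; fALFF set to 0", sum(bad)))
  v <- ifelse(bad, 0, num / den)
  vals[mi] <- v
  voxel_map(vals, mask, "falff")
}

#' Aggregate a voxel map into a region vector
#'
#' Arithmetic mean of the map values over each region's masked voxels, in the
#' order of the parcellation's region table.
#'
#' @param map a [voxel_map].
#' @param parcellation a [parcellation] on the same grid.
#' @return named numeric vector of class `region_vector` (names are region
#'   names; `region_labels` and `feature_kind` attached as attributes).
#' @export
roi_means <- function(map, parcellation) {
  stopifnot(inherits(map, "voxel_map"), inherits(parcellation, "parcellation"),
            identical(dim(map$values), dim(parcellation$labels)))
  tab <- parcellation$region_table
  vals <- vapply(seq_len(nrow(tab)), function(i) {
    vox <- parcellation$labels == tab$label[i] & map$mask
    if (!any(vox))
      stop(sprintf("region %d (%s) has no masked voxels", tab$label[i], tab$name[i]))
    mean(map$values[vox])
  }, numeric(1))
  structure(stats::setNames(vals, tab$name),
            region_labels = tab$label, feature_kind = map$feature_kind,
            class = "region_vector")
}

#' Extract a feature table from a cohort of runs
#'
#' Applies the per-feature pipeline order around each map: ReHo = band-pass,
#' ReHo map, then smoothing of the *map*; DC = smoothing of the run, band-pass,
#' DC map; fALFF = smoothing of the run, fALFF map with no band-pass. Region
#' means are then collected into a samples x regions [feature_table].
#'
#' @param runs list of [bold_run] (two per subject in the paired design).
#' @param parcellation a [parcellation] on the runs' grid.
#' @param feature `"reho"`, `"dc"` or `"falff"`.
#' @param fwhm,voxel_size smoothing kernel (mm); `fwhm = 0` disables smoothing.
#' @param band temporal band in Hz for the band-passed features.
#' @param r_threshold correlation cutoff for degree centrality.
#' @param include_dc_bin see [falff_map].
#' @param verbose log one line per run.
#' @return a [feature_table] with `feature_kind` set.
#' @export
extract_feature_table <- function(runs, parcellation,
                                  feature = c("reho", "dc", "falff"),
                                  fwhm = 6, voxel_size = 3,
                                  band = c(0.01, 0.08), r_threshold = 0.25,
                                  include_dc_bin = FALSE, verbose = FALSE) {
  feature <- match.arg(feature)
  stopifnot(length(runs) >= 2)
  mask <- parcellation$mask
  rows <- lapply(runs, function(run) {
    t0 <- Sys.time()
    mp <- switch(feature,
      reho = {
        r1 <- bandpass(run, band[1], band[2])
        smooth_gaussian(reho_map(r1, mask), fwhm, voxel_size)
      },
      dc = {
        r1 <- bandpass(smooth_gaussian(run, fwhm, voxel_size), band[1], band[2])
        dc_map(r1, mask, r_threshold)
      },
      falff = {
        r1 <- smooth_gaussian(run, fwhm, voxel_size)
        falff_map(r1, mask, low_band = band, include_dc_bin = include_dc_bin)
      })
    stage_log(verbose, paste0("extract_", feature), t0,
              sprintf("subject=%s condition=%s", run$subject_id, run$condition))
    roi_means(mp, parcellation)
  })
  X <- do.call(rbind, lapply(rows, as.numeric))
  feature_table(X,
                condition = vapply(runs, `[[`, character(1), "condition"),
                subject = vapply(runs, `[[`, character(1), "subject_id"),
                region_labels = parcellation$region_table$label,
                region_names = parcellation$region_table$name,
                feature_kind = feature)
}
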