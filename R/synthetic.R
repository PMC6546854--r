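#' Cohort specification for the synthetic BOLD generator
#'
#' Defaults mirror the study design this package emulates: 24 subjects, each
#' scanned once per metabolic condition, 170 retained time points per run at a
#' repetition time of 2 s (Nyquist 0.25 Hz).
#'
#' @param n_subjects number of subjects (>= 2); each contributes one run per
#'   condition.
#' @param n_timepoints time points per run (>= 16).
#' @param tr repetition time in seconds.
#' @param conditions exactly two condition labels; the first is the positive
#'   class downstream.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 24, n_timepoints = 170, tr = 2.0,
                        conditions = c("hunger", "satiety")) {
  stopifnot(n_subjects >= 2, n_timepoints >= 16, tr > 0)
  if (length(conditions) != 2 || anyDuplicated(conditions))
    stop("exactly two distinct condition labels are required")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_timepoints = as.integer(n_timepoints),
                 tr = tr, conditions = as.character(conditions)),
            class = "cohort_spec")
}

#' Condition-effect specification for the synthetic BOLD generator
#'
#' Describes where and how the two conditions differ. `effect_kind` names the
#' feature the effect targets: `"amplitude"` modulates the band-limited latent
#' signal amplitude (raises fALFF), `"local_coherence"` modulates the coupling
#' of a region's voxels to their shared latent (raises ReHo), and
#' `"global_coupling"` modulates the weight of a cross-region shared component
#' (raises degree centrality). `effect_size` is the requested standardized
#' mean difference (Cohen's d) of the region-mean feature between conditions;
#' the generator calibrates its internal modulation by pilot simulation so the
#' realized difference approximates this d.
#'
#' @param informative_regions integer region labels carrying the effect.
#' @param effect_kind one of `"amplitude"`, `"local_coherence"`,
#'   `"global_coupling"`.
#' @param effect_size requested Cohen's d per informative region (finite).
#' @param subject_rho within-subject correlation of the paired measurements,
#'   in `[0, 1)`.
#' @param noise_sd standard deviation of the white voxel noise (a.u.).
#' @param coupling baseline coupling weight of voxels to their region latent.
#' @param global_base baseline weight of the cross-region shared component
#'   (used by the `global_coupling` kind).
#' @param n_sinusoids number of sinusoids summed into each latent signal.
#' @param freq_band frequency band (Hz) the latent sinusoids are drawn from.
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(informative_regions = integer(),
                        effect_kind = c("amplitude", "local_coherence", "global_coupling"),
                        effect_size = 0, subject_rho = 0.5, noise_sd = 1,
                        coupling = 1, global_base = 0.4, n_sinusoids = 3,
                        freq_band = c(0.01, 0.08)) {
  effect_kind <- match.arg(effect_kind)
  if (!is.finite(effect_size)) stop("effect_size must be finite")
  if (subject_rho < 0 || subject_rho >= 1) stop("subject_rho must be in [0, 1)")
  stopifnot(noise_sd > 0, n_sinusoids >= 1, length(freq_band) == 2,
            freq_band[1] < freq_band[2])
  structure(list(informative_regions = as.integer(informative_regions),
                 effect_kind = effect_kind, effect_size = effect_size,
                 subject_rho = subject_rho, noise_sd = noise_sd,
                 coupling = coupling, global_base = global_base,
                 n_sinusoids = as.integer(n_sinusoids), freq_band = freq_band),
            class = "effect_spec")
}

#' Construct a BOLD run object
#'
#' @param data 4D numeric array (x, y, z, t), BOLD amplitude in arbitrary units.
#' @param tr repetition time in seconds.
#' @param subject_id subject identifier.
#' @param condition condition label.
#' @return object of class `bold_run`.
#' @export
bold_run <- function(data, tr, subject_id, condition) {
  stopifnot(is.array(data), length(dim(data)) == 4, tr > 0)
  if (dim(data)[4] < 16) stop("a BOLD run needs at least 16 time points")
  if (!all(is.finite(data))) stop("BOLD data contain non-finite values")
  structure(list(data = data, tr = tr,
                 subject_id = as.character(subject_id),
                 condition = as.character(condition)),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bold_run: subject %s, condition %s, %dx%dx%d grid, %d time points, TR %.3g s\n",
              x$subject_id, x$condition, d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

# ---- direct feature-table generator -----------------------------------------

#' Simulate a samples x regions feature table with known informative regions
#'
#' Generates the paired two-condition design directly on the region-vector
#' scale: per subject, the two condition rows share a subject-level random
#' effect with correlation `subject_rho`; every region has unit marginal
#' standard deviation; informative regions get a between-condition mean shift
#' of `effect_size` standard deviations (+d/2 for the first condition, -d/2
#' for the second). Non-informative regions are pure noise.
#'
#' @param n_subjects number of subjects (rows = 2 * n_subjects).
#' @param n_regions number of regions (columns).
#' @param informative_regions integer labels in `1..n_regions`.
#' @param effect_size Cohen's d of the condition shift in informative regions.
#' @param subject_rho within-subject correlation, in `[0, 1)`.
#' @param seed integer seed; the output is bit-identical given the same
#'   arguments and seed.
#' @param conditions two condition labels.
#' @return list with elements `table` (a [feature_table]) and `truth`
#'   (ground-truth record: informative regions, requested and realized effect
#'   sizes, seed and parameter echo).
#' @export
simulate_feature_table <- function(n_subjects = 24, n_regions = 90,
                                   informative_regions = integer(),
                                   effect_size = 0, subject_rho = 0.5,
                                   seed = 1L,
                                   conditions = c("hunger", "satiety")) {
  stopifnot(n_subjects >= 2, n_regions >= 1)
  informative_regions <- as.integer(informative_regions)
  if (!is.finite(effect_size)) stop("effect_size must be finite")
  if (subject_rho < 0 || subject_rho >= 1) stop("subject_rho must be in [0, 1)")
  if (length(informative_regions) &&
      !all(informative_regions %in% seq_len(n_regions)))
    stop("informative_regions must be a subset of 1..n_regions")

  X <- with_seed(seed, {
    subj_eff <- matrix(rnorm(n_subjects * n_regions, sd = sqrt(subject_rho)),
                       n_subjects, n_regions)
    noise <- array(rnorm(2 * n_subjects * n_regions, sd = sqrt(1 - subject_rho)),
                   c(2, n_subjects, n_regions))
    x <- matrix(0, 2 * n_subjects, n_regions)
    for (s in seq_len(n_subjects)) {
      for (a in 1:2) {
        row <- 2 * (s - 1) + a
        x[row, ] <- subj_eff[s, ] + noise[a, s, ]
      }
    }
    shift <- ifelse(seq_len(2 * n_subjects) %% 2 == 1, effect_size / 2, -effect_size / 2)
    for (r in informative_regions) x[, r] <- x[, r] + shift
    x
  })

  condition <- factor(rep(conditions, n_subjects), levels = conditions)
  subject <- factor(rep(sprintf("S%02d", seq_len(n_subjects)), each = 2))
  tab <- feature_table(X, condition, subject)

  realized <- vapply(informative_regions, function(r) {
    a <- X[condition == conditions[1], r]
    b <- X[condition == conditions[2], r]
    (mean(a) - mean(b)) / sqrt((stats::var(a) + stats::var(b)) / 2)
  }, numeric(1))

  truth <- structure(list(informative_regions = informative_regions,
                          effect_kind = "mean_shift",
                          requested_d = effect_size,
                          realized_d = stats::setNames(realized,
                                                       as.character(informative_regions)),
                          seed = as.integer(seed),
                          params = list(n_subjects = n_subjects,
                                        n_regions = n_regions,
                                        subject_rho = subject_rho)),
                     class = "ground_truth")
  list(table = tab, truth = truth)
}

# ---- BOLD cohort generator --------------------------------------------------

# one standardized latent signal: sum of sinusoids inside the band
latent_signal <- function(n, tr, n_sin, band) {
  t_sec <- (seq_len(n) - 1) * tr
  f <- runif(n_sin, band[1], band[2])
  ph <- runif(n_sin, 0, 2 * pi)
  x <- rowSums(vapply(seq_len(n_sin),
                      function(h) sin(2 * pi * f[h] * t_sec + ph[h]),
                      numeric(n)))
  s <- sd(x)
  if (s < 1e-12) s <- 1
  (x - mean(x)) / s
}

# region-mean feature of one simulated region instance, per effect kind;
# used by the pilot calibration below
surrogate_feature <- function(kind, gain, es, n, tr, K = 27, n_bg = 162) {
  L <- latent_signal(n, tr, es$n_sinusoids, es$freq_band)
  noise <- matrix(rnorm(K * n, sd = es$noise_sd), K, n)
  if (kind %in% c("amplitude", "local_coherence")) {
    ts <- sweep(noise, 2, gain * es$coupling * L, `+`)
    if (kind == "amplitude") {
      tv <- t(ts)                                # n x K, one column per voxel
      a <- abs(mvfft(sweep(tv, 2, colMeans(tv))))
      kk <- seq_len(floor(n / 2))
      fr <- kk / (n * tr)
      num <- colSums(a[1 + kk[fr >= es$freq_band[1] & fr <= es$freq_band[2]], , drop = FALSE])
      den <- colSums(a[1 + kk, , drop = FALSE])
      mean(num / den)
    } else {
      kendall_w(ts)
    }
  } else {  # global_coupling: count connections to background voxels
    G <- latent_signal(n, tr, es$n_sinusoids, es$freq_band)
    ts <- sweep(noise, 2, es$coupling * L + gain * es$global_base * G, `+`)
    n_bg_regions <- max(1L, n_bg %/% K)
    bg <- do.call(rbind, lapply(seq_len(n_bg_regions), function(i) {
      Lb <- latent_signal(n, tr, es$n_sinusoids, es$freq_band)
      sweep(matrix(rnorm(K * n, sd = es$noise_sd), K, n), 2,
            es$coupling * Lb + es$global_base * G, `+`)
    }))
    r <- cor(t(ts), t(bg))
    mean(rowSums(r >= 0.25))
  }
}

# Pilot calibration: find the condition multiplier of the targeted parameter
# whose region-mean feature shift is `d` pooled standard deviations. Monotone
# interpolation on a multiplier grid; each grid point is a Monte-Carlo
# estimate that includes the subject/run gain variability used in the real
# generator, so the realized (marginal) d matches the request.
calibrate_modulation <- function(es, n, tr, sigma_log, reps = 200) {
  d <- abs(es$effect_size)
  if (d == 0) return(1)
  grid <- c(1, 1.25, 1.5, 2, 3, 5, 8)
  draw <- function(mult) {
    vapply(seq_len(reps), function(i) {
      gain <- mult * exp(rnorm(1, 0, sigma_log))
      surrogate_feature(es$effect_kind, gain, es, n, tr)
    }, numeric(1))
  }
  base <- draw(1)
  mu0 <- mean(base); v0 <- stats::var(base)
  dd <- vapply(grid, function(m) {
    if (m == 1) return(0)
    x <- draw(m)
    (mean(x) - mu0) / sqrt((stats::var(x) + v0) / 2)
  }, numeric(1))
  dd <- cummax(dd)  # enforce monotonicity against Monte-Carlo wiggle
  if (d >= max(dd)) {
    warning(sprintf("requested effect size %.3g exceeds the reachable range (max ~%.3g); using the largest modulation",
                    d, max(dd)))
    return(grid[length(grid)])
  }
  exp(stats::approx(dd, log(grid), xout = d, ties = "ordered")$y)
}

#' Simulate a two-condition BOLD cohort with known ground truth
#'
#' Every run is built from region-wise latent low-frequency signals (sums of
#' sinusoids with frequencies drawn inside `freq_band`, random phases), shared
#' by the region's voxels with coupling weight `coupling`, plus white voxel
#' noise. The condition modulates, in informative regions only, the parameter
#' named by `effect_kind`; the modulation strength is calibrated by pilot
#' simulation so that the between-condition difference of the targeted
#' region-mean feature is approximately `effect_size` pooled standard
#' deviations. A subject-level log-normal gain shared by a subject's two runs
#' induces the within-subject correlation.
#'
#' @param parcellation a [parcellation].
#' @param cohort a [cohort_spec].
#' @param effects an [effect_spec].
#' @param seed integer seed; output is bit-identical given the same inputs.
#' @return list with `runs` (list of [bold_run], two per subject) and `truth`
#'   (ground-truth record with the calibrated modulation and parameter echo).
#' @export
simulate_bold_cohort <- function(parcellation, cohort = cohort_spec(),
                                 effects = effect_spec(), seed = 1L) {
  stopifnot(inherits(parcellation, "parcellation"),
            inherits(cohort, "cohort_spec"), inherits(effects, "effect_spec"))
  labs <- parcellation$region_table$label
  if (length(effects$informative_regions) &&
      !all(effects$informative_regions %in% labs))
    stop("informative region(s) absent from the parcellation: ",
         paste(setdiff(effects$informative_regions, labs), collapse = ", "))
  if (effects$freq_band[2] > 1 / (2 * cohort$tr))
    stop("latent frequency band exceeds the Nyquist frequency")

  n <- cohort$n_timepoints; tr <- cohort$tr
  sigma_run <- 0.1
  sigma_subj <- sigma_run * sqrt(effects$subject_rho / (1 - effects$subject_rho))
  sigma_log <- sqrt(sigma_run^2 + sigma_subj^2)

  with_seed(seed, {
    mult <- calibrate_modulation(effects, n, tr, sigma_log)
    dims <- dim(parcellation$labels)
    vox_by_region <- lapply(labs, function(l) which(parcellation$labels == l))
    informative <- labs %in% effects$informative_regions
    hungry_mult <- ifelse(effects$effect_size >= 0, mult, 1)
    sated_mult <- ifelse(effects$effect_size >= 0, 1, mult)

    runs <- vector("list", 2L * cohort$n_subjects)
    k <- 0L
    for (s in seq_len(cohort$n_subjects)) {
      z_subj <- rnorm(1)
      for (cond in cohort$conditions) {
        gain_run <- exp(sigma_subj * z_subj + sigma_run * rnorm(1))
        cond_mult <- if (cond == cohort$conditions[1]) hungry_mult else sated_mult
        G <- latent_signal(n, tr, effects$n_sinusoids, effects$freq_band)
        dat <- matrix(rnorm(prod(dims) * n, sd = effects$noise_sd), prod(dims), n)
        for (ri in seq_along(labs)) {
          L <- latent_signal(n, tr, effects$n_sinusoids, effects$freq_band)
          w <- effects$coupling * gain_run
          g <- if (effects$effect_kind == "global_coupling") effects$global_base * gain_run else 0
          if (informative[ri]) {
            if (effects$effect_kind == "global_coupling") g <- g * cond_mult
            else w <- w * cond_mult
          }
          vox <- vox_by_region[[ri]]
          dat[vox, ] <- dat[vox, ] + rep(w * L + g * G, each = length(vox))
        }
        k <- k + 1L
        runs[[k]] <- bold_run(array(dat, c(dims, n)), tr,
                              subject_id = sprintf("S%02d", s), condition = cond)
      }
    }

    truth <- structure(list(informative_regions = effects$informative_regions,
                            effect_kind = effects$effect_kind,
                            requested_d = effects$effect_size,
                            modulation = mult,
                            seed = as.integer(seed),
                            params = list(cohort = unclass(cohort),
                                          effects = unclass(effects),
                                          sigma_run = sigma_run,
                                          sigma_subj = sigma_subj)),
                       class = "ground_truth")
    list(runs = runs, truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: kind %s, requested d = %.3g, informative regions: %s (seed %d)\n",
              x$effect_kind, x$requested_d,
              if (length(x$informative_regions)) paste(x$informative_regions, collapse = ", ") else "none",
              x$seed))
  invisible(x)
}

#' A feature table exhibiting the nesting effect of greedy forward selection
#'
#' Deterministic 20-sample, 8-region table constructed so that region 5 is the
#' best single region (a strong marker spoiled by three "trap" samples),
#' regions 1 and 2 are individually weak but jointly separate the conditions
#' perfectly (their sum is the class signal), and no supersets of region 5
#' reach zero error. Plain forward selection locks onto region 5 and stops;
#' the floating search discards it and finds \{1, 2\} — the textbook nesting
#' effect that motivates conditional exclusion.
#'
#' @return a [feature_table] with 20 samples (10 paired subjects) x 8 regions.
#' @export
nesting_demo_table <- function() {
  with_seed(3L, {
    ns <- 10
    y <- rep(c(1, -1), ns)
    z <- rnorm(2 * ns, sd = 4)
    X <- matrix(rnorm(2 * ns * 8), 2 * ns, 8)
    X[, 1] <- z
    X[, 2] <- 2 * y - z
    f5 <- y
    f5[1:3] <- -2 * y[1:3]
    X[, 5] <- f5
    feature_table(X,
                  condition = factor(ifelse(y > 0, "hunger", "satiety"),
                                     levels = c("hunger", "satiety")),
                  subject = rep(sprintf("S%02d", seq_len(ns)), each = 2))
  })
}
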