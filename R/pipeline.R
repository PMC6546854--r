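# End-to-end orchestration: simulate -> extract -> select -> evaluate ->
# permutation test, from a single configuration with reproducible seeds.

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. The `"study2019"` preset
#' encodes the emulated study's conditions: 24 subjects, 170 time points at
#' TR = 2 s, a 90-region parcellation (named after the anatomical atlas),
#' correlation threshold 0.25, bands 0.01-0.08 Hz over 0-0.25 Hz, 6 mm FWHM
#' smoothing at 3 mm voxels, and 10,000 label permutations. Any field can be
#' overridden after the preset is applied.
#'
#' @param preset `NULL` or `"study2019"`.
#' @param ... field overrides, see Details.
#' @details Fields: `n_subjects`, `n_timepoints`, `tr`, `grid_shape`,
#'   `n_regions`, `informative_regions`, `effect_kind`, `effect_size`,
#'   `subject_rho`, `noise_sd`, `features` (subset of reho/dc/falff),
#'   `strategy` (`"none"`, `"sfs"`, `"sffs"`; `"none"` evaluates the full
#'   region vector), `max_k`, `cost`, `standardize`, `folds`
#'   (`"sample"`/`"subject"`), `n_perm`, `perm_mode`
#'   (`"post_selection"`/`"full_pipeline"`), `perm_scheme`, `band`,
#'   `r_threshold`, `fwhm`, `voxel_size`, `include_dc_bin`, `seed`, `out_dir`,
#'   `write_volumes`, `verbose`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = NULL, ...) {
  cfg <- list(
    n_subjects = 8, n_timepoints = 64, tr = 2.0,
    grid_shape = c(6, 6, 6), n_regions = 8,
    informative_regions = integer(), effect_kind = "amplitude",
    effect_size = 0, subject_rho = 0.5, noise_sd = 1,
    features = c("reho", "dc", "falff"),
    strategy = "sffs", max_k = 10,
    cost = 1.0, standardize = TRUE, folds = "sample",
    n_perm = 199, perm_mode = "post_selection", perm_scheme = "within_subject",
    band = c(0.01, 0.08), r_threshold = 0.25,
    fwhm = 6, voxel_size = 3, include_dc_bin = FALSE,
    seed = 1L, out_dir = NULL, write_volumes = FALSE, verbose = FALSE)
  if (!is.null(preset)) {
    preset <- match.arg(preset, "study2019")
    cfg[c("n_subjects", "n_timepoints", "tr", "grid_shape", "n_regions",
          "n_perm", "strategy")] <-
      list(24L, 170L, 2.0, c(18L, 15L, 9L), 90L, 10000L, "sffs")
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown configuration field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$strategy %in% c("none", "sfs", "sffs"),
            all(cfg$features %in% c("reho", "dc", "falff")),
            cfg$folds %in% c("sample", "subject"),
            cfg$perm_mode %in% c("post_selection", "full_pipeline"),
            cfg$perm_scheme %in% c("within_subject", "free"))
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates a BOLD cohort, extracts the configured feature kinds in their
#' pipeline order, selects region subsets with the configured strategy,
#' evaluates the LOOCV confusion matrix and metrics, and runs the label
#' permutation test — producing one report row per feature kind (the same
#' columns as the study's summary table: CA, confusion matrix, Sen, Spe, plus
#' the permutation p). All artifacts are written under `out_dir` when given;
#' reruns with identical configuration and seed produce byte-identical
#' reports.
#'
#' @param config a [pipeline_config].
#' @return object of class `pipeline_report` (also written to
#'   `out_dir/report.json` when `out_dir` is set).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  v <- config$verbose

  t0 <- Sys.time()
  region_names <- if (config$n_regions == 90) aal_region_table()$name else NULL
  parc <- make_toy_parcellation(config$grid_shape, config$n_regions,
                                region_names = region_names)
  cohort <- cohort_spec(config$n_subjects, config$n_timepoints, config$tr)
  effects <- effect_spec(informative_regions = config$informative_regions,
                         effect_kind = config$effect_kind,
                         effect_size = config$effect_size,
                         subject_rho = config$subject_rho,
                         noise_sd = config$noise_sd)
  sim <- simulate_bold_cohort(parc, cohort, effects, seed = config$seed)
  stage_log(v, "simulate", t0, sprintf("runs=%d hash=%s", length(sim$runs),
                                       obj_hash(sim$truth)))
  if (!is.null(out)) {
    write_parcellation(parc, file.path(out, "parcellation.nii.gz"),
                       file.path(out, "regions.tsv"), config$voxel_size)
    jsonlite::write_json(list(informative_regions = sim$truth$informative_regions,
                              effect_kind = sim$truth$effect_kind,
                              requested_d = sim$truth$requested_d,
                              modulation = sim$truth$modulation,
                              seed = sim$truth$seed),
                         file.path(out, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (isTRUE(config$write_volumes)) {
      for (r in sim$runs)
        write_bold_run(r, file.path(out, sprintf("bold_%s_%s.nii.gz",
                                                 r$subject_id, r$condition)),
                       config$voxel_size)
    }
  }

  svm <- svm_config(cost = config$cost, standardize = config$standardize)
  rows <- list()
  results <- list()
  for (i in seq_along(config$features)) {
    f <- config$features[i]
    t1 <- Sys.time()
    tbl <- extract_feature_table(sim$runs, parc, feature = f,
                                 fwhm = config$fwhm, voxel_size = config$voxel_size,
                                 band = config$band, r_threshold = config$r_threshold,
                                 include_dc_bin = config$include_dc_bin)
    stage_log(v, paste0("extract_", f), t1, sprintf("table=%dx%d hash=%s",
                                                    nrow(tbl$X), ncol(tbl$X),
                                                    obj_hash(tbl$X)))
    if (!is.null(out)) write_feature_table(tbl, file.path(out, paste0("features_", f, ".tsv")))

    t2 <- Sys.time()
    trace <- NULL
    if (config$strategy == "none") {
      subset <- tbl$region_labels
    } else {
      sel_fun <- if (config$strategy == "sffs") sffs else sfs
      trace <- sel_fun(tbl, max_k = config$max_k, svm = svm, folds = config$folds)
      subset <- trace$final_subset
      if (!is.null(out)) write_selection_trace(trace, file.path(out, paste0("trace_", f, ".json")))
    }
    stage_log(v, paste0("select_", f), t2,
              sprintf("subset={%s}", paste(subset, collapse = ",")))

    t3 <- Sys.time()
    cm <- loocv_confusion(tbl, subset, svm, config$folds)
    met <- classification_metrics(cm)
    perm_seed <- config$seed + 1000L + i
    perm <- permutation_test(tbl,
                             subset = subset,
                             n_perm = config$n_perm,
                             mode = if (config$strategy == "none") "post_selection" else config$perm_mode,
                             scheme = config$perm_scheme,
                             seed = perm_seed, svm = svm, folds = config$folds,
                             selector = if (config$strategy == "sffs") "sffs" else "sfs",
                             max_k = config$max_k)
    stage_log(v, paste0("evaluate_", f), t3,
              sprintf("ER=%.4f p=%.4g", met$ER, perm$p_value))

    rows[[f]] <- data.frame(
      feature = f, strategy = config$strategy,
      subset = paste(subset, collapse = ","),
      CA = met$display$CA, TP = cm[1, 1], FP = cm[1, 2],
      FN = cm[2, 1], TN = cm[2, 2],
      Sen = met$display$Sen, Spe = met$display$Spe,
      ER = met$ER, p = perm$p_value,
      stringsAsFactors = FALSE)
    results[[f]] <- list(
      subset = subset,
      subset_names = tbl$region_names[match(subset, tbl$region_labels)],
      confusion = list(TP = cm[1, 1], FP = cm[1, 2], FN = cm[2, 1], TN = cm[2, 2]),
      metrics = list(raw = list(CA = met$CA, Sen = met$Sen, Spe = met$Spe, ER = met$ER),
                     display = met$display),
      permutation = list(p_value = perm$p_value, n_perm = perm$n_perm,
                         mode = perm$mode, scheme = perm$scheme,
                         seed = perm_seed,
                         observed_error = perm$observed_error,
                         null_histogram = as.list(
                           table(cut(perm$null_errors, breaks = seq(0, 1, 0.05),
                                     include.lowest = TRUE)))),
      selection = if (is.null(trace)) NULL else list(
        n_evals = trace$n_evals,
        best_per_size = lapply(trace$best_per_size, function(b)
          list(subset = b$subset, criterion = b$criterion))))
  }

  cfg_echo <- unclass(config)
  cfg_echo$out_dir <- NULL  # a local path, not part of the analysis identity
  report <- list(package = "rsmvpa",
                 version = as.character(packageVersion("rsmvpa")),
                 config = cfg_echo,
                 seeds = list(master = config$seed,
                              permutation = config$seed + 1000L + seq_along(config$features)),
                 ground_truth = list(informative_regions = sim$truth$informative_regions,
                                     effect_kind = sim$truth$effect_kind,
                                     requested_d = sim$truth$requested_d),
                 table = do.call(rbind, rows),
                 results = results)
  class(report) <- "pipeline_report"
  if (!is.null(out)) write_report_json(unclass(report), file.path(out, "report.json"))
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("rsmvpa pipeline report (version %s, seed %d)\n",
              x$version, x$seeds$master))
  df <- x$table
  df$CM <- sprintf("[%d %d; %d %d]", df$TP, df$FP, df$FN, df$TN)
  print(df[, c("feature", "strategy", "subset", "CA", "CM", "Sen", "Spe", "ER", "p")],
        row.names = FALSE)
  invisible(x)
}
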