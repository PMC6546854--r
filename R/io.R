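# Disk formats: NIfTI volumes (RNifti), tab-separated feature tables, JSON
# traces and reports. Writers use full double precision so a write-read
# round trip reproduces the object.

#' Write a 3D/4D volume as NIfTI
#'
#' @param x numeric array (3D or 4D) or a [voxel_map] (NA outside the mask is
#'   stored as NaN).
#' @param path output file (`.nii` or `.nii.gz`).
#' @param voxel_size voxel edge in mm.
#' @param tr repetition time in seconds (4D only).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, voxel_size = 3, tr = NULL) {
  arr <- if (inherits(x, "voxel_map")) x$values else x
  stopifnot(is.array(arr), length(dim(arr)) %in% c(3, 4))
  img <- RNifti::asNifti(arr)
  pd <- rep(voxel_size, 3)
  if (length(dim(arr)) == 4) pd <- c(pd, tr %||% 1)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file.
#' @return numeric array with attribute `pixdim`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read NIfTI file '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  attr(arr, "pixdim") <- RNifti::pixdim(img)
  arr
}

#' Write / read a BOLD run as NIfTI
#'
#' The repetition time is carried in the fourth pixdim slot; subject and
#' condition are not part of the NIfTI header and must be re-supplied (or are
#' encoded in the file name by [run_pipeline]).
#'
#' @param run a [bold_run].
#' @param path NIfTI file.
#' @param voxel_size voxel edge in mm.
#' @return `path`, invisibly.
#' @export
write_bold_run <- function(run, path, voxel_size = 3) {
  stopifnot(inherits(run, "bold_run"))
  write_volume(run$data, path, voxel_size = voxel_size, tr = run$tr)
}

#' @rdname write_bold_run
#' @param subject_id,condition identifiers for the returned object.
#' @export
read_bold_run <- function(path, subject_id = NA, condition = NA) {
  arr <- read_volume(path)
  if (length(dim(arr)) != 4) stop("'", path, "' is not a 4D volume")
  tr <- attr(arr, "pixdim")[4]
  attr(arr, "pixdim") <- NULL
  bold_run(arr, tr = tr, subject_id = subject_id, condition = condition)
}

#' Write / read a parcellation (label volume + region table)
#'
#' @param parc a [parcellation].
#' @param label_path NIfTI file for the integer label volume.
#' @param table_path two-column TSV (label, name) for the region table.
#' @param voxel_size voxel edge in mm.
#' @return `label_path`, invisibly.
#' @export
write_parcellation <- function(parc, label_path, table_path, voxel_size = 3) {
  stopifnot(inherits(parc, "parcellation"))
  img <- RNifti::asNifti(parc$labels)
  RNifti::pixdim(img) <- rep(voxel_size, 3)
  RNifti::writeNifti(img, label_path, datatype = "int32")
  write.table(parc$region_table, table_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(label_path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(label_path, table_path = NULL) {
  arr <- read_volume(label_path)
  attr(arr, "pixdim") <- NULL
  storage.mode(arr) <- "integer"
  tab <- if (is.null(table_path)) NULL else {
    t <- read.delim(table_path, stringsAsFactors = FALSE)
    if (!all(c("label", "name") %in% names(t)))
      stop("region table '", table_path, "' must have columns 'label' and 'name'")
    t$label <- as.integer(t$label)
    t
  }
  parcellation(arr, tab)
}

#' Write / read a feature table as tab-separated text
#'
#' Layout: header `subject  condition  <region names>`, one row per sample,
#' values at full double precision so the round trip is exact.
#'
#' @param table a [feature_table].
#' @param path TSV file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  num <- apply(table$X, 2, function(col) sprintf("%.17g", col))
  df <- data.frame(subject = as.character(table$subject),
                   condition = as.character(table$condition),
                   num, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("subject", "condition", table$region_names)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param region_labels integer labels to attach to the columns (defaults to
#'   1..m in file order).
#' @param feature_kind optional tag.
#' @export
read_feature_table <- function(path, region_labels = NULL, feature_kind = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3 || !identical(names(df)[1:2], c("subject", "condition")))
    stop("'", path, "': expected header starting with 'subject\tcondition'")
  reg_names <- names(df)[-(1:2)]
  X <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(X)) {
    bad <- which(!vapply(df[-(1:2)], is.numeric, logical(1)))[1]
    row <- which(is.na(suppressWarnings(as.numeric(df[[bad + 2]]))))[1]
    stop(sprintf("'%s': non-numeric value in column '%s' (data row %d)",
                 path, reg_names[bad], row))
  }
  feature_table(X, condition = df$condition, subject = df$subject,
                region_labels = region_labels %||% seq_along(reg_names),
                region_names = reg_names, feature_kind = feature_kind)
}

#' Serialize a selection trace to JSON
#'
#' @param trace a `selection_trace`.
#' @param path JSON file.
#' @return `path`, invisibly.
#' @export
write_selection_trace <- function(trace, path) {
  stopifnot(inherits(trace, "selection_trace"))
  nm <- trace$table$region_names[match(trace$final_subset, trace$table$region_labels)]
  out <- list(method = trace$method,
              steps = trace$steps,
              best_per_size = lapply(trace$best_per_size, function(b)
                list(subset = b$subset, criterion = b$criterion)),
              final_subset = trace$final_subset,
              final_region_names = nm,
              final_criterion = trace$final_criterion,
              n_evals = trace$n_evals,
              budget_exhausted = trace$budget_exhausted,
              svm = unclass(trace$svm), folds = trace$folds)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
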