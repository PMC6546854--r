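#' Construct a samples x regions feature table
#'
#' The container carried through selection and evaluation: a numeric matrix of
#' region-mean feature values, one row per scan, with the condition label and
#' subject id of every row and the ordered region labels of the columns.
#'
#' @param X numeric matrix, samples x regions.
#' @param condition factor (or character) with exactly two levels.
#' @param subject subject identifier per row; in the paired design every
#'   subject appears exactly once per condition.
#' @param region_labels integer labels of the columns (atlas order).
#' @param region_names optional region names matching `region_labels`.
#' @param feature_kind optional tag (`"reho"`, `"dc"`, `"falff"`, ...).
#' @return object of class `feature_table`.
#' @export
feature_table <- function(X, condition, subject,
                          region_labels = seq_len(ncol(X)),
                          region_names = sprintf("R%03d", region_labels),
                          feature_kind = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("feature table contains non-finite values")
  condition <- as.factor(condition)
  if (nlevels(condition) != 2) stop("exactly two condition levels are required")
  if (length(condition) != nrow(X) || length(subject) != nrow(X))
    stop("condition and subject must have one entry per row of X")
  stopifnot(length(region_labels) == ncol(X))
  subject <- as.factor(as.character(subject))
  tab <- table(subject, condition)
  paired <- all(tab == 1)
  if (!paired)
    warning("design is not fully paired (some subject does not appear exactly once per condition)")
  colnames(X) <- region_names
  structure(list(X = X, condition = condition, subject = subject,
                 region_labels = as.integer(region_labels),
                 region_names = region_names,
                 feature_kind = feature_kind, paired = paired),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table%s: %d samples x %d regions (%s vs %s, %d subjects%s)\n",
              if (is.null(x$feature_kind)) "" else paste0(" [", x$feature_kind, "]"),
              nrow(x$X), ncol(x$X),
              levels(x$condition)[1], levels(x$condition)[2],
              nlevels(x$subject), if (x$paired) ", paired" else ""))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$X)

#' @export
as.data.frame.feature_table <- function(x, ...) {
  data.frame(subject = x$subject, condition = x$condition, x$X,
             check.names = FALSE, stringsAsFactors = FALSE)
}

# columns of X for a set of region labels, in label order
region_columns <- function(table, subset) {
  subset <- sort(unique(as.integer(subset)))
  idx <- match(subset, table$region_labels)
  if (anyNA(idx))
    stop("unknown region label(s): ",
         paste(subset[is.na(idx)], collapse = ", "))
  idx
}
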