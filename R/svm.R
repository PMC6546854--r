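#' Linear SVM configuration
#'
#' The classifier behind the wrapper criterion and the evaluation loop: a
#' linear soft-margin C-SVC. The penalty and the training-fold z-scoring are
#' configuration (they are echoed into every report) because typical studies
#' do not pin them down; the defaults are C = 1 with standardization.
#'
#' @param cost soft-margin penalty C (> 0).
#' @param standardize z-score each feature using training-fold statistics
#'   before fitting (the held-out sample is scaled with the same statistics).
#' @param positive the positive class label (true positives count scans of
#'   this condition classified as this condition).
#' @return object of class `svm_config`.
#' @export
svm_config <- function(cost = 1.0, standardize = TRUE, positive = "hunger") {
  stopifnot(cost > 0)
  structure(list(cost = cost, standardize = isTRUE(standardize),
                 positive = as.character(positive)),
            class = "svm_config")
}

# resolve the positive class against the table's condition levels
positive_level <- function(table, config) {
  lv <- levels(table$condition)
  if (config$positive %in% lv) config$positive else lv[1]
}

# LOOCV predictions (factor, one per sample) for a region subset.
# folds = "sample": leave one scan out (the study's scheme, 2n folds);
# folds = "subject": leave both scans of one subject out (no paired leakage).
loocv_predictions <- function(table, subset, config = svm_config(),
                              folds = c("sample", "subject")) {
  folds <- match.arg(folds)
  if (length(subset) == 0) stop("the region subset is empty")
  cols <- region_columns(table, subset)
  X <- table$X[, cols, drop = FALSE]
  pos <- positive_level(table, config)
  yy <- ifelse(table$condition == pos, 1L, -1L)
  if (min(table(yy)) < 2) stop("need at least 2 samples per class")

  if (folds == "sample") {
    pred <- svm_loocv_cpp(X, yy, config$cost, config$standardize)
  } else {
    pred <- integer(nrow(X))
    for (s in levels(table$subject)) {
      te <- which(table$subject == s)
      tr <- setdiff(seq_len(nrow(X)), te)
      if (length(unique(yy[tr])) < 2) stop("single-class training fold")
      pred[te] <- svm_fit_predict_cpp(X[tr, , drop = FALSE], yy[tr],
                                      X[te, , drop = FALSE],
                                      config$cost, config$standardize)
    }
  }
  lv <- levels(table$condition)
  factor(ifelse(pred > 0, pos, setdiff(lv, pos)), levels = lv)
}

#' LOOCV misclassification rate of a linear SVM on a region subset
#'
#' The wrapper criterion: every sample is held out once, the classifier is
#' trained on the remaining samples restricted to the subset's columns, and
#' the held-out sample is predicted; the returned value is the fraction
#' misclassified.
#'
#' @param table a [feature_table].
#' @param subset non-empty set of region labels.
#' @param svm an [svm_config].
#' @param folds `"sample"` (leave one scan out; study scheme) or `"subject"`
#'   (leave one subject's pair out).
#' @return error rate in `[0, 1]`.
#' @export
criterion_loocv_error <- function(table, subset, svm = svm_config(),
                                  folds = c("sample", "subject")) {
  pred <- loocv_predictions(table, subset, svm, folds)
  mean(pred != table$condition)
}
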