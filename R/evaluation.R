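# LOOCV evaluation (confusion matrix + metrics) and the label-permutation
# significance test.

#' LOOCV confusion matrix of a linear SVM on a region subset
#'
#' Runs the same leave-one-out loop as [criterion_loocv_error] and accumulates
#' the four cells of the 2x2 confusion matrix, laid out
#' `[TP FP; FN TN]` with rows = classified and columns = reference condition;
#' the positive class is the one named in the [svm_config] (hunger by
#' default). `(FP + FN) / total` equals the criterion exactly — both are
#' reporters of one computation.
#'
#' @inheritParams criterion_loocv_error
#' @return 2x2 integer matrix of class `confusion_matrix`.
#' @export
loocv_confusion <- function(table, subset, svm = svm_config(),
                            folds = c("sample", "subject")) {
  pred <- loocv_predictions(table, subset, svm, folds)
  confusion_matrix(pred, table$condition, positive = positive_level(table, svm))
}

#' Build a confusion matrix from predicted and reference labels
#'
#' @param predicted,reference factors with identical levels.
#' @param positive the positive class label.
#' @return 2x2 integer matrix of class `confusion_matrix`,
#'   layout `[TP FP; FN TN]` (rows = classified, columns = reference).
#' @export
confusion_matrix <- function(predicted, reference, positive = levels(reference)[1]) {
  stopifnot(length(predicted) == length(reference))
  lv <- levels(as.factor(reference))
  stopifnot(positive %in% lv)
  neg <- setdiff(lv, positive)
  tp <- sum(predicted == positive & reference == positive)
  fp <- sum(predicted == positive & reference == neg)
  fn <- sum(predicted == neg & reference == positive)
  tn <- sum(predicted == neg & reference == neg)
  m <- matrix(as.integer(c(tp, fn, fp, tn)), nrow = 2,
              dimnames = list(classified = c(positive, neg),
                              reference = c(positive, neg)))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion matrix (rows = classified, columns = reference)\n")
  print(unclass(x))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Computes classification accuracy `CA = (TP+TN)/total`, sensitivity
#' `Sen = TP/(TP+FN)`, specificity `Spe = TN/(TN+FP)` and the error rate
#' `ER = (FP+FN)/total` (so `CA + ER = 1` exactly). Display values follow the
#' usual reporting convention: percentages rounded half-up to the nearest
#' integer, ER to two decimals. A zero denominator yields `NA` (undefined),
#' never 0.
#'
#' @param cm a [confusion_matrix] (or any 2x2 matrix in the same layout).
#' @return object of class `classification_metrics` with raw values and a
#'   `display` sub-list.
#' @export
classification_metrics <- function(cm) {
  cm <- unclass(cm)
  stopifnot(is.matrix(cm), all(dim(cm) == 2), all(cm >= 0))
  tp <- cm[1, 1]; fp <- cm[1, 2]; fn <- cm[2, 1]; tn <- cm[2, 2]
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty confusion matrix")
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  ca <- (tp + tn) / total
  sen <- safe_div(tp, tp + fn)
  spe <- safe_div(tn, tn + fp)
  er <- (fp + fn) / total
  structure(list(CA = ca, Sen = sen, Spe = spe, ER = er, total = total,
                 display = list(CA = round_half_up(100 * ca),
                                Sen = round_half_up(100 * sen),
                                Spe = round_half_up(100 * spe),
                                ER = round_half_up(er, 2))),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("CA %s%%  Sen %s%%  Spe %s%%  ER %s  (n = %d)\n",
              format(x$display$CA), format(x$display$Sen),
              format(x$display$Spe), format(x$display$ER), x$total))
  invisible(x)
}

# permute condition labels: within-subject pair swaps (the paired design's
# exchangeability unit) or a free permutation of all labels
permute_labels <- function(table, scheme = c("within_subject", "free")) {
  scheme <- match.arg(scheme)
  y <- table$condition
  if (scheme == "free") return(sample(y))
  if (!table$paired)
    stop("within-subject permutation requires a fully paired design; use scheme = 'free'")
  for (s in levels(table$subject)) {
    if (rbinom(1, 1, 0.5) == 1) {
      i <- which(table$subject == s)
      y[i] <- rev(y[i])
    }
  }
  y
}

#' Label-permutation test of the LOOCV error
#'
#' Builds the empirical null distribution of the LOOCV error rate by
#' recomputing it under random label permutations (default: within-subject
#' pair swaps, respecting the paired design) and returns
#' `p = (1 + #\{null <= observed\}) / (1 + n_perm)`.
#'
#' Two modes: `post_selection` keeps the region subset fixed and only
#' re-evaluates the classifier — cheap, but anti-conservative when the subset
#' was selected on the *same* data; `full_pipeline` reruns the configured
#' selection inside every permutation and evaluates its final subset —
#' unbiased, at roughly `n_regions * max_k` times the cost per permutation
#' (the call refuses budgets that would exceed `max_total_evals`).
#'
#' @param table a [feature_table].
#' @param subset region subset (required in `post_selection` mode; in
#'   `full_pipeline` mode it is ignored and selection is rerun).
#' @param n_perm number of label permutations (study value 10,000).
#' @param mode `"post_selection"` or `"full_pipeline"`.
#' @param scheme permutation unit: `"within_subject"` (default) or `"free"`.
#' @param seed integer seed for the permutation draws.
#' @param svm an [svm_config].
#' @param folds fold scheme, see [criterion_loocv_error].
#' @param selector selection method for `full_pipeline` mode.
#' @param max_k largest subset size for `full_pipeline` selection.
#' @param max_total_evals refuse a `full_pipeline` run whose rough cost
#'   estimate exceeds this many criterion evaluations.
#' @return object of class `permutation_null`: `null_errors`,
#'   `observed_error`, `p_value`, `n_perm`, `mode`, `scheme`, `seed`, config.
#' @export
permutation_test <- function(table, subset = NULL, n_perm = 10000,
                             mode = c("post_selection", "full_pipeline"),
                             scheme = c("within_subject", "free"),
                             seed = 1L, svm = svm_config(),
                             folds = c("sample", "subject"),
                             selector = c("sffs", "sfs"), max_k = 10,
                             max_total_evals = 2e6) {
  mode <- match.arg(mode)
  scheme <- match.arg(scheme)
  folds <- match.arg(folds)
  selector <- match.arg(selector)
  stopifnot(n_perm >= 1)

  if (mode == "post_selection") {
    if (is.null(subset) || length(subset) == 0)
      stop("post_selection mode needs a non-empty region subset")
    observed <- criterion_loocv_error(table, subset, svm, folds)
    eval_one <- function(tab) criterion_loocv_error(tab, subset, svm, folds)
  } else {
    est <- as.double(n_perm) * ncol(table$X) * (2 * max_k)
    if (est > max_total_evals)
      stop(sprintf(paste0("full_pipeline with n_perm = %d would need roughly %.3g criterion ",
                          "evaluations (budget %.3g); lower n_perm or raise max_total_evals"),
                   n_perm, est, max_total_evals))
    sel_fun <- if (selector == "sffs") sffs else sfs
    observed <- sel_fun(table, max_k = max_k, svm = svm, folds = folds)$final_criterion
    eval_one <- function(tab) sel_fun(tab, max_k = max_k, svm = svm, folds = folds)$final_criterion
  }

  null_errors <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      tab <- table
      tab$condition <- permute_labels(table, scheme)
      eval_one(tab)
    }, numeric(1))
  })

  p <- (1 + sum(null_errors <= observed + 1e-12)) / (1 + n_perm)
  structure(list(null_errors = null_errors, observed_error = observed,
                 n_perm = as.integer(n_perm), p_value = p,
                 mode = mode, scheme = scheme, seed = as.integer(seed),
                 svm = svm, folds = folds,
                 subset = if (mode == "post_selection") sort(as.integer(subset)) else NULL),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation test (%s, %s swaps, %d permutations, seed %d)\n",
              x$mode, x$scheme, x$n_perm, x$seed))
  cat(sprintf("observed ER = %.4f, null mean = %.4f, p = %.4g\n",
              x$observed_error, mean(x$null_errors), x$p_value))
  invisible(x)
}

#' Histogram of the permutation null with the observed error marked
#'
#' @param x a `permutation_null`.
#' @param ... passed to [graphics::hist].
#' @export
plot.permutation_null <- function(x, ...) {
  hist(x$null_errors, breaks = 30, col = "grey85", border = "grey60",
       xlab = "classification error rate", main = sprintf(
         "null distribution (%d permutations), p = %.4g", x$n_perm, x$p_value),
       xlim = range(c(x$null_errors, x$observed_error)), ...)
  abline(v = x$observed_error, col = "red", lwd = 2)
  invisible(x)
}
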