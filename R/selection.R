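# Wrapper region selection: sequential forward selection and its floating
# variant, both driven by the LOOCV misclassification rate of the linear SVM.
# There is no randomness inside selection: a fixed table and configuration
# give an identical trace. Ties are broken by the smallest region label, then
# by lexicographically smallest subset.

# shared bookkeeping: criterion cache + evaluation counter
new_crit_env <- function(table, svm, folds, max_evals = Inf) {
  e <- new.env(parent = emptyenv())
  e$cache <- new.env(parent = emptyenv())
  e$n_evals <- 0L
  e$budget <- max_evals
  e$exhausted <- FALSE
  e$table <- table; e$svm <- svm; e$folds <- folds
  e
}

crit_eval <- function(env, subset) {
  key <- paste(sort(subset), collapse = ",")
  hit <- get0(key, envir = env$cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  if (env$n_evals >= env$budget) {
    env$exhausted <- TRUE
    return(NA_real_)
  }
  env$n_evals <- env$n_evals + 1L
  v <- criterion_loocv_error(env$table, subset, env$svm, env$folds)
  assign(key, v, envir = env$cache)
  v
}

# is subset a lexicographically smaller than b (both sorted)?
lex_smaller <- function(a, b) {
  if (length(a) != length(b)) return(length(a) < length(b))
  d <- which(a != b)
  if (length(d) == 0) FALSE else a[d[1]] < b[d[1]]
}

update_best <- function(best, subset, crit, tol) {
  k <- as.character(length(subset))
  cur <- best[[k]]
  if (is.null(cur) || crit < cur$criterion - tol ||
      (abs(crit - cur$criterion) <= tol && lex_smaller(sort(subset), cur$subset))) {
    best[[k]] <- list(subset = sort(subset), criterion = crit)
  }
  best
}

final_from_best <- function(best, tol) {
  sizes <- as.integer(names(best))
  crits <- vapply(best, `[[`, numeric(1), "criterion")
  m <- min(crits)
  cand <- which(crits <= m + tol)
  cand <- cand[order(sizes[cand])]
  pick <- cand[1]
  for (i in cand[-1]) {
    if (sizes[i] == sizes[pick] && lex_smaller(best[[i]]$subset, best[[pick]]$subset))
      pick <- i
  }
  best[[pick]]
}

selection_trace <- function(method, steps, best, tol, env, max_k) {
  fin <- final_from_best(best, tol)
  structure(list(method = method,
                 steps = steps,
                 best_per_size = best,
                 final_subset = fin$subset,
                 final_criterion = fin$criterion,
                 n_evals = env$n_evals,
                 budget_exhausted = env$exhausted,
                 max_k = max_k,
                 svm = env$svm, folds = env$folds,
                 table = env$table),
            class = "selection_trace")
}

step_row <- function(action, region, subset, crit) {
  data.frame(action = action, region = region, size = length(subset),
             criterion = crit,
             subset = paste(sort(subset), collapse = ","),
             stringsAsFactors = FALSE)
}

# best single change: returns list(region, crit) or NULL when budget dies
best_addition <- function(env, subset, candidates, tol) {
  best_r <- NA_integer_; best_c <- Inf
  for (r in sort(candidates)) {
    v <- crit_eval(env, c(subset, r))
    if (is.na(v)) return(NULL)
    if (v < best_c - tol) { best_c <- v; best_r <- r }
  }
  list(region = best_r, criterion = best_c)
}

best_removal <- function(env, subset, tol) {
  best_r <- NA_integer_; best_c <- Inf
  for (r in sort(subset)) {
    v <- crit_eval(env, setdiff(subset, r))
    if (is.na(v)) return(NULL)
    if (v < best_c - tol) { best_c <- v; best_r <- r }
  }
  list(region = best_r, criterion = best_c)
}

#' Sequential forward selection (SFS)
#'
#' Greedy forward search: starting from the empty set, at each step the region
#' whose addition minimises the LOOCV error of the linear SVM is added; the
#' search stops when no addition strictly decreases the criterion (tolerance
#' `tol`) or when the subset reaches `max_k` regions. The final subset is the
#' best subset over all sizes encountered (ties: smaller size, then
#' lexicographically smaller subset).
#'
#' @param table a [feature_table].
#' @param max_k largest subset size to consider.
#' @param svm an [svm_config].
#' @param folds fold scheme, see [criterion_loocv_error].
#' @param tol strict-improvement tolerance on the error rate (error rates are
#'   multiples of 1/samples, so this only guards floating-point noise).
#' @return object of class `selection_trace`: ordered `steps`, the best subset
#'   per size, the final subset and criterion, and the evaluation count.
#' @export
sfs <- function(table, max_k = 10, svm = svm_config(),
                folds = c("sample", "subject"), tol = 1e-12) {
  folds <- match.arg(folds)
  if (max_k < 1) stop("max_k must be at least 1")
  max_k <- min(max_k, ncol(table$X))
  env <- new_crit_env(table, svm, folds)
  labels <- table$region_labels
  steps <- NULL; best <- list()
  subset <- integer(); cur <- Inf

  while (length(subset) < max_k) {
    add <- best_addition(env, subset, setdiff(labels, subset), tol)
    if (length(subset) > 0 && add$criterion >= cur - tol) break
    subset <- sort(c(subset, add$region))
    cur <- add$criterion
    steps <- rbind(steps, step_row("add", add$region, subset, cur))
    best <- update_best(best, subset, cur, tol)
    if (cur <= 0) break
  }
  selection_trace("sfs", steps, best, tol, env, max_k)
}

#' Sequential forward floating selection (SFFS)
#'
#' The floating variant of [sfs]: after every forward addition, conditional
#' exclusion is tested repeatedly — the member whose removal gives a criterion
#' strictly better than the best known subset of the reduced size is dropped,
#' and the best-per-size record updated. The forward march continues until the
#' working subset reaches `max_k` regions (or the evaluation budget runs out,
#' flagged in the trace); the final subset is then the best subset over all
#' sizes encountered. Unlike plain SFS, the floating search can discard a
#' region that was selected early (e.g. the best singleton) once a better
#' combination without it is found.
#'
#' @inheritParams sfs
#' @param max_evals budget of criterion evaluations (cache misses) per run,
#'   bounding worst-case floating oscillation.
#' @return object of class `selection_trace`.
#' @export
sffs <- function(table, max_k = 10, svm = svm_config(),
                 folds = c("sample", "subject"), tol = 1e-12,
                 max_evals = 10000) {
  folds <- match.arg(folds)
  if (max_k < 1) stop("max_k must be at least 1")
  max_k <- min(max_k, ncol(table$X))
  env <- new_crit_env(table, svm, folds, max_evals)
  labels <- table$region_labels
  steps <- NULL; best <- list()
  subset <- integer()

  repeat {
    if (length(subset) >= max_k) break
    add <- best_addition(env, subset, setdiff(labels, subset), tol)
    if (is.null(add)) break  # budget exhausted mid-scan
    subset <- sort(c(subset, add$region))
    crit <- add$criterion
    steps <- rbind(steps, step_row("add", add$region, subset, crit))
    best <- update_best(best, subset, crit, tol)

    # conditional exclusion cascade: drop a member only while doing so beats
    # the best subset already known at the reduced size
    while (length(subset) >= 2) {
      rem <- best_removal(env, subset, tol)
      if (is.null(rem)) break
      k1 <- as.character(length(subset) - 1L)
      if (!is.null(best[[k1]]) && rem$criterion >= best[[k1]]$criterion - tol) break
      subset <- sort(setdiff(subset, rem$region))
      crit <- rem$criterion
      steps <- rbind(steps, step_row("remove", rem$region, subset, crit))
      best <- update_best(best, subset, crit, tol)
    }
    if (env$exhausted) break
  }
  selection_trace("sffs", steps, best, tol, env, max_k)
}

#' Exhaustive search over all region subsets up to a size
#'
#' Brute-force reference: evaluates the LOOCV criterion on every subset of
#' size 1..`max_k` and records the optimum per size. Only feasible for small
#' region counts; used as the optimality oracle for the sequential searches.
#'
#' @inheritParams sfs
#' @return object of class `selection_trace` (steps omitted).
#' @export
exhaustive_selection <- function(table, max_k = 3, svm = svm_config(),
                                 folds = c("sample", "subject"), tol = 1e-12) {
  folds <- match.arg(folds)
  max_k <- min(max_k, ncol(table$X))
  env <- new_crit_env(table, svm, folds)
  labels <- table$region_labels
  best <- list()
  for (k in seq_len(max_k)) {
    sets <- combn(labels, k)
    for (j in seq_len(ncol(sets))) {
      s <- sets[, j]
      best <- update_best(best, s, crit_eval(env, s), tol)
    }
  }
  selection_trace("exhaustive", NULL, best, tol, env, max_k)
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("%s selection (max_k = %d, %s folds): %d criterion evaluations%s\n",
              toupper(x$method), x$max_k, x$folds, x$n_evals,
              if (x$budget_exhausted) " [budget exhausted]" else ""))
  nm <- x$table$region_names[match(x$final_subset, x$table$region_labels)]
  cat(sprintf("final subset (LOOCV error %.4f): R[%s]\n", x$final_criterion,
              paste(x$final_subset, collapse = ",")))
  cat(paste0("  ", format(x$final_subset, width = 4), "  ", nm, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
summary.selection_trace <- function(object, ...) {
  sizes <- sort(as.integer(names(object$best_per_size)))
  df <- data.frame(
    size = sizes,
    criterion = vapply(as.character(sizes),
                       function(k) object$best_per_size[[k]]$criterion, numeric(1)),
    subset = vapply(as.character(sizes),
                    function(k) paste(object$best_per_size[[k]]$subset, collapse = ","),
                    character(1)),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' @export
plot.selection_trace <- function(x, ...) {
  df <- summary(x)
  plot(df$size, df$criterion, type = "b", pch = 19,
       xlab = "subset size", ylab = "LOOCV error",
       main = sprintf("%s: best criterion per subset size", toupper(x$method)), ...)
  points(length(x$final_subset), x$final_criterion, col = 2, cex = 2)
  invisible(x)
}

#' Predict conditions for new region vectors from a selection
#'
#' Trains the configured linear SVM on the full table restricted to the final
#' subset and predicts the given samples.
#'
#' @param object a `selection_trace`.
#' @param newdata numeric matrix with one column per region of the original
#'   table (same order), or a [feature_table].
#' @param ... unused.
#' @return factor of predicted condition labels.
#' @export
predict.selection_trace <- function(object, newdata, ...) {
  table <- object$table
  X <- if (inherits(newdata, "feature_table")) newdata$X else as.matrix(newdata)
  if (ncol(X) == ncol(table$X)) {
    X <- X[, region_columns(table, object$final_subset), drop = FALSE]
  } else if (ncol(X) != length(object$final_subset)) {
    stop("newdata must have one column per original region or per selected region")
  }
  cols <- region_columns(table, object$final_subset)
  pos <- positive_level(table, object$svm)
  yy <- ifelse(table$condition == pos, 1L, -1L)
  pred <- svm_fit_predict_cpp(table$X[, cols, drop = FALSE], yy, X,
                              object$svm$cost, object$svm$standardize)
  lv <- levels(table$condition)
  factor(ifelse(pred > 0, pos, setdiff(lv, pos)), levels = lv)
}
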