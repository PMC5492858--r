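#' Stratified fold assignment for cross-validation
#'
#' Assigns every feature vector to one of `k` folds so that, within each
#' class, fold sizes differ by at most one. In `clip` mode whole clips are
#' assigned to folds (no clip's frames are split across train and test),
#' which avoids leaking intra-clip correlation; `frame` mode stratifies raw
#' frames, matching the protocol of training on 90% of the audio samples and
#' testing on the rest.
#'
#' @param labels Factor or character vector, one class label per vector.
#' @param k Number of folds (default 10; must be at least 2).
#' @param mode `"frame"` (default) or `"clip"`.
#' @param clip_ids Integer clip identifier per vector (required in clip mode).
#' @param seed Integer seed (default 0).
#' @return A `fold_plan`: list with `assignment` (fold id per vector), `k`,
#'   `mode` and `seed`.
#' @export
make_folds <- function(labels, k = 10, mode = c("frame", "clip"),
                       clip_ids = NULL, seed = 0) {
  mode <- match.arg(mode)
  labels <- as.factor(labels)
  if (k < 2) stop("k-fold cross-validation needs k >= 2 (no held-out set otherwise)")
  set.seed(as.integer(seed))
  assignment <- integer(length(labels))
  if (mode == "frame") {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        stop("class ", cl, " has only ", length(idx), " vectors for k = ", k)
      assignment[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    if (is.null(clip_ids)) stop("clip mode needs clip_ids")
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      clips <- unique(clip_ids[idx])
      if (length(clips) < k)
        stop("class ", cl, " has only ", length(clips), " clips for k = ", k)
      clip_fold <- sample(rep_len(seq_len(k), length(clips)))
      assignment[idx] <- clip_fold[match(clip_ids[idx], clips)]
    }
  }
  structure(list(assignment = assignment, k = k, mode = mode, seed = seed),
            class = "fold_plan")
}

#' Row-percentage view of a confusion matrix
#'
#' Divides each row of a count matrix by its sum, times 100. The returned
#' matrix is unrounded; round only at presentation (see
#' [format_confusion()]).
#'
#' @param counts n x n confusion count matrix (actual classes on rows,
#'   predicted on columns).
#' @return n x n numeric matrix with rows summing to 100.
#' @export
confusion_to_percent <- function(counts) {
  counts <- as.matrix(counts)
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    bad <- rownames(counts)[rs == 0]
    if (is.null(bad)) bad <- which(rs == 0)
    stop("confusion matrix row for class ", paste(bad, collapse = ", "),
         " is empty")
  }
  sweep(counts, 1, rs, `/`) * 100
}

#' @rdname confusion_to_percent
#' @param row_percent Unrounded row-percentage matrix.
#' @param digits Decimals for display (default 2).
#' @export
format_confusion <- function(row_percent, digits = 2) {
  round(row_percent, digits)
}

#' Cross-validated evaluation of the GMM recognizer
#'
#' For each fold: fits one GMM per species on the training split, classifies
#' the held-out frames, and accumulates confusion counts. Reports per-fold
#' per-class accuracy, its mean and variance, the pooled confusion matrix in
#' counts and row percentages, and the smallest log-likelihood step observed
#' across all EM runs (a direct check of the EM ascent property).
#'
#' @param features A [feature_matrix()] or R x d matrix.
#' @param labels Class label per frame.
#' @param plan A `fold_plan` from [make_folds()].
#' @param config A [gmm_config()].
#' @param verbose Print per-fold progress.
#' @return A `cv_report`: list with `per_fold_accuracy` (k x n), `mean_accuracy`,
#'   `var_accuracy`, `counts`, `row_percent`, `labels`, `predicted`, `actual`,
#'   `em_min_loglik_step` and `n_test_frames`.
#' @export
run_cv <- function(features, labels, plan, config = gmm_config(),
                   verbose = FALSE) {
  X <- as_feature_rows(features)
  labels <- as.factor(labels)
  stopifnot(inherits(plan, "fold_plan"), length(labels) == nrow(X))
  classes <- levels(labels)
  n <- length(classes)
  k <- plan$k
  per_fold <- matrix(NA_real_, k, n, dimnames = list(NULL, classes))
  counts <- matrix(0L, n, n, dimnames = list(classes, classes))
  predicted <- character(0)
  actual <- character(0)
  em_min_step <- Inf
  for (f in seq_len(k)) {
    test <- plan$assignment == f
    models <- vector("list", n)
    for (ci in seq_len(n)) {
      idx <- !test & labels == classes[ci]
      fit <- tryCatch(
        fit_gmm(X[idx, , drop = FALSE], label = classes[ci], config = config),
        error = function(e) stop("fold ", f, ", class ", classes[ci],
                                 ": training failed (",
                                 conditionMessage(e), ")"))
      tr <- fit$metadata$loglik_trace
      if (length(tr) > 1) em_min_step <- min(em_min_step, min(diff(tr)))
      models[[ci]] <- fit
    }
    bank <- model_bank(models)
    pred <- classify_frames(X[test, , drop = FALSE], bank)$labels
    act <- as.character(labels[test])
    predicted <- c(predicted, pred)
    actual <- c(actual, act)
    counts <- counts + table(factor(act, classes), factor(pred, classes))
    for (ci in seq_len(n)) {
      sel <- act == classes[ci]
      per_fold[f, ci] <- mean(pred[sel] == classes[ci])
    }
    if (verbose)
      message(sprintf("fold %d/%d: accuracy %.4f", f, k, mean(pred == act)))
  }
  counts <- matrix(as.integer(counts), n, n, dimnames = list(classes, classes))
  structure(list(
    per_fold_accuracy = per_fold,
    mean_accuracy = colMeans(per_fold),
    var_accuracy = apply(per_fold, 2, stats::var),
    counts = counts,
    row_percent = confusion_to_percent(counts),
    labels = classes, predicted = predicted, actual = actual,
    em_min_loglik_step = em_min_step,
    n_test_frames = length(predicted), mode = plan$mode, k = k),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold (%s mode), %d test frames\n",
              x$k, x$mode, x$n_test_frames))
  cat(sprintf("  overall accuracy: %.4f\n", mean(x$actual == x$predicted)))
  cat(sprintf("  mean per-class accuracy: %.4f (range %.4f-%.4f)\n",
              mean(x$mean_accuracy), min(x$mean_accuracy),
              max(x$mean_accuracy)))
  invisible(x)
}

#' Per-class boxplot statistics of fold accuracies
#'
#' Five-number summaries (min, q1, median, q3, max) of the per-fold
#' accuracies of each class, for external plotting.
#'
#' @param report A `cv_report`.
#' @return Data frame with one row per class.
#' @export
cv_boxplot_stats <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  qs <- apply(report$per_fold_accuracy, 2, stats::quantile,
              probs = c(0, 0.25, 0.5, 0.75, 1))
  data.frame(class = report$labels, min = qs[1, ], q1 = qs[2, ],
             median = qs[3, ], q3 = qs[4, ], max = qs[5, ],
             row.names = NULL)
}
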