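#' Per-class accuracies
#'
#' @param labels 0/1 vector of true labels (both classes present).
#' @param predictions 0/1 vector of predicted labels.
#' @return A tibble with columns `class` (0, 1) and `accuracy` (percent).
#' @export
class_accuracies <- function(labels, predictions) {
  if (length(labels) != length(predictions)) abort("Length mismatch.")
  if (!all(c(0, 1) %in% labels)) abort("Both classes must be present in `labels`.")
  acc <- vapply(c(0, 1), function(cl) {
    100 * mean(predictions[labels == cl] == cl)
  }, numeric(1))
  tibble(class = c(0L, 1L), accuracy = acc)
}

#' Recall and precision of the positive class
#'
#' Recall = TP / (TP + FN); precision = TP / (TP + FP), reported as `NA` when
#' nothing is predicted positive.
#'
#' @inheritParams class_accuracies
#' @return A one-row tibble with `recall` and `precision` (percent).
#' @export
recall_precision <- function(labels, predictions) {
  if (length(labels) != length(predictions)) abort("Length mismatch.")
  tp <- sum(labels == 1 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  fp <- sum(labels == 0 & predictions == 1)
  tibble(recall = 100 * tp / (tp + fn),
         precision = if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp))
}

# thresholds at evenly spaced score quantiles, bracketed so the swept curve
# always reaches (0,0) and (1,1)
score_thresholds <- function(scores, n_thresholds) {
  q <- stats::quantile(scores, probs = seq(1, 0, length.out = n_thresholds),
                       names = FALSE, type = 7)
  c(Inf, q, -Inf)
}

roc_points <- function(labels, scores, thresholds) {
  pos <- sum(labels == 1)
  neg <- sum(labels == 0)
  t(vapply(thresholds, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & labels == 0) / neg, tpr = sum(pred & labels == 1) / pos)
  }, numeric(2)))
}

pr_points <- function(labels, scores, thresholds) {
  pos <- sum(labels == 1)
  t(vapply(thresholds, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    c(recall = tp / pos,
      precision = if (sum(pred) == 0) NA_real_ else tp / sum(pred))
  }, numeric(2)))
}

# area under a curve by trapezoid after sorting on (x, y)
trapezoid_auc <- function(x, y) {
  o <- order(x, y)
  x <- x[o]
  y <- y[o]
  sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)
}

boot_curve <- function(labels, scores, thresholds, point_fun, n_resamples, seed) {
  n <- length(labels)
  with_seed(seed, {
    draws <- lapply(seq_len(n_resamples), function(i) {
      for (attempt in 1:25) {
        idx <- sample.int(n, n, replace = TRUE)
        if (all(c(0, 1) %in% labels[idx])) return(idx)
      }
      abort("Could not draw a class-complete resample in 25 attempts.")
    })
    arr <- vapply(draws,
                  function(idx) point_fun(labels[idx], scores[idx], thresholds),
                  matrix(0, length(thresholds), 2))
    list(x_mean = apply(arr[, 1, ], 1, mean, na.rm = TRUE),
         x_sd = apply(arr[, 1, ], 1, stats::sd, na.rm = TRUE),
         y_mean = apply(arr[, 2, ], 1, mean, na.rm = TRUE),
         y_sd = apply(arr[, 2, ], 1, stats::sd, na.rm = TRUE))
  })
}

#' ROC curve with bootstrap error bars
#'
#' Sweeps the decision threshold over evenly spaced score quantiles; per
#' threshold, the mean and SD of TPR and FPR are taken over bootstrap
#' resamples of the (label, score) rows. The AUC is the trapezoidal area
#' under the full-data curve sorted by FPR.
#'
#' @param labels 0/1 vector (both classes present).
#' @param scores Continuous decision scores, larger = more positive.
#' @param n_thresholds Number of quantile thresholds (plus the two bracketing
#'   endpoints).
#' @param n_resamples Bootstrap resamples per threshold (default 500).
#' @param seed RNG seed for the resampling.
#' @return A list of class `roc_curve`: `curve` tibble (`threshold`,
#'   `x_mean`, `x_sd`, `y_mean`, `y_sd`; x = FPR, y = TPR), `auc`,
#'   `n_resamples`.
#' @export
roc_with_error <- function(labels, scores, n_thresholds = 101L,
                           n_resamples = 500L, seed = 1L) {
  if (length(unique(labels)) < 2L) abort("Both classes must be present.")
  thresholds <- score_thresholds(scores, n_thresholds)
  full <- roc_points(labels, scores, thresholds)
  auc <- trapezoid_auc(full[, "fpr"], full[, "tpr"])
  bc <- boot_curve(labels, scores, thresholds, roc_points, n_resamples, seed)
  structure(list(
    curve = tibble(threshold = thresholds, x_mean = bc$x_mean, x_sd = bc$x_sd,
                   y_mean = bc$y_mean, y_sd = bc$y_sd),
    full = tibble(threshold = thresholds, fpr = full[, "fpr"],
                  tpr = full[, "tpr"]),
    auc = auc, n_resamples = n_resamples
  ), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("# ROC curve: AUC = %.4f (%d thresholds, %d resamples)\n",
              x$auc, nrow(x$curve), x$n_resamples))
  invisible(x)
}

#' Precision-recall curve with bootstrap error bars
#'
#' Same sweep and resampling scheme as [roc_with_error()], reporting recall
#' on x and precision on y. Thresholds where a resample predicts nothing
#' positive contribute no precision value (excluded from that threshold's
#' mean).
#'
#' @inheritParams roc_with_error
#' @return A list of class `pr_curve` with a `curve` tibble (x = recall,
#'   y = precision) and the full-data curve.
#' @export
pr_with_error <- function(labels, scores, n_thresholds = 101L,
                          n_resamples = 500L, seed = 1L) {
  if (length(unique(labels)) < 2L) abort("Both classes must be present.")
  thresholds <- score_thresholds(scores, n_thresholds)
  full <- pr_points(labels, scores, thresholds)
  bc <- boot_curve(labels, scores, thresholds, pr_points, n_resamples, seed)
  structure(list(
    curve = tibble(threshold = thresholds, x_mean = bc$x_mean, x_sd = bc$x_sd,
                   y_mean = bc$y_mean, y_sd = bc$y_sd),
    full = tibble(threshold = thresholds, recall = full[, "recall"],
                  precision = full[, "precision"]),
    n_resamples = n_resamples
  ), class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("# PR curve: %d thresholds, %d resamples\n",
              nrow(x$curve), x$n_resamples))
  invisible(x)
}

#' Full evaluation report for a classifier on labeled pairs
#'
#' Bundles per-class accuracies, recall/precision at the default threshold,
#' and the ROC and PR curves with bootstrap error bars. One-class models do
#' not produce a false-positive rate, so their report carries class-1
#' accuracy only (no ROC/PR).
#'
#' @param labels 0/1 vector.
#' @param scores Continuous scores (probabilities or decision values).
#' @param predictions 0/1 vector at the operating threshold.
#' @param classifier_tag,dataset_tag Free-text labels stored in the report.
#' @param n_resamples Bootstrap resamples for the curves.
#' @param seed RNG seed.
#' @param one_class Set `TRUE` to skip ROC/PR (one-class SVM).
#' @return A list of class `evaluation_report`.
#' @export
evaluation_report <- function(labels, scores, predictions,
                              classifier_tag = "", dataset_tag = "",
                              n_resamples = 500L, seed = 1L,
                              one_class = FALSE) {
  if (one_class) {
    acc1 <- 100 * mean(predictions[labels == 1] == 1)
    return(structure(list(
      class_accuracy = tibble(class = 1L, accuracy = acc1),
      recall_precision = recall_precision(labels, predictions),
      auc = NA_real_, roc = NULL, pr = NULL,
      classifier_tag = classifier_tag, dataset_tag = dataset_tag
    ), class = "evaluation_report"))
  }
  roc <- roc_with_error(labels, scores, n_resamples = n_resamples, seed = seed)
  pr <- pr_with_error(labels, scores, n_resamples = n_resamples, seed = seed + 1L)
  structure(list(
    class_accuracy = class_accuracies(labels, predictions),
    recall_precision = recall_precision(labels, predictions),
    auc = roc$auc, roc = roc, pr = pr,
    classifier_tag = classifier_tag, dataset_tag = dataset_tag
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("# Evaluation [%s%s]\n", x$classifier_tag,
              if (nzchar(x$dataset_tag)) paste0(" / ", x$dataset_tag) else ""))
  for (i in seq_len(nrow(x$class_accuracy))) {
    cat(sprintf("#   class %d accuracy: %.1f%%\n",
                x$class_accuracy$class[i], x$class_accuracy$accuracy[i]))
  }
  cat(sprintf("#   recall: %.1f%%  precision: %s\n",
              x$recall_precision$recall,
              ifelse(is.na(x$recall_precision$precision), "NA",
                     sprintf("%.1f%%", x$recall_precision$precision))))
  if (!is.na(x$auc)) cat(sprintf("#   AUC: %.4f\n", x$auc))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return A long tibble of metric/value rows.
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble(metric = sprintf("class_accuracy_%d", x$class_accuracy$class),
           value = x$class_accuracy$accuracy),
    tibble(metric = c("recall", "precision", "auc"),
           value = c(x$recall_precision$recall, x$recall_precision$precision,
                     x$auc))
  ) |>
    dplyr::mutate(classifier = x$classifier_tag, dataset = x$dataset_tag)
}
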