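#' Fit a two-class RBF support vector machine
#'
#' Soft-margin SVM with the gamma-parameterized RBF kernel (libsvm via
#' e1071). The continuous decision score is exposed for ROC/PR sweeps;
#' features are used as-is (no internal rescaling), matching the pipeline's
#' explicit moment standardization.
#'
#' @param train Labeled training tibble (`label` 0/1 + numeric features).
#' @param cost Penalty parameter C (> 0).
#' @param gamma RBF coefficient (> 0).
#' @param max_per_class,subsample_seed Per-class cap as in [train_rewklr()].
#' @return An object of class `grn_svm` wrapping the libsvm fit.
#' @export
train_svm <- function(train, cost = 18, gamma = 4,
                      max_per_class = 4000L, subsample_seed = 1L) {
  check_positive_scalar(cost, "cost")
  check_positive_scalar(gamma, "gamma")
  tf <- training_features(train)
  capped <- cap_training(tf$X, tf$y, max_per_class, subsample_seed)
  if (length(unique(capped$y)) < 2L) abort("Both classes must be present.")
  fit <- e1071::svm(x = capped$X, y = factor(capped$y, levels = c(0, 1)),
                    type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  structure(list(fit = fit, feature_names = tf$feature_names,
                 config = list(cost = cost, gamma = gamma)),
            class = "grn_svm")
}

#' Predict from a two-class SVM
#'
#' @param object A `grn_svm` model.
#' @param newdata Data frame with the model's feature columns, or a matrix.
#' @param ... Unused.
#' @return A tibble with `score` (signed decision value, positive for the
#'   interacting class) and `label` (0/1).
#' @export
predict.grn_svm <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata
       else as.matrix(as_tibble(newdata)[object$feature_names])
  pred <- stats::predict(object$fit, X, decision.values = TRUE)
  dv <- drop(attr(pred, "decision.values"))
  # libsvm orients the decision value by the first training class; flip so
  # that positive scores always mean class 1
  if (colnames(attr(pred, "decision.values"))[1] == "0/1") dv <- -dv
  tibble(score = dv, label = as.integer(as.character(pred)))
}

#' Fit a one-class SVM on known-interaction pairs
#'
#' Novelty-detection SVM trained on the positive class only, for the setting
#' where negatives are not deterministic. `nu` bounds (from both sides) the
#' fraction of training points treated as outliers.
#'
#' @param positives Numeric feature matrix or data frame of positive pairs
#'   (at least 2 rows).
#' @param nu Bound in (0, 1].
#' @param gamma RBF coefficient (> 0).
#' @return An object of class `grn_ocsvm`.
#' @export
train_ocsvm <- function(positives, nu = 0.03, gamma = 1.8) {
  if (!is.numeric(nu) || nu <= 0 || nu > 1) abort("`nu` must be in (0, 1].")
  check_positive_scalar(gamma, "gamma")
  X <- if (is.matrix(positives)) positives else {
    d <- as_tibble(positives)
    keep <- setdiff(names(d)[vapply(d, is.numeric, logical(1))],
                    c("label", "pc_ignore"))
    as.matrix(d[keep])
  }
  if (nrow(X) < 2L) abort("Need at least 2 positive points.")
  fit <- e1071::svm(x = X, y = NULL, type = "one-classification",
                    kernel = "radial", nu = nu, gamma = gamma, scale = FALSE)
  structure(list(fit = fit, feature_names = colnames(X),
                 config = list(nu = nu, gamma = gamma)),
            class = "grn_ocsvm")
}

#' Predict inlier status from a one-class SVM
#'
#' @param object A `grn_ocsvm` model.
#' @param newdata Feature matrix or data frame.
#' @param ... Unused.
#' @return A tibble with `score` (signed distance to the boundary) and
#'   `inlier` (logical; `TRUE` = predicted interaction-like).
#' @export
predict.grn_ocsvm <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata
       else {
         d <- as_tibble(newdata)
         cols <- intersect(object$feature_names, names(d))
         if (length(cols) != length(object$feature_names)) {
           X0 <- d[vapply(d, is.numeric, logical(1))]
           as.matrix(X0)
         } else as.matrix(d[object$feature_names])
       }
  pred <- stats::predict(object$fit, X, decision.values = TRUE)
  tibble(score = drop(attr(pred, "decision.values")),
         inlier = as.logical(pred))
}
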