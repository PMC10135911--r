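#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_col
#'   geom_abline labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a ROC curve with bootstrap error ribbon
#'
#' @param object A `roc_curve` from [roc_with_error()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  d <- object$curve
  ggplot(d, aes(x = .data$x_mean, y = .data$y_mean)) +
    geom_ribbon(aes(ymin = pmax(0, .data$y_mean - .data$y_sd),
                    ymax = pmin(1, .data$y_mean + .data$y_sd)),
                fill = "steelblue", alpha = 0.25) +
    geom_line(color = "steelblue") +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                color = "grey60") +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("ROC (AUC = %.3f, %d bootstrap resamples)",
                         object$auc, object$n_resamples)) +
    theme_minimal()
}

#' Plot a precision-recall curve with bootstrap error ribbon
#'
#' @param object A `pr_curve` from [pr_with_error()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pr_curve
#' @export
autoplot.pr_curve <- function(object, ...) {
  d <- object$curve[is.finite(object$curve$y_mean), ]
  ggplot(d, aes(x = .data$x_mean, y = .data$y_mean)) +
    geom_ribbon(aes(ymin = pmax(0, .data$y_mean - .data$y_sd),
                    ymax = pmin(1, .data$y_mean + .data$y_sd)),
                fill = "darkorange", alpha = 0.25) +
    geom_line(color = "darkorange") +
    labs(x = "Recall", y = "Precision",
         title = sprintf("Precision-recall (%d bootstrap resamples)",
                         object$n_resamples)) +
    theme_minimal()
}

#' Plot the absolute-correlation histogram of all pairs
#'
#' @param object A `correlation_histogram` from [correlation_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot correlation_histogram
#' @export
autoplot.correlation_histogram <- function(object, ...) {
  d <- as_tibble(object)
  d$mid <- (d$bin_lo + d$bin_hi) / 2
  ggplot(d, aes(x = .data$mid, y = .data$count)) +
    geom_col(width = d$bin_hi[1] - d$bin_lo[1], fill = "grey40") +
    labs(x = "|moment (1,1)| (absolute pair correlation)", y = "Pairs") +
    theme_minimal()
}

#' Plot linked vs unlinked correlation densities
#'
#' Overlaid density estimates of the (1,1) moment for gold-standard pairs and
#' all remaining pairs; heavy overlap shows why correlation alone cannot
#' separate the classes.
#'
#' @param object A `density_overlap` from [density_overlap()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot density_overlap
#' @export
autoplot.density_overlap <- function(object, ...) {
  d <- tibble(
    m11 = rep(object$grid, 2),
    density = c(object$density_positive, object$density_rest),
    pairs = rep(c("linked (gold)", "unlinked"), each = length(object$grid))
  )
  ggplot(d, aes(x = .data$m11, y = .data$density, color = .data$pairs)) +
    geom_line() +
    labs(x = "moment (1,1) (pair correlation)", y = "Density",
         title = sprintf("Correlation densities (overlap = %.2f)",
                         object$overlap)) +
    theme_minimal()
}
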