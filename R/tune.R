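#' Bootstrap hyperparameter tuning
#'
#' For every row of the parameter grid, draws `n_boot` bootstrap resamples of
#' the training rows; each resample trains on the drawn rows and tests on the
#' out-of-bag rows. The score is the mean over resamples of the average of
#' the two per-class accuracies (binary classifiers), or of the
#' positive-class accuracy (one-class). The winner is the highest mean score,
#' ties broken by grid order. A resample that misses a class (in bag or out
#' of bag where required) is redrawn, up to 25 attempts.
#'
#' @param train Labeled training tibble (for `"ocsvm"` only rows with
#'   `label == 1` are used to fit; out-of-bag positives are scored).
#' @param classifier `"rewklr"`, `"svm"` or `"ocsvm"`.
#' @param grid Tibble of candidate parameters: columns `lambda`, `sigma`
#'   (rewklr); `cost`, `gamma` (svm); `nu`, `gamma` (ocsvm).
#' @param n_boot Number of bootstrap resamples per grid point.
#' @param seed RNG seed; the whole search is deterministic under it.
#' @param ... Extra arguments passed to the training function.
#' @return A list of class `tune_result`: `best` (one-row tibble), `scores`
#'   (grid with `mean_score`, `sd_score`), `classifier`.
#' @export
bootstrap_tune <- function(train, classifier = c("rewklr", "svm", "ocsvm"),
                           grid, n_boot = 20L, seed = 1L, ...) {
  classifier <- match.arg(classifier)
  grid <- as_tibble(grid)
  if (nrow(grid) == 0) abort("The parameter grid is empty.")
  needed <- switch(classifier, rewklr = c("lambda", "sigma"),
                   svm = c("cost", "gamma"), ocsvm = c("nu", "gamma"))
  if (!all(needed %in% names(grid))) {
    abort(sprintf("Grid for %s needs columns: %s.", classifier,
                  paste(needed, collapse = ", ")))
  }
  tf <- training_features(train)
  n <- nrow(tf$X)

  resample_once <- function() {
    for (attempt in 1:25) {
      bag <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(bag))
      ok <- length(oob) > 0 &&
        (classifier == "ocsvm" ||
           (length(unique(tf$y[bag])) == 2L && length(unique(tf$y[oob])) == 2L))
      if (classifier == "ocsvm") {
        ok <- ok && sum(tf$y[bag] == 1L) >= 2L && sum(tf$y[oob] == 1L) >= 1L
      }
      if (ok) return(list(bag = bag, oob = oob))
    }
    abort("Could not draw a class-complete bootstrap resample in 25 attempts.")
  }

  score_one <- function(params, bag, oob) {
    Xb <- tf$X[bag, , drop = FALSE]
    yb <- tf$y[bag]
    Xo <- tf$X[oob, , drop = FALSE]
    yo <- tf$y[oob]
    tryCatch({
      if (classifier == "rewklr") {
        d <- as_tibble(Xb)
        d$label <- yb
        fit <- train_rewklr(d, lambda = params$lambda, sigma = params$sigma, ...)
        pred <- predict(fit, Xo, type = "class")
        mean(class_accuracies(yo, pred)$accuracy) / 100
      } else if (classifier == "svm") {
        d <- as_tibble(Xb)
        d$label <- yb
        fit <- train_svm(d, cost = params$cost, gamma = params$gamma, ...)
        pred <- predict(fit, Xo)$label
        mean(class_accuracies(yo, pred)$accuracy) / 100
      } else {
        fit <- train_ocsvm(Xb[yb == 1L, , drop = FALSE],
                           nu = params$nu, gamma = params$gamma)
        inl <- predict(fit, Xo[yo == 1L, , drop = FALSE])$inlier
        mean(inl)
      }
    }, error = function(e) NA_real_)
  }

  res <- with_seed(seed, {
    resamples <- lapply(seq_len(n_boot), function(i) resample_once())
    purrr::map_dfr(seq_len(nrow(grid)), function(g) {
      sc <- vapply(resamples,
                   function(r) score_one(grid[g, ], r$bag, r$oob),
                   numeric(1))
      tibble(grid_row = g, mean_score = mean(sc, na.rm = TRUE),
             sd_score = stats::sd(sc, na.rm = TRUE),
             n_failed = sum(is.na(sc)))
    })
  })
  scores <- dplyr::bind_cols(grid, res[c("mean_score", "sd_score", "n_failed")])
  best_row <- which.max(scores$mean_score)  # first max: stable tie-break
  structure(list(best = scores[best_row, ], scores = scores,
                 classifier = classifier),
            class = "tune_result")
}

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf("# Bootstrap tuning (%s): best mean score %.3f\n",
              x$classifier, x$best$mean_score))
  print(x$best)
  invisible(x)
}
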