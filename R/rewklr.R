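#' Gaussian radial basis function kernel
#'
#' Two parameterizations are in circulation and both are used here:
#' `sigma` (bandwidth) gives `K(u, v) = exp(-||u - v||^2 / (2 sigma^2))`, the
#' form used by the kernel logistic regression; `gamma` gives
#' `K(u, v) = exp(-gamma ||u - v||^2)`, the libsvm convention used by the
#' SVMs. They coincide when `gamma = 1 / (2 sigma^2)`.
#'
#' @param U,V Numeric matrices with matching column counts (rows are points).
#' @param bandwidth Positive kernel parameter (sigma or gamma).
#' @param parameterization `"sigma"` or `"gamma"`.
#' @return The `nrow(U)` x `nrow(V)` kernel matrix.
#' @export
rbf_kernel <- function(U, V = U, bandwidth,
                       parameterization = c("sigma", "gamma")) {
  parameterization <- match.arg(parameterization)
  check_positive_scalar(bandwidth, "bandwidth")
  U <- as.matrix(U)
  V <- as.matrix(V)
  if (ncol(U) != ncol(V)) abort("Feature widths of U and V differ.")
  d2 <- outer(rowSums(U^2), rowSums(V^2), "+") - 2 * tcrossprod(U, V)
  d2[d2 < 0] <- 0
  if (parameterization == "sigma") exp(-d2 / (2 * bandwidth^2))
  else exp(-bandwidth * d2)
}

# split a labeled training tibble into (X, y); feature columns are the
# numeric columns other than the bookkeeping ones
training_features <- function(train) {
  if (is.matrix(train)) abort("`train` must be a data frame with a `label` column.")
  if (!"label" %in% names(train)) abort("`train` needs a `label` column.")
  y <- as.integer(train$label)
  if (!all(y %in% c(0L, 1L))) abort("Labels must be 0/1.")
  drop_cols <- c("pair_a", "pair_b", "label", "provenance")
  feat_cols <- setdiff(names(train)[vapply(train, is.numeric, logical(1))],
                       drop_cols)
  if (length(feat_cols) == 0) abort("No numeric feature columns found.")
  X <- as.matrix(train[feat_cols])
  if (!all(is.finite(X))) abort("Features must be finite.")
  list(X = X, y = y, feature_names = feat_cols)
}

# subsample each class to at most `cap` rows (deterministic under seed)
cap_training <- function(X, y, cap, seed) {
  keep <- unlist(lapply(c(0L, 1L), function(cl) {
    idx <- which(y == cl)
    if (length(idx) > cap) {
      inform(sprintf("Subsampling class %d from %d to %d rows (seed %d).",
                     cl, length(idx), cap, seed))
      with_seed(seed + cl, sort(sample(idx, cap)))
    } else idx
  }))
  keep <- sort(keep)
  list(X = X[keep, , drop = FALSE], y = y[keep])
}

# weighted penalized log-likelihood of kernel logistic regression
rewklr_objective <- function(alpha, b, K, y, w, lambda) {
  eta <- drop(K %*% alpha) + b
  s <- 2 * y - 1
  ll <- -log1p(exp(-s * eta))
  big <- s * eta < -30  # avoid overflow in exp(); log1p(exp(x)) ~ x there
  ll[big] <- (s * eta)[big]
  sum(w * ll) - (lambda / 2) * drop(crossprod(alpha, K %*% alpha))
}

rewklr_gradient <- function(alpha, b, K, y, w, lambda) {
  p <- logistic(drop(K %*% alpha) + b)
  r <- w * (y - p)
  c(drop(K %*% (r - lambda * alpha)), sum(r))
}

#' Fit rare-event weighted kernel logistic regression (REWKLR)
#'
#' Kernel logistic regression with an RBF (sigma-parameterized) kernel, a
#' quadratic penalty on the dual coefficients, and per-class likelihood
#' weights that correct a case-control-style training sample for the true
#' event prevalence. With prevalence `tau` and sample prevalence `ybar`, the
#' positive class is weighted `tau / ybar` and the negative class
#' `(1 - tau) / (1 - ybar)`; regulatory interactions are rare among all gene
#' pairs, so `tau` is small when a balanced training set is drawn from an
#' unbalanced population. `tau = "sample"` gives unit weights.
#'
#' The fit maximizes
#' `J(alpha, b) = sum_i w_{y_i} [y_i log p_i + (1 - y_i) log(1 - p_i)] -
#'  (lambda / 2) alpha' K alpha`, `p_i = logistic((K alpha)_i + b)`,
#' by damped Newton iterations on `(alpha, b)`; `J` is concave, and the fit
#' errors out rather than return a point whose gradient norm exceeds `tol`.
#'
#' @param train Labeled training tibble: a `label` column (0/1) plus numeric
#'   feature columns (see [assemble_training_set()]).
#' @param lambda Regularization weight (> 0).
#' @param sigma RBF bandwidth (> 0).
#' @param tau Population event prevalence in (0, 1), or `"sample"` for unit
#'   weights.
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence threshold on the Euclidean norm of the gradient
#'   over `(alpha, b)`.
#' @param jitter Diagonal stabilizer added to the kernel matrix.
#' @param max_per_class Per-class training-size cap; larger classes are
#'   subsampled (the Gram matrix is quadratic in the training size).
#' @param subsample_seed Seed for the cap subsampling.
#' @return An object of class `rewklr`: support points, dual coefficients
#'   `alpha`, intercept, class weights, convergence diagnostics.
#' @export
train_rewklr <- function(train, lambda = 2.4, sigma = 0.2, tau = "sample",
                         max_iter = 100L, tol = 1e-6, jitter = 1e-8,
                         max_per_class = 4000L, subsample_seed = 1L) {
  check_positive_scalar(lambda, "lambda")
  check_positive_scalar(sigma, "sigma")
  check_positive_scalar(tol, "tol")
  tf <- training_features(train)
  capped <- cap_training(tf$X, tf$y, max_per_class, subsample_seed)
  X <- capped$X
  y <- capped$y
  n <- length(y)
  if (length(unique(y)) < 2L) abort("Both classes must be present.")
  ybar <- mean(y)
  if (identical(tau, "sample")) {
    w1 <- 1; w0 <- 1
  } else {
    if (!is.numeric(tau) || tau <= 0 || tau >= 1) {
      abort("`tau` must be in (0, 1) or \"sample\".")
    }
    w1 <- tau / ybar
    w0 <- (1 - tau) / (1 - ybar)
  }
  w <- ifelse(y == 1L, w1, w0)

  K0 <- rbf_kernel(X, X, sigma, "sigma")
  K <- K0
  diag(K) <- diag(K) + jitter
  alpha <- rep(0, n)
  b <- 0
  obj <- rewklr_objective(alpha, b, K, y, w, lambda)
  n_iter <- 0L
  g <- rewklr_gradient(alpha, b, K, y, w, lambda)

  for (iter in seq_len(max_iter)) {
    if (sqrt(sum(g^2)) <= tol) break
    p <- logistic(drop(K %*% alpha) + b)
    d <- w * p * (1 - p)
    # negative Hessian blocks; solve (-H) delta = g
    KD <- K * rep(d, each = n)          # K %*% diag(d), K symmetric
    H11 <- KD %*% K + lambda * K
    h12 <- drop(K %*% d)
    M <- rbind(cbind(H11, h12), c(h12, sum(d)))
    delta <- tryCatch(solve(M, g), error = function(e) {
      solve(M + diag(1e-6 * max(diag(M)), n + 1L), g)
    })
    # backtracking so accepted iterates never decrease J
    step <- 1
    repeat {
      a_new <- alpha + step * delta[seq_len(n)]
      b_new <- b + step * delta[n + 1L]
      obj_new <- rewklr_objective(a_new, b_new, K, y, w, lambda)
      if (is.finite(obj_new) && obj_new >= obj - 1e-12) break
      step <- step / 2
      if (step < 1e-10) abort("Line search failed; the system may be ill-conditioned.")
    }
    alpha <- a_new
    b <- b_new
    obj <- obj_new
    n_iter <- iter
    g <- rewklr_gradient(alpha, b, K, y, w, lambda)
  }
  grad_norm <- sqrt(sum(g^2))
  if (grad_norm > tol) {
    abort(sprintf(
      "REWKLR did not converge in %d iterations (gradient norm %.3e > tol %.1e).",
      max_iter, grad_norm, tol))
  }
  structure(list(
    support_points = X, alpha = alpha, intercept = b,
    class_weights = c(w0 = w0, w1 = w1),
    config = list(lambda = lambda, sigma = sigma, tau = tau,
                  max_iter = max_iter, tol = tol, jitter = jitter),
    feature_names = tf$feature_names,
    # fitted values use the exact prediction formula (unjittered kernel)
    fitted = logistic(drop(K0 %*% alpha) + b),
    labels = y, objective = obj, grad_norm = grad_norm, n_iter = n_iter
  ), class = "rewklr")
}

#' @export
print.rewklr <- function(x, ...) {
  cat(sprintf(
    "# REWKLR fit: %d support points, lambda = %g, sigma = %g\n",
    nrow(x$support_points), x$config$lambda, x$config$sigma))
  cat(sprintf("#   converged in %d Newton steps (gradient norm %.2e)\n",
              x$n_iter, x$grad_norm))
  invisible(x)
}

#' Predict interaction probabilities from a REWKLR fit
#'
#' @param object A `rewklr` model.
#' @param newdata Data frame carrying the model's feature columns, or a
#'   numeric matrix with matching width.
#' @param type `"prob"` for probabilities, `"class"` for 0/1 labels.
#' @param threshold Probability cut for `type = "class"`.
#' @param ... Unused.
#' @return Numeric probabilities in (0, 1), or integer labels.
#' @export
predict.rewklr <- function(object, newdata, type = c("prob", "class"),
                           threshold = 0.5, ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) newdata
       else as.matrix(as_tibble(newdata)[object$feature_names])
  if (ncol(X) != ncol(object$support_points)) {
    abort(sprintf("Feature width %d does not match the model's %d.",
                  ncol(X), ncol(object$support_points)))
  }
  K <- rbf_kernel(X, object$support_points, object$config$sigma, "sigma")
  p <- logistic(drop(K %*% object$alpha) + object$intercept)
  if (type == "prob") p else as.integer(p >= threshold)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the dual coefficients of a REWKLR fit
#'
#' @param x A `rewklr` model.
#' @param ... Unused.
#' @return A tibble with one row per training point (`term`, `estimate`,
#'   `label`, `weight`) plus the intercept row.
#' @method tidy rewklr
#' @export
tidy.rewklr <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = "(intercept)", estimate = x$intercept,
           label = NA_integer_, weight = NA_real_),
    tibble(term = sprintf("alpha_%d", seq_along(x$alpha)),
           estimate = x$alpha, label = x$labels,
           weight = unname(x$class_weights[x$labels + 1L]))
  )
}

#' One-row summary of a REWKLR fit
#'
#' @param x A `rewklr` model.
#' @param ... Unused.
#' @return A one-row tibble: objective, gradient norm, iterations,
#'   hyperparameters, training size.
#' @method glance rewklr
#' @export
glance.rewklr <- function(x, ...) {
  tibble(objective = x$objective, grad_norm = x$grad_norm,
         n_iter = x$n_iter, lambda = x$config$lambda,
         sigma = x$config$sigma,
         tau = if (identical(x$config$tau, "sample")) NA_real_ else x$config$tau,
         n_support = nrow(x$support_points))
}
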